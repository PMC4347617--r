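#' Relative vertex-to-vertex clustering value
#'
#' The clustering value of \code{u} relative to \code{v} is the fraction of
#' \code{u}'s augmented neighborhood \eqn{N_u^+ = N_u \cup \{u\}} that is
#' shared with \code{v}'s:
#' \deqn{R(u \to v) = \frac{|N_u^+ \cap N_v^+|}{|N_u^+|}.}
#' On a weighted graph each shared vertex \eqn{a} contributes
#' \eqn{w^*(u,a) \cdot w^*(a,v)} to the numerator and each
#' \eqn{b \in N_u^+} contributes \eqn{w^*(u,b)} to the denominator, where
#' \eqn{w^*} equals the edge weight on edges and, by convention,
#' \eqn{w^*(x,x) = 1} on the self-pair. Under this convention the weighted
#' form reduces exactly to the unweighted ratio above when all weights are
#' 1. Setting \code{strict_eq10 = TRUE} instead restricts both sums to true
#' edges (excluding the endpoint self-terms); that variant does not reduce
#' to the unweighted form and is retained for comparison only.
#'
#' \eqn{R(u \to v)} is a similarity premetric: it satisfies self-similarity
#' and maximality but is deliberately asymmetric. By preferential
#' attachment, a low-degree vertex is more likely to have joined the
#' community of a high-degree partner than the reverse, and
#' \eqn{R(u \to v) \ge R(v \to u)} whenever \eqn{|N_u^+| \le |N_v^+|} on
#' unit weights. The pair \code{(u, v)} need not be an edge.
#'
#' @param g a \code{pin_graph}.
#' @param u,v distinct vertex identifiers.
#' @param strict_eq10 use the strict edges-only weighted form (see above).
#' @return a number in \eqn{[0, 1]}.
#' @examples
#' g <- pin_graph(data.frame(from = c("a", "b", "a"),
#'                           to   = c("b", "c", "c")))
#' relative_clustering_value(g, "a", "b")
#' @export
relative_clustering_value <- function(g, u, v, strict_eq10 = FALSE) {
  ui <- vertex_index(g, u)
  vi <- vertex_index(g, v)
  if (ui == vi) {
    stop("u and v must be distinct (self-similarity is 1 by definition)")
  }
  rcv_idx(g, ui, vi, strict_eq10)
}

# index-level kernel shared with the clustering loop
rcv_idx <- function(g, ui, vi, strict = FALSE) {
  nu <- g$adj[[ui]]; wu <- g$adjw[[ui]]
  nv <- g$adj[[vi]]; wv <- g$adjw[[vi]]
  if (strict) {
    den <- sum(wu)
    if (den == 0) return(0)
    pos <- match(nu, nv)
    keep <- which(!is.na(pos))
    return(sum(wu[keep] * wv[pos[keep]]) / den)
  }
  nup <- c(ui, nu)           # N_u^+
  wup <- c(1, wu)            # w*(u, a) for a in N_u^+
  den <- sum(wup)
  pos <- match(nup, nv)
  in_nvp <- !is.na(pos) | nup == vi
  wav <- numeric(length(nup))
  wav[!is.na(pos)] <- wv[pos[!is.na(pos)]]
  wav[nup == vi] <- 1        # w*(v, v)
  sum(wup[in_nvp] * wav[in_nvp]) / den
}

#' Edge clustering value (comparator criterion)
#'
#' The symmetric common-neighbor criterion used by hierarchical PIN
#' clustering methods: on unit weights
#' \deqn{ECV(u, v) = \frac{|N_u \cap N_v|^2}{|N_u| \cdot |N_v|},}
#' and on weighted graphs the squared intersection is replaced by the
#' product of the weight sums of each endpoint's edges into the
#' intersection, over the product of the weighted degrees. Returns 0 when
#' either vertex is isolated.
#'
#' @inheritParams relative_clustering_value
#' @return a number in \eqn{[0, 1]}.
#' @export
edge_clustering_value <- function(g, u, v) {
  ui <- vertex_index(g, u)
  vi <- vertex_index(g, v)
  if (ui == vi) stop("u and v must be distinct")
  nu <- g$adj[[ui]]; wu <- g$adjw[[ui]]
  nv <- g$adj[[vi]]; wv <- g$adjw[[vi]]
  den <- sum(wu) * sum(wv)
  if (den == 0) return(0)
  pos <- match(nu, nv)
  keep <- which(!is.na(pos))
  sum(wu[keep]) * sum(wv[pos[keep]]) / den
}

#' Edge clustering coefficient (triangle comparator)
#'
#' Number of triangles through an edge over the maximum possible,
#' \eqn{Z^{(3)}_{u,v} / \min(k_u - 1, k_v - 1)}. When either endpoint is a
#' pendant the denominator vanishes and the coefficient is defined as 0,
#' keeping the function total over all edges.
#'
#' @inheritParams relative_clustering_value
#' @return a nonnegative number.
#' @export
edge_clustering_coefficient3 <- function(g, u, v) {
  ui <- vertex_index(g, u)
  vi <- vertex_index(g, v)
  if (!(vi %in% g$adj[[ui]])) stop("(u, v) is not an edge")
  z <- length(intersect(g$adj[[ui]], g$adj[[vi]]))
  den <- min(length(g$adj[[ui]]), length(g$adj[[vi]])) - 1L
  if (den <= 0L) return(0)
  z / den
}

#' Local edge betweenness
#'
#' Percentage of local paths between the exclusive neighborhoods of the two
#' endpoints that must cross the edge itself:
#' \eqn{\lambda(u, v) = 100 / (|N_u \cap N_v| + 1)}. A bridge between two
#' communities has no common neighbors and scores 100; edges embedded in
#' many triangles score low. High-\eqn{\lambda} edges are likely
#' inter-community bridges.
#'
#' @inheritParams relative_clustering_value
#' @return a number in \eqn{(0, 100]}.
#' @export
local_edge_betweenness <- function(g, u, v) {
  ui <- vertex_index(g, u)
  vi <- vertex_index(g, v)
  if (!(vi %in% g$adj[[ui]])) stop("(u, v) is not an edge")
  100 / (length(intersect(g$adj[[ui]], g$adj[[vi]])) + 1)
}

# validate the merging parameter
check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu >= 2) {
    stop("`mu` must be a single number with 0 <= mu < 2")
  }
  invisible(mu)
}

#' Merging test
#'
#' Decides whether vertex \code{u} should join the current cluster of
#' \code{v}: the test passes when
#' \eqn{R_w(u \to v) > 0.5\mu} and \eqn{R_w(u \to v) \ge R_w(v \to u)},
#' with a strict inequality against the threshold and a non-strict one in
#' the symmetry comparison. The merging parameter \eqn{\mu \in [0, 2)} maps
#' the threshold \eqn{0.5\mu} onto \eqn{[0, 1)}: larger \eqn{\mu} is
#' stricter and yields more, smaller clusters.
#'
#' @inheritParams relative_clustering_value
#' @param mu merging parameter, \eqn{0 \le \mu < 2}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
merge_test <- function(g, u, v, mu = 0.5, strict_eq10 = FALSE) {
  check_mu(mu)
  ruv <- relative_clustering_value(g, u, v, strict_eq10)
  ruv > 0.5 * mu &&
    ruv >= relative_clustering_value(g, v, u, strict_eq10)
}
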