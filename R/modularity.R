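#' Total link weight between two vertex sets
#'
#' \eqn{L(S_1, S_2) = \sum_{u \in S_1, v \in S_2} w(u, v)} over ordered
#' pairs, with \eqn{w(u, v) = 0} for non-edges. An edge with both endpoints
#' in \eqn{S_1 \cap S_2} therefore contributes twice — the double-count
#' convention under which \eqn{L(V, V) = 2\sum_e w(e)} and the cluster
#' coverage fractions \eqn{a_i} of Newman modularity sum to 1.
#'
#' @param g a \code{pin_graph}.
#' @param s1,s2 character vectors of vertex identifiers.
#' @return a nonnegative number.
#' @export
link_weight <- function(g, s1, s2) {
  e <- g$edges
  fwd <- e$from %in% s1 & e$to %in% s2
  bwd <- e$to %in% s1 & e$from %in% s2
  sum(e$weight * (fwd + bwd))
}

# per-cluster internal (2x) and cut link weights for a partition
partition_link_terms <- function(g, p) {
  if (!inherits(p, "pin_partition")) stop("`p` must be a pin_partition")
  if (!setequal(names(p$membership), g$vertices)) {
    stop("partition does not cover the graph's vertex set")
  }
  k <- length(p$clusters)
  e <- g$edges
  mi <- unname(p$membership[e$from])
  mj <- unname(p$membership[e$to])
  internal <- cut <- numeric(k)
  same <- mi == mj
  if (any(same)) {
    tw <- tapply(e$weight[same], mi[same], sum)
    internal[as.integer(names(tw))] <- tw
  }
  if (any(!same)) {
    for (side in list(mi[!same], mj[!same])) {
      tw <- tapply(e$weight[!same], side, sum)
      cut[as.integer(names(tw))] <- cut[as.integer(names(tw))] + tw
    }
  }
  list(internal2 = 2 * internal, cut = cut, total = 2 * sum(e$weight),
       sizes = lengths(p$clusters))
}

#' Partition quality: weighted modularity and modularity density
#'
#' Three quality functions for a partition \eqn{P_k = \{C_1, \dots, C_k\}}
#' of a weighted undirected graph, all built on the link-weight function
#' \eqn{L} of \code{\link{link_weight}} with
#' \eqn{e_{ii} = L(C_i, C_i)/L(V, V)} (fraction of link weight inside
#' cluster \eqn{i}) and \eqn{a_i = L(C_i, V)/L(V, V)} (fraction touching
#' it):
#' \itemize{
#'   \item \code{modularity_q}: Newman modularity
#'     \eqn{Q = \sum_i e_{ii} - a_i^2}; larger is better, \eqn{Q \le 1},
#'     and the single-cluster partition scores 0.
#'   \item \code{modularity_omega}: \eqn{\Omega = \sum_i e_{ii} \log a_i}
#'     (natural log), which tolerates more diverse cluster sizes than
#'     \eqn{Q}; note that by its definition smaller values indicate
#'     stronger structure. A term with \eqn{e_{ii} = 0} contributes 0.
#'   \item \code{modularity_d}: modularity density
#'     \eqn{D = \sum_i (L(C_i, C_i) - L(C_i, \bar{C_i})) / |C_i|}, which
#'     sidesteps the resolution limit of \eqn{Q} by normalizing per
#'     cluster size instead of per total edge weight.
#' }
#' For an edgeless graph all three return 0 by convention.
#'
#' @param g a \code{pin_graph}.
#' @param p a \code{pin_partition} of \code{g}'s vertices.
#' @return a single number.
#' @examples
#' toy <- pin_graph(data.frame(
#'   from = c("a", "a", "b", "c", "d", "d", "e"),
#'   to   = c("b", "c", "c", "d", "e", "f", "f")))
#' p <- facpin_cluster(toy, mu = 1)
#' modularity_q(toy, p)  # 5/14 for the two-triangle split
#' @export
modularity_q <- function(g, p) {
  t <- partition_link_terms(g, p)
  if (t$total == 0) return(0)
  e_ii <- t$internal2 / t$total
  a_i <- (t$internal2 + t$cut) / t$total
  sum(e_ii - a_i^2)
}

#' @rdname modularity_q
#' @export
modularity_omega <- function(g, p) {
  t <- partition_link_terms(g, p)
  if (t$total == 0) return(0)
  e_ii <- t$internal2 / t$total
  a_i <- (t$internal2 + t$cut) / t$total
  sum(ifelse(e_ii > 0, e_ii * log(a_i), 0))
}

#' @rdname modularity_q
#' @export
modularity_d <- function(g, p) {
  t <- partition_link_terms(g, p)
  sum((t$internal2 - t$cut) / t$sizes)
}

#' Full modularity report for a partition
#'
#' Computes all three quality functions plus the per-cluster link-weight
#' terms they are built from.
#'
#' @inheritParams modularity_q
#' @return a list with components \code{q}, \code{omega}, \code{d},
#'   \code{k}, and \code{per_cluster} (data.frame with columns
#'   \code{cluster_id}, \code{size}, \code{e_ii}, \code{a_i},
#'   \code{internal_link_weight}, \code{cut_link_weight}).
#' @export
modularity_report <- function(g, p) {
  t <- partition_link_terms(g, p)
  if (t$total == 0) {
    e_ii <- a_i <- numeric(length(t$sizes))
  } else {
    e_ii <- t$internal2 / t$total
    a_i <- (t$internal2 + t$cut) / t$total
  }
  list(q = if (t$total == 0) 0 else sum(e_ii - a_i^2),
       omega = if (t$total == 0) 0 else sum(ifelse(e_ii > 0, e_ii * log(a_i), 0)),
       d = sum((t$internal2 - t$cut) / t$sizes),
       k = length(t$sizes),
       per_cluster = data.frame(
         cluster_id = seq_along(t$sizes),
         size = t$sizes,
         e_ii = e_ii,
         a_i = a_i,
         internal_link_weight = t$internal2,
         cut_link_weight = t$cut))
}
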