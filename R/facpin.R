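#' Construct a partition of the vertex set
#'
#' A partition is a disjoint cover of the vertices by non-empty clusters —
#' the output form of \code{\link{facpin_cluster}} and the ground-truth form
#' of the planted-community simulator. The constructor validates
#' disjointness and coverage.
#'
#' @param clusters a list of character vectors of vertex identifiers.
#' @param vertices the full vertex set the clusters must cover; defaults to
#'   the union of the clusters.
#' @return an object of class \code{pin_partition} with components
#'   \code{clusters} (list of sorted character vectors) and
#'   \code{membership} (named integer vector of cluster indices).
#' @export
pin_partition <- function(clusters, vertices = NULL) {
  clusters <- lapply(clusters, function(cl) sort(as.character(cl)))
  if (any(lengths(clusters) == 0L)) stop("clusters must be non-empty")
  all_v <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_v)) {
    stop("clusters overlap: partition must be disjoint")
  }
  if (!is.null(vertices)) {
    vertices <- as.character(vertices)
    if (!setequal(all_v, vertices)) {
      stop("clusters do not cover the vertex set exactly")
    }
  }
  membership <- rep(seq_along(clusters), lengths(clusters))
  names(membership) <- all_v
  membership <- membership[order(names(membership))]
  structure(list(clusters = clusters, membership = membership),
            class = "pin_partition")
}

#' @export
print.pin_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("pin_partition: %d clusters over %d vertices", length(sz),
              sum(sz)))
  if (length(sz)) {
    cat(sprintf(" (max size %d, mean size %.2f)", max(sz), mean(sz)))
  }
  cat("\n")
  invisible(x)
}

#' Number of clusters and cluster sizes
#'
#' @param p a \code{pin_partition}.
#' @return \code{n_clusters} the number of clusters; \code{cluster_sizes}
#'   an integer vector of cluster sizes.
#' @export
n_clusters <- function(p) length(p$clusters)

#' @rdname n_clusters
#' @export
cluster_sizes <- function(p) lengths(p$clusters)

#' Fast agglomerative clustering of a protein interaction network
#'
#' Detects non-overlapping communities by a single greedy pass over the
#' vertices in non-increasing order of weighted degree \eqn{\kappa_v}. Every
#' vertex starts as a singleton cluster. Each hub \code{v}, in turn, tests
#' each of its still-unassigned neighbors \code{u} with the merging
#' condition \eqn{R_w(u \to v) > 0.5\mu} and
#' \eqn{R_w(u \to v) \ge R_w(v \to u)} (see \code{\link{merge_test}}) and
#' absorbs those that pass into its current cluster. A vertex counts as
#' assigned once it belongs to a cluster of size two or more; a processed
#' hub that absorbed no one therefore remains absorbable by a later,
#' lower-degree hub, which prevents peripheral vertices from being stranded
#' as singletons. Ties in \eqn{\kappa_v}, and neighbor iteration within a
#' hub, are broken lexicographically so results are reproducible and
#' independent of edge-list row order.
#'
#' The cost of one merging test is proportional to the degrees involved, so
#' the whole pass runs in roughly \eqn{O(n \kappa_{ave}^2)} time — linear in
#' the number of vertices when the average degree is bounded, as in
#' scale-free PINs.
#'
#' @param g a \code{pin_graph}.
#' @param mu merging parameter, \eqn{0 \le \mu < 2}; larger values are
#'   stricter and produce more, smaller clusters. Default 0.5.
#' @param strict_eq10 forwarded to
#'   \code{\link{relative_clustering_value}}.
#' @return a \code{pin_partition}. Cluster indices are assigned in order of
#'   first appearance over the lexicographically sorted vertices.
#' @examples
#' toy <- pin_graph(data.frame(
#'   from = c("a", "a", "b", "c", "d", "d", "e"),
#'   to   = c("b", "c", "c", "d", "e", "f", "f")))
#' facpin_cluster(toy, mu = 1)
#' @export
facpin_cluster <- function(g, mu = 0.5, strict_eq10 = FALSE) {
  check_mu(mu)
  n <- length(g$vertices)
  if (n == 0L) {
    return(structure(list(clusters = list(),
                          membership = structure(integer(0),
                                                 names = character(0))),
                     class = "pin_partition"))
  }
  kappa <- vapply(g$adjw, sum, numeric(1))
  queue <- order(-kappa, seq_len(n)) # vertices are sorted, so index = lex
  cid <- seq_len(n)                  # cluster id of each vertex
  csize <- rep(1L, n)
  thr <- 0.5 * mu
  for (v in queue) {
    cv <- cid[v]
    for (u in g$adj[[v]]) {          # adj is sorted: lexicographic
      if (csize[cid[u]] == 1L && cid[u] != cv) {
        ruv <- rcv_idx(g, u, v, strict_eq10)
        if (ruv > thr && ruv >= rcv_idx(g, v, u, strict_eq10)) {
          csize[cid[u]] <- 0L
          cid[u] <- cv
          csize[cv] <- csize[cv] + 1L
        }
      }
    }
  }
  labels <- match(cid, unique(cid))  # first appearance over sorted vertices
  clusters <- unname(split(g$vertices, labels))
  pin_partition(clusters)
}

#' Sweep the merging parameter
#'
#' Re-clusters the network at each value of \eqn{\mu} and tabulates the
#' number of clusters \eqn{k}, the largest cluster size and the mean cluster
#' size. Because the merge threshold \eqn{0.5\mu} tightens as \eqn{\mu}
#' grows, cluster count typically increases (and sizes shrink) across an
#' increasing sweep.
#'
#' @param g a \code{pin_graph}.
#' @param mus numeric vector of merging parameter values, each in
#'   \eqn{[0, 2)}.
#' @param strict_eq10 forwarded to \code{\link{facpin_cluster}}.
#' @return a data.frame with columns \code{mu}, \code{k}, \code{max_size},
#'   \code{ave_size}.
#' @export
mu_sweep <- function(g, mus, strict_eq10 = FALSE) {
  rows <- lapply(mus, function(mu) {
    p <- facpin_cluster(g, mu, strict_eq10)
    sz <- cluster_sizes(p)
    data.frame(mu = mu,
               k = length(sz),
               max_size = if (length(sz)) max(sz) else 0L,
               ave_size = if (length(sz)) mean(sz) else 0)
  })
  do.call(rbind, rows)
}

#' Write a partition as TSV
#'
#' Writes one row per vertex (\code{vertex}, \code{cluster_id}), sorted by
#' vertex id, and optionally a companion summary with one row per cluster
#' (\code{cluster_id}, \code{size}, \code{members} semicolon-joined).
#'
#' @param p a \code{pin_partition}.
#' @param path output path for the per-vertex table.
#' @param summary_path optional output path for the per-cluster summary.
#' @return invisibly, \code{path}.
#' @export
write_partition <- function(p, path, summary_path = NULL) {
  df <- data.frame(vertex = names(p$membership),
                   cluster_id = unname(p$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- data.frame(
      cluster_id = seq_along(p$clusters),
      size = lengths(p$clusters),
      members = vapply(p$clusters, paste, character(1), collapse = ";"))
    utils::write.table(sm, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a partition written by \code{write_partition}
#'
#' @param path path to a TSV with columns \code{vertex},
#'   \code{cluster_id}.
#' @return a \code{pin_partition}.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  pin_partition(unname(split(df$vertex, df$cluster_id)))
}
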