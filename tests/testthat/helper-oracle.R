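# Independent brute-force oracles, computed straight from a raw edge table
# with plain set operations -- deliberately sharing no code with the package
# internals they are used to check.

oracle_neighbors <- function(edges, v) {
  sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
}

oracle_weight <- function(edges, x, y) {
  hit <- (edges$from == x & edges$to == y) | (edges$from == y & edges$to == x)
  if (any(hit)) edges$weight[which(hit)[1]] else 0
}

# Unweighted relative clustering value: |Nu+ n Nv+| / |Nu+|
oracle_rcv_unweighted <- function(edges, u, v) {
  nu_plus <- union(oracle_neighbors(edges, u), u)
  nv_plus <- union(oracle_neighbors(edges, v), v)
  length(intersect(nu_plus, nv_plus)) / length(nu_plus)
}

# Weighted relative clustering value under the self-weight w*(x,x)=1
# convention, evaluated term by term.
oracle_rcv_weighted <- function(edges, u, v) {
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  wstar <- function(x, y) if (x == y) 1 else oracle_weight(edges, x, y)
  nu_plus <- union(oracle_neighbors(edges, u), u)
  nv_plus <- union(oracle_neighbors(edges, v), v)
  iplus <- intersect(nu_plus, nv_plus)
  num <- sum(vapply(iplus, function(a) wstar(u, a) * wstar(a, v), numeric(1)))
  den <- sum(vapply(nu_plus, function(b) wstar(u, b), numeric(1)))
  if (den == 0) 0 else num / den
}

# Literal step-by-step transcription of the clustering pseudocode: every
# vertex a singleton, vertices processed in non-increasing weighted-degree
# order (ties lexicographic), unassigned neighbors (cluster size 1) merged
# into the current hub's cluster when the merging condition holds, clusters
# read off by first appearance over sorted vertices. No shared code with
# facpin_cluster; neighborhoods, weighted degrees and the premetric are all
# recomputed from the edge table.
oracle_facpin <- function(edges, vertices, mu) {
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  vertices <- sort(vertices)
  cluster_of <- stats::setNames(vertices, vertices) # cluster label per vertex
  kappa <- vapply(vertices, function(v) {
    sum(vapply(oracle_neighbors(edges, v),
               function(b) oracle_weight(edges, v, b), numeric(1)))
  }, numeric(1))
  queue <- vertices[order(-kappa, vertices)]
  for (v in queue) {
    for (u in sort(oracle_neighbors(edges, v))) {
      assigned <- sum(cluster_of == cluster_of[u]) >= 2
      if (!assigned && cluster_of[u] != cluster_of[v]) {
        ruv <- oracle_rcv_weighted(edges, u, v)
        rvu <- oracle_rcv_weighted(edges, v, u)
        if (ruv > 0.5 * mu && ruv >= rvu) {
          cluster_of[u] <- cluster_of[v]
        }
      }
    }
  }
  unname(split(vertices, match(cluster_of, unique(cluster_of))))
}
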