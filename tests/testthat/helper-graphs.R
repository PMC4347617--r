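# Two unit-weight triangles {a,b,c} and {d,e,f} joined by the bridge (c,d).
toy6_edges <- function() {
  data.frame(from = c("a", "a", "b", "c", "d", "d", "e"),
             to   = c("b", "c", "c", "d", "e", "f", "f"),
             stringsAsFactors = FALSE)
}

toy6_graph <- function() pin_graph(toy6_edges())

# Erdos-Renyi edge table on vertices v01..vNN; optionally random weights.
random_edge_table <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  verts <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  data.frame(from = verts[idx[keep, 1]],
             to = verts[idx[keep, 2]],
             weight = if (weighted) runif(sum(keep)) else rep(1, sum(keep)),
             stringsAsFactors = FALSE)
}

random_unit_graph <- function(n, p, seed, weighted = FALSE) {
  n <- as.integer(n)
  pin_graph(random_edge_table(n, p, seed, weighted),
            vertices = sprintf("v%02d", seq_len(n)))
}

clique_graph <- function(labels) {
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
             stringsAsFactors = FALSE)
}
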