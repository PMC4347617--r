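#' Construct a weighted protein interaction network
#'
#' Builds an undirected, simple, weighted graph from an edge table. This is
#' the basic container used throughout the package: vertices are opaque
#' protein identifiers (strings), and each edge carries a reliability weight
#' in \eqn{[0,1]} interpreted as the probability that the interaction is a
#' true positive.
#'
#' Self-loops are dropped with a warning: every neighborhood-based criterion
#' in this package assumes a vertex is not its own neighbor, and a stored
#' self-loop would corrupt weighted degrees and augmented neighborhoods.
#' Duplicate rows for the same unordered pair collapse to a single edge; the
#' first weight wins and a warning is emitted. Weights outside \eqn{[0,1]}
#' are an error, not a clamp, so that data problems surface immediately.
#'
#' @param edges a data.frame whose first two columns are vertex identifiers
#'   and whose optional third column is a numeric weight.
#' @param default_weight weight assigned to rows without a weight column.
#' @param vertices optional character vector of additional (possibly
#'   isolated) vertices to include.
#' @return an object of class \code{pin_graph}.
#' @examples
#' g <- pin_graph(data.frame(from = c("a", "b", "a"),
#'                           to   = c("b", "c", "c")))
#' pin_degree(g, "a")
#' @export
pin_graph <- function(edges, default_weight = 1, vertices = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    stop("`edges` must be a data.frame with at least two columns")
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (ncol(edges) >= 3L) {
    weight <- as.numeric(edges[[3L]])
    weight[is.na(edges[[3L]])] <- default_weight
  } else {
    weight <- rep(default_weight, length(from))
  }
  if (anyNA(from) || anyNA(to) || anyNA(weight)) {
    stop("edge table contains missing values")
  }
  if (any(weight < 0 | weight > 1)) {
    bad <- which(weight < 0 | weight > 1)[1L]
    stop(sprintf("edge weight %g outside [0, 1] (row %d)", weight[bad], bad))
  }
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop row(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  # canonical unordered representation: lexicographically smaller id first
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge row(s); first weight kept",
                    sum(dup)))
    a <- a[!dup]; b <- b[!dup]; weight <- weight[!dup]
  }
  verts <- sort(unique(c(a, b, as.character(vertices))))
  n <- length(verts)
  ai <- match(a, verts)
  bi <- match(b, verts)
  # adjacency lists over integer vertex indices, neighbors sorted
  adj <- vector("list", n)
  adjw <- vector("list", n)
  deg <- tabulate(c(ai, bi), nbins = n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer(deg[i])
    adjw[[i]] <- numeric(deg[i])
  }
  fill <- integer(n)
  for (e in seq_along(ai)) {
    i <- ai[e]; j <- bi[e]; w <- weight[e]
    fill[i] <- fill[i] + 1L; adj[[i]][fill[i]] <- j; adjw[[i]][fill[i]] <- w
    fill[j] <- fill[j] + 1L; adj[[j]][fill[j]] <- i; adjw[[j]][fill[j]] <- w
  }
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- adj[[i]][o]
    adjw[[i]] <- adjw[[i]][o]
  }
  eord <- order(a, b)
  structure(
    list(vertices = verts,
         edges = data.frame(from = a[eord], to = b[eord],
                            weight = weight[eord],
                            stringsAsFactors = FALSE),
         adj = adj, adjw = adjw),
    class = "pin_graph")
}

#' @export
print.pin_graph <- function(x, ...) {
  cat(sprintf("pin_graph: %d vertices, %d edges", length(x$vertices),
              nrow(x$edges)))
  w <- x$edges$weight
  if (nrow(x$edges) > 0 && any(w != 1)) {
    cat(sprintf(" (weighted, range [%.3g, %.3g])", min(w), max(w)))
  }
  cat("\n")
  invisible(x)
}

# resolve a vertex id to its index, erroring on unknown ids
vertex_index <- function(g, v) {
  i <- match(as.character(v), g$vertices)
  if (anyNA(i)) {
    stop(sprintf("unknown vertex: %s",
                 paste(v[is.na(i)], collapse = ", ")))
  }
  i
}

#' Vertices and edges of a PIN
#'
#' @param g a \code{pin_graph}.
#' @return \code{pin_vertices} returns the sorted character vector of vertex
#'   identifiers; \code{pin_edges} the canonical edge table with columns
#'   \code{from}, \code{to}, \code{weight} (with \code{from < to}).
#' @export
pin_vertices <- function(g) g$vertices

#' @rdname pin_vertices
#' @export
pin_edges <- function(g) g$edges

#' Vertex degree and weighted degree
#'
#' The degree \eqn{k_v} is the number of interaction partners; the weighted
#' degree \eqn{\kappa_v = \sum_b w(v, b)} sums the reliability weights of
#' incident edges. On a unit-weight graph the two coincide.
#'
#' @param g a \code{pin_graph}.
#' @param v vertex identifier(s); if \code{NULL}, all vertices.
#' @return a named integer (resp. numeric) vector.
#' @export
pin_degree <- function(g, v = NULL) {
  idx <- if (is.null(v)) seq_along(g$vertices) else vertex_index(g, v)
  out <- vapply(g$adj[idx], length, integer(1))
  names(out) <- g$vertices[idx]
  out
}

#' @rdname pin_degree
#' @export
weighted_degree <- function(g, v = NULL) {
  idx <- if (is.null(v)) seq_along(g$vertices) else vertex_index(g, v)
  out <- vapply(g$adjw[idx], sum, numeric(1))
  names(out) <- g$vertices[idx]
  out
}

#' Neighborhood of a vertex
#'
#' Returns the neighbor set \eqn{N_v} and the augmented neighborhood
#' \eqn{N_v^+ = N_v \cup \{v\}} on which the relative clustering value is
#' defined.
#'
#' @param g a \code{pin_graph}.
#' @param v a single vertex identifier.
#' @return a list with components \code{vertex}, \code{neighbors} and
#'   \code{augmented} (character vectors, sorted).
#' @export
neighborhood <- function(g, v) {
  if (length(v) != 1L) stop("`v` must be a single vertex id")
  i <- vertex_index(g, v)
  nb <- g$vertices[g$adj[[i]]]
  list(vertex = g$vertices[i],
       neighbors = nb,
       augmented = sort(c(g$vertices[i], nb)))
}

#' Read and write edge lists
#'
#' Edge lists are whitespace- or tab-delimited text with two or three
#' columns: \code{node_a node_b [weight]}. Lines beginning with \code{#} and
#' blank lines are ignored. Rows without a weight receive
#' \code{default_weight}; this mirrors the convention that an unweighted PIN
#' is treated as having all weights equal to 1.
#'
#' @param path file path.
#' @param default_weight weight for two-column rows.
#' @return \code{read_edge_list} returns a \code{pin_graph};
#'   \code{write_edge_list} invisibly returns \code{path}.
#' @export
read_edge_list <- function(path, default_weight = 1) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    bad <- lineno[which(nf < 2 | nf > 3)[1L]]
    stop(sprintf("malformed edge-list row at line %d of %s", bad, path))
  }
  from <- vapply(fields, `[`, character(1), 1L)
  to <- vapply(fields, `[`, character(1), 2L)
  wtxt <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_,
                 character(1))
  weight <- suppressWarnings(as.numeric(wtxt))
  badw <- !is.na(wtxt) & is.na(weight)
  if (any(badw)) {
    stop(sprintf("unparseable weight at line %d of %s",
                 lineno[which(badw)[1L]], path))
  }
  weight[is.na(weight)] <- default_weight
  pin_graph(data.frame(from = from, to = to, weight = weight,
                       stringsAsFactors = FALSE))
}

#' @rdname read_edge_list
#' @param g a \code{pin_graph}.
#' @export
write_edge_list <- function(g, path) {
  e <- g$edges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight), con)
  invisible(path)
}
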