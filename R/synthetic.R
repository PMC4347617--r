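#' Specify a planted-community PIN simulation
#'
#' Describes a planted-partition random graph dressed up as a protein
#' interaction network: disjoint communities of given sizes, an edge between
#' each intra-community pair with probability \code{p_in} and each
#' inter-community pair with probability \code{p_out}, plus an optional
#' layer of spurious false-positive edges mimicking noisy interaction data.
#' True edges draw reliability weights uniformly from \code{w_true},
#' spurious edges from \code{w_false}; with both at \code{c(1, 1)} the graph
#' is effectively unweighted. The number of spurious edges is
#' \code{round(fp_rate * m_true)}, relative to the realized true-edge count
#' so that noise levels are comparable across sizes.
#'
#' Generation is fully determined by \code{seed} (R's Mersenne-Twister,
#' seeded locally without touching the caller's RNG state).
#'
#' @param community_sizes integer vector of community sizes (each \eqn{\ge}
#'   1). Default: four communities of 20.
#' @param p_in intra-community edge probability; default 0.9.
#' @param p_out inter-community edge probability; default 0.02. Planted
#'   structure requires \code{p_in > p_out}; \code{p_in <= p_out} is
#'   allowed as a deliberately structureless baseline.
#' @param fp_rate spurious-edge rate relative to the true-edge count, in
#'   \eqn{[0, 1]}; default 0.
#' @param w_true,w_false length-2 numeric ranges in \eqn{[0, 1]} for true
#'   and spurious edge weights; default \code{c(1, 1)} (unit weights).
#' @param seed integer random seed; default 1.
#' @return an object of class \code{planted_spec}.
#' @export
planted_spec <- function(community_sizes = rep(20L, 4L), p_in = 0.9,
                         p_out = 0.02, fp_rate = 0, w_true = c(1, 1),
                         w_false = c(1, 1), seed = 1L) {
  community_sizes <- as.integer(community_sizes)
  if (length(community_sizes) == 0L || any(community_sizes < 1L)) {
    stop("`community_sizes` must be a non-empty vector of sizes >= 1")
  }
  for (nm in c("p_in", "p_out", "fp_rate")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < 0 || val > 1) {
      stop(sprintf("`%s` must be a single probability in [0, 1]", nm))
    }
  }
  for (nm in c("w_true", "w_false")) {
    rng <- get(nm)
    if (length(rng) != 2L || any(rng < 0) || any(rng > 1) ||
        rng[1] > rng[2]) {
      stop(sprintf("`%s` must be an increasing range within [0, 1]", nm))
    }
  }
  structure(list(community_sizes = community_sizes, p_in = p_in,
                 p_out = p_out, fp_rate = fp_rate, w_true = w_true,
                 w_false = w_false, seed = as.integer(seed)),
            class = "planted_spec")
}

# run expr under a locally-seeded RNG, restoring caller state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# sample `count` distinct unordered inter-community vertex pairs uniformly,
# excluding pairs already present in `taken` (codes a*(n+1) + b, a < b)
sample_inter_pairs <- function(n, comm, count, taken = double(0)) {
  base <- n + 1
  chosen <- double(0)
  while (length(chosen) < count) {
    need <- count - length(chosen)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(n, 2L * need, replace = TRUE)
    a <- pmin(i, j); b <- pmax(i, j)
    ok <- a != b & comm[a] != comm[b]
    code <- as.double(a[ok]) * base + b[ok]
    code <- setdiff(unique(code), c(taken, chosen))
    chosen <- c(chosen, utils::head(code, need))
  }
  list(a = as.integer(chosen %/% base), b = as.integer(chosen %% base))
}

#' Generate a planted-community PIN with matching gold standards
#'
#' Realizes the random graph described by a \code{\link{planted_spec}} and
#' packages it with the ground truth needed to score a clustering: the
#' planted partition itself, a known-complex catalog (the communities of
#' size \eqn{\ge} 3) and a functional-annotation catalog assigning each
#' community a category. Vertices are named \code{c<i>_n<j>} (community
#' \code{i}, member \code{j}). Inter-community edges are realized by
#' drawing their total count from the exact binomial law and placing them
#' uniformly at random, which is equivalent to independent per-pair coin
#' flips but scales to large vertex counts.
#'
#' @param spec a \code{planted_spec}.
#' @return a list with components \code{graph} (\code{pin_graph}),
#'   \code{truth} (\code{pin_partition}), \code{complexes} and
#'   \code{annotations} (named lists), and \code{manifest} (the spec fields
#'   plus realized edge counts).
#' @examples
#' sim <- generate_planted_pin(planted_spec(c(5, 5), p_in = 1, p_out = 0))
#' sim$graph
#' @export
generate_planted_pin <- function(spec) {
  if (!inherits(spec, "planted_spec")) {
    stop("`spec` must be a planted_spec")
  }
  sizes <- spec$community_sizes
  n <- sum(sizes)
  comm <- rep(seq_along(sizes), sizes)
  vnames <- sprintf("c%d_n%02d", comm,
                    unlist(lapply(sizes, seq_len), use.names = FALSE))
  with_local_seed(spec$seed, {
    # intra-community candidate pairs, enumerated per community
    ia <- integer(0); ib <- integer(0)
    offset <- 0L
    for (s in sizes) {
      if (s > 1L) {
        idx <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
        ia <- c(ia, offset + idx[, 1L])
        ib <- c(ib, offset + idx[, 2L])
      }
      offset <- offset + s
    }
    keep <- stats::runif(length(ia)) < spec$p_in
    ea <- ia[keep]; eb <- ib[keep]
    # inter-community edges: binomial count, uniform placement
    inter_pairs <- n * (n - 1) / 2 - sum(sizes * (sizes - 1) / 2)
    if (spec$p_out > 0 && inter_pairs > 0) {
      m_out <- stats::rbinom(1L, inter_pairs, spec$p_out)
      if (m_out > 0) {
        pr <- sample_inter_pairs(n, comm, m_out)
        ea <- c(ea, pr$a); eb <- c(eb, pr$b)
      }
    }
    m_true <- length(ea)
    w <- stats::runif(m_true, spec$w_true[1], spec$w_true[2])
    # spurious false-positive edges on top of the true graph
    m_fp <- round(spec$fp_rate * m_true)
    if (m_fp > 0) {
      taken <- as.double(ea) * (n + 1) + eb
      pr <- sample_inter_pairs(n, comm, m_fp, taken = taken)
      ea <- c(ea, pr$a); eb <- c(eb, pr$b)
      w <- c(w, stats::runif(m_fp, spec$w_false[1], spec$w_false[2]))
    }
    graph <- pin_graph(
      data.frame(from = vnames[ea], to = vnames[eb], weight = w,
                 stringsAsFactors = FALSE),
      vertices = vnames)
    truth <- pin_partition(split(vnames, comm), vertices = vnames)
    big <- which(sizes >= 3L)
    complexes <- lapply(big, function(i) vnames[comm == i])
    names(complexes) <- sprintf("K%02d", big)
    annotations <- lapply(seq_along(sizes), function(i) vnames[comm == i])
    names(annotations) <- sprintf("F%02d", seq_along(sizes))
    list(graph = graph, truth = truth, complexes = complexes,
         annotations = annotations,
         manifest = c(unclass(spec),
                      list(n_vertices = n, n_true_edges = m_true,
                           n_false_edges = m_fp)))
  })
}

#' Community recovery experiment on planted PINs
#'
#' Repeats generate-cluster-score over consecutive seeds: each replicate
#' draws a planted PIN, clusters it with \code{\link{facpin_cluster}}, and
#' scores the predicted clusters against the planted communities with
#' \code{\link{complex_match_stats}}.
#'
#' @param spec a \code{planted_spec}; its \code{seed} seeds the first
#'   replicate and subsequent replicates use consecutive seeds.
#' @param mu merging parameter passed to \code{\link{facpin_cluster}}.
#' @param n_seeds number of replicates; default 20.
#' @param tau,min_size matching parameters passed to
#'   \code{\link{complex_match_stats}}.
#' @return a list with \code{per_seed} (data.frame: \code{seed},
#'   \code{k}, \code{sensitivity}, \code{specificity}, \code{f_score}) and
#'   \code{summary} (means and standard deviations of the three rates).
#' @export
recovery_experiment <- function(spec, mu = 0.5, n_seeds = 20, tau = 0.2,
                                min_size = 3) {
  rows <- lapply(seq_len(n_seeds) - 1L, function(off) {
    sp <- spec
    sp$seed <- spec$seed + off
    sim <- generate_planted_pin(sp)
    p <- facpin_cluster(sim$graph, mu)
    ms <- complex_match_stats(p, sim$complexes, tau = tau,
                              min_size = min_size)
    data.frame(seed = sp$seed, k = n_clusters(p),
               sensitivity = ms$sensitivity,
               specificity = ms$specificity, f_score = ms$f_score)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       summary = data.frame(
         metric = c("sensitivity", "specificity", "f_score"),
         mean = c(mean(per_seed$sensitivity), mean(per_seed$specificity),
                  mean(per_seed$f_score)),
         sd = c(stats::sd(per_seed$sensitivity),
                stats::sd(per_seed$specificity),
                stats::sd(per_seed$f_score))))
}

#' Write simulator output as fixture files
#'
#' Writes the edge list, ground-truth partition, complex catalog and
#' annotation catalog of a simulated PIN into a directory, together with a
#' JSON manifest recording the generating spec and seed.
#'
#' @param sim output of \code{\link{generate_planted_pin}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_planted_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(sim$graph, file.path(dir, "edges.tsv"))
  write_partition(sim$truth, file.path(dir, "truth.tsv"))
  write_complex_catalog(sim$complexes, file.path(dir, "complexes.tsv"))
  write_annotation_catalog(sim$annotations,
                           file.path(dir, "annotations.tsv"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
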