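test_that("deterministic extremes yield two disjoint triangles", {
  sim <- generate_planted_pin(planted_spec(c(3L, 3L), p_in = 1, p_out = 0,
                                           seed = 7))
  g <- sim$graph
  expect_length(pin_vertices(g), 6)
  expect_equal(nrow(pin_edges(g)), 6) # two complete triangles, no bridge
  expect_equal(n_clusters(sim$truth), 2)
  expect_equal(unname(lengths(sim$complexes)), c(3L, 3L))
  expect_equal(names(sim$annotations), c("F01", "F02"))
  expect_true(all(pin_edges(g)$weight == 1))
})

test_that("same seed reproduces bit-identical output; different seeds differ", {
  spec <- planted_spec(rep(10L, 3L), p_in = 0.6, p_out = 0.05,
                       fp_rate = 0.1, w_true = c(0.7, 1),
                       w_false = c(0.05, 0.3), seed = 11)
  a <- generate_planted_pin(spec)
  b <- generate_planted_pin(spec)
  expect_identical(pin_edges(a$graph), pin_edges(b$graph))
  spec2 <- spec; spec2$seed <- 12L
  expect_false(identical(pin_edges(a$graph),
                         pin_edges(generate_planted_pin(spec2)$graph)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_planted_pin(planted_spec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("realized edge counts stay within binomial three-sigma bounds", {
  spec <- planted_spec(rep(20L, 4L), p_in = 0.9, p_out = 0.02, seed = 1)
  sim <- generate_planted_pin(spec)
  n_in_pairs <- 4 * choose(20, 2)
  n_out_pairs <- choose(80, 2) - n_in_pairs
  m <- nrow(pin_edges(sim$graph))
  mu <- n_in_pairs * 0.9 + n_out_pairs * 0.02
  sigma <- sqrt(n_in_pairs * 0.9 * 0.1 + n_out_pairs * 0.02 * 0.98)
  expect_lt(abs(m - mu), 3 * sigma)
})

test_that("spurious edges are inter-community, at the requested rate and weights", {
  spec <- planted_spec(rep(10L, 4L), p_in = 0.8, p_out = 0, fp_rate = 0.2,
                       w_true = c(0.9, 1), w_false = c(0.1, 0.2), seed = 3)
  sim <- generate_planted_pin(spec)
  e <- pin_edges(sim$graph)
  comm_of <- sub("_.*", "", e$from)
  comm_to <- sub("_.*", "", e$to)
  inter <- comm_of != comm_to
  # with p_out = 0 every inter-community edge is an injected false positive
  expect_true(all(e$weight[inter] >= 0.1 & e$weight[inter] <= 0.2))
  expect_true(all(e$weight[!inter] >= 0.9))
  expect_equal(sum(inter), round(0.2 * sum(!inter)))
  expect_equal(sim$manifest$n_false_edges, sum(inter))
})

test_that("spec validation rejects bad probabilities, ranges and sizes", {
  expect_error(planted_spec(p_in = 1.2), "p_in")
  expect_error(planted_spec(p_out = -0.1), "p_out")
  expect_error(planted_spec(fp_rate = 2), "fp_rate")
  expect_error(planted_spec(w_true = c(0.8, 0.2)), "w_true")
  expect_error(planted_spec(community_sizes = integer(0)), "community_sizes")
  expect_error(generate_planted_pin(list()), "planted_spec")
})

test_that("disjoint cliques are recovered perfectly by the full pipeline", {
  res <- recovery_experiment(planted_spec(rep(8L, 4L), p_in = 1, p_out = 0,
                                          seed = 1),
                             mu = 0.5, n_seeds = 3)
  expect_true(all(res$per_seed$sensitivity == 1))
  expect_true(all(res$per_seed$specificity == 1))
  expect_true(all(res$per_seed$k == 4))
})

test_that("recovery collapses when structure is removed (p_in = p_out)", {
  structured <- recovery_experiment(
    planted_spec(rep(12L, 4L), p_in = 0.8, p_out = 0.05, seed = 1),
    mu = 0.5, n_seeds = 5)
  flat <- recovery_experiment(
    planted_spec(rep(12L, 4L), p_in = 0.25, p_out = 0.25, seed = 1),
    mu = 0.5, n_seeds = 5)
  expect_gt(mean(structured$per_seed$f_score), mean(flat$per_seed$f_score))
})

test_that("reliability weights help on noisy graphs (weighted vs flattened)", {
  # spurious edges with low reliability: clustering the weighted graph
  # should match the planted communities at least as well, on average, as
  # clustering the same topology with weights flattened to 1
  f_w <- f_u <- numeric(6)
  for (s in seq_along(f_w)) {
    sim <- generate_planted_pin(planted_spec(
      rep(12L, 4L), p_in = 0.75, p_out = 0, fp_rate = 0.35,
      w_true = c(0.85, 1), w_false = c(0.05, 0.2), seed = 100 + s))
    e <- pin_edges(sim$graph)
    flat <- pin_graph(data.frame(from = e$from, to = e$to),
                      vertices = pin_vertices(sim$graph))
    f_w[s] <- complex_match_stats(facpin_cluster(sim$graph, 0.5),
                                  sim$complexes)$f_score
    f_u[s] <- complex_match_stats(facpin_cluster(flat, 0.5),
                                  sim$complexes)$f_score
  }
  expect_gte(mean(f_w), mean(f_u)) # soft premise of the weighted criterion
})

test_that("fixture writer emits the four files plus a manifest", {
  dir <- withr::local_tempdir()
  sim <- generate_planted_pin(planted_spec(c(4L, 4L), p_in = 1, p_out = 0,
                                           seed = 2))
  write_planted_fixtures(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("edges.tsv", "truth.tsv", "complexes.tsv", "annotations.tsv",
           "manifest.json")))))
  g2 <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(pin_edges(g2)[c("from", "to")],
               pin_edges(sim$graph)[c("from", "to")])
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2)
  expect_equal(man$n_vertices, 8)
})
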