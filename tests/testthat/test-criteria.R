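test_that("relative clustering value matches hand-derived toy values", {
  g <- toy6_graph()
  expect_equal(relative_clustering_value(g, "a", "b"), 1.0)
  expect_equal(relative_clustering_value(g, "c", "d"), 0.5)
  # defined for non-edge pairs too
  expect_equal(relative_clustering_value(g, "a", "d"), 1 / 3)
  expect_error(relative_clustering_value(g, "a", "a"), "distinct")
  expect_error(relative_clustering_value(g, "a", "zz"), "unknown vertex")
})

test_that("a pendant vertex has maximal clustering value toward its neighbor", {
  g <- pin_graph(data.frame(from = c("p", "v", "v"), to = c("v", "x", "y")))
  expect_equal(relative_clustering_value(g, "p", "v"), 1.0)
  # ...and the hub's value toward the pendant is smaller: asymmetry witness
  expect_lt(relative_clustering_value(g, "v", "p"), 1.0)
})

test_that("weighted premetric follows the self-weight convention on a triangle", {
  wt <- pin_graph(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                             weight = c(0.5, 1, 1)))
  # (1*0.5 + 0.5*1 + 1*1) / (1 + 0.5 + 1)
  expect_equal(relative_clustering_value(wt, "a", "b"), 0.8)
  # strict edges-only reading drops both endpoint self-terms
  expect_equal(relative_clustering_value(wt, "a", "b", strict_eq10 = TRUE),
               (1 * 1) / (0.5 + 1))
})

test_that("weighted premetric equals the set-based oracle on unit-weight graphs", {
  for (seed in 1:20) {
    n <- 5 + (seed %% 8)
    edges <- random_edge_table(n, 0.35, seed)
    g <- pin_graph(edges, vertices = sprintf("v%02d", 1:n))
    verts <- pin_vertices(g)
    for (u in verts) for (v in verts) {
      if (u != v) {
        expect_equal(relative_clustering_value(g, u, v),
                     oracle_rcv_unweighted(edges, u, v),
                     info = sprintf("seed %d pair %s->%s", seed, u, v))
      }
    }
  }
})

test_that("weighted premetric equals a term-by-term oracle on weighted graphs", {
  for (seed in 1:8) {
    edges <- random_edge_table(7, 0.5, seed, weighted = TRUE)
    g <- pin_graph(edges, vertices = sprintf("v%02d", 1:7))
    for (u in pin_vertices(g)) for (v in pin_vertices(g)) {
      if (u != v) {
        expect_equal(relative_clustering_value(g, u, v),
                     oracle_rcv_weighted(edges, u, v),
                     info = sprintf("seed %d pair %s->%s", seed, u, v))
      }
    }
  }
})

test_that("premetric is bounded in [0,1] and monotone in augmented-neighborhood size", {
  for (seed in 21:30) {
    g <- random_unit_graph(10, 0.4, seed, weighted = (seed %% 2 == 0))
    verts <- pin_vertices(g)
    deg <- pin_degree(g)
    for (u in verts) for (v in verts) {
      if (u == v) next
      r_uv <- relative_clustering_value(g, u, v)
      expect_gte(r_uv, 0)
      expect_lte(r_uv, 1)
      # |Nu+| <= |Nv+| forces R(u->v) >= R(v->u) on unit weights
      if (seed %% 2 == 1 && deg[u] <= deg[v]) {
        expect_gte(r_uv, relative_clustering_value(g, v, u))
      }
    }
  }
})

test_that("edge clustering value matches hand values and is symmetric", {
  g <- toy6_graph()
  expect_equal(edge_clustering_value(g, "a", "b"), 0.25)
  expect_equal(edge_clustering_value(g, "c", "d"), 0)
  for (seed in 1:3) {
    gr <- random_unit_graph(8, 0.5, seed, weighted = TRUE)
    verts <- pin_vertices(gr)
    pairs <- utils::combn(verts, 2)
    for (i in seq_len(ncol(pairs))) {
      expect_equal(edge_clustering_value(gr, pairs[1, i], pairs[2, i]),
                   edge_clustering_value(gr, pairs[2, i], pairs[1, i]))
    }
  }
})

test_that("triangle coefficient uses the min-degree denominator with a total guard", {
  g <- toy6_graph()
  expect_equal(edge_clustering_coefficient3(g, "a", "b"), 1.0)
  expect_equal(edge_clustering_coefficient3(g, "c", "d"), 0.0)
  path2 <- pin_graph(data.frame(from = "u", to = "v"))
  expect_equal(edge_clustering_coefficient3(path2, "u", "v"), 0) # degenerate
  expect_error(edge_clustering_coefficient3(g, "a", "d"), "not an edge")
})

test_that("local betweenness is 100 on bridges and decreases with shared neighbors", {
  g <- toy6_graph()
  expect_equal(local_edge_betweenness(g, "c", "d"), 100)
  expect_equal(local_edge_betweenness(g, "a", "b"), 50)
  k4 <- pin_graph(clique_graph(c("w", "x", "y", "z")))
  expect_equal(local_edge_betweenness(k4, "w", "x"), 100 / 3)
  expect_error(local_edge_betweenness(g, "a", "d"), "not an edge")
  # strictly decreasing in the common-neighbor count
  lambda <- vapply(0:5, function(s) 100 / (s + 1), numeric(1))
  expect_true(all(diff(lambda) < 0))
})

test_that("merge test applies the strict threshold and the asymmetry comparison", {
  g <- toy6_graph()
  expect_true(merge_test(g, "a", "c", mu = 1))   # R=1 > 0.5, 1 >= 3/4
  expect_false(merge_test(g, "c", "d", mu = 1))  # R=0.5 is not > 0.5
  expect_true(merge_test(g, "c", "d", mu = 0.99))
  # near the top of the mu range only exact-1 values can pass
  expect_false(merge_test(g, "c", "d", mu = 1.99))
  expect_true(merge_test(g, "a", "c", mu = 1.99))
  expect_error(merge_test(g, "a", "c", mu = 2), "mu")
  expect_error(merge_test(g, "a", "c", mu = -0.1), "mu")
})
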