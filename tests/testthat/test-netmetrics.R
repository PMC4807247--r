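test_that("degree records count replies and thread creations separately", {
  g <- graph_from_pairs(1, 2, n = 2)  # single edge a->b
  dr <- degree_records(g)
  expect_equal(dr$in_degree, c(0, 1))
  expect_equal(dr$out_degree, c(1, 0))
  # toy conversation graph, hand-counted (non-loop edges B->A, C->B, A->B, B->A)
  co <- make_toy_corpus()
  dr2 <- degree_records(build_conversation_graph(co))
  expect_equal(dr2$node, c("A", "B", "C"))
  expect_equal(dr2$in_degree, c(2, 2, 0))
  expect_equal(dr2$out_degree, c(1, 2, 1))
  expect_equal(dr2$n_threads_created, c(1, 1, 1))
  # handshake identity
  expect_equal(sum(dr2$in_degree), sum(dr2$out_degree))
  expect_equal(sum(dr2$in_degree), 4)
})

test_that("density uses the carried multi-edge count without self-loops", {
  g <- graph_from_pairs(c(1, 1, 2, 2), c(2, 2, 1, 2), n = 3)
  # edges: a->b x2, b->a, b->b(loop dropped): m = 3, n = 3
  expect_equal(graph_density(g), 3 / 6)
  expect_error(graph_density(graph_from_pairs(integer(), integer(), n = 1)),
               "at least 2")
  # complete directed graph -> 1
  k4 <- igraph::make_full_graph(4, directed = TRUE)
  expect_equal(graph_density(k4), 1)
  # undirected convention
  u <- igraph::make_ring(4)
  expect_equal(graph_density(u), 2 * 4 / (4 * 3))
})

test_that("reciprocity is the mutual-edge share on the simple projection", {
  expect_equal(as.numeric(graph_reciprocity(graph_from_pairs(c(1, 2), c(2, 1), n = 2))), 1)
  g <- graph_from_pairs(c(1, 2, 3), c(2, 3, 2), n = 3)  # a->b, b->c, c->b
  expect_equal(as.numeric(graph_reciprocity(g)), 2 / 3)
  # multiplicity must not inflate it
  g2 <- graph_from_pairs(c(1, 1, 1, 2), c(2, 2, 2, 1), n = 2)
  expect_equal(as.numeric(graph_reciprocity(g2)), 1)
  expect_error(graph_reciprocity(graph_from_pairs(c(1), c(1), n = 1)), "edgeless")
})

test_that("clustering and path statistics match hand values on small graphs", {
  tri <- igraph::make_full_graph(3, directed = FALSE)
  expect_equal(graph_clustering(tri), 1)
  path4 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)
  expect_equal(graph_clustering(path4), 0)
  # directed 3-cycle: every ordered pair reachable; distances 1 and 2
  cyc <- graph_from_pairs(c(1, 2, 3), c(2, 3, 1), n = 3)
  sp <- shortest_path_stats(cyc)
  expect_equal(sp$average_shortest_path, 1.5)
  expect_equal(sp$diameter, 2)
  expect_error(shortest_path_stats(graph_from_pairs(integer(), integer(), n = 2)),
               "reachable")
})

test_that("all metrics agree with brute-force oracles on small digraphs", {
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(3:6, 1)
      g <- random_digraph(n, p = stats::runif(1, 0.15, 0.6))
      if (igraph::ecount(g) == 0) next
      a <- simple_adj(g)
      expect_equal(graph_density(g), igraph::ecount(g) / (n * (n - 1)))
      expect_equal(as.numeric(graph_reciprocity(g)), reciprocity_oracle(g))
      expect_equal(graph_clustering(g), clustering_oracle(g))
      o <- asp_oracle(g)
      if (is.finite(o$asp)) {
        sp <- shortest_path_stats(g)
        expect_equal(sp$average_shortest_path, o$asp)
        expect_equal(sp$diameter, o$diameter)
      }
      expect_equal(unname(betweenness_centrality(g)), betweenness_oracle(g),
                   tolerance = 1e-12)
    }
  })
})

test_that("betweenness is extremal at a star center and exact on a path", {
  star <- graph_from_pairs(c(2, 3, 4, 1, 1, 1), c(1, 1, 1, 2, 3, 4), n = 4)
  b <- betweenness_centrality(star)
  expect_equal(unname(which.max(b)), 1)
  expect_equal(unname(b["a"]), 1)  # all 6 indirect ordered pairs pass through
  p4 <- graph_from_pairs(c(1, 2, 3), c(2, 3, 4), n = 4)
  expect_equal(unname(betweenness_centrality(p4, normalized = FALSE)),
               c(0, 2, 2, 0))
})

test_that("weak components partition and report the largest share", {
  g <- graph_from_pairs(c(1, 3), c(2, 4), n = 4)
  wc <- weak_components(g)
  expect_equal(wc$sizes, c(2L, 2L))
  co <- make_toy_corpus()
  wc2 <- weak_components(build_conversation_graph(co))
  expect_equal(wc2$n_components, 1)
  expect_equal(wc2$largest_fraction, 1)
})

test_that("adding an edge never increases ASP nor decreases density", {
  withr::with_seed(17, {
    for (i in 1:10) {
      g <- random_digraph(6, 0.3)
      if (igraph::ecount(g) == 0) next
      sp0 <- tryCatch(shortest_path_stats(g)$average_shortest_path,
                      error = function(e) NA)
      d0 <- graph_density(g)
      # add one absent edge
      a <- simple_adj(g)
      diag(a) <- TRUE
      absent <- which(!a, arr.ind = TRUE)
      if (nrow(absent) == 0) next
      pick <- absent[sample(nrow(absent), 1), ]
      g2 <- igraph::add_edges(g, pick)
      expect_gte(graph_density(g2), d0)
      if (!is.na(sp0)) {
        # mean over reachable pairs can only shrink when reachability is fixed;
        # with new reachable pairs the monotone comparison is on the distance
        # matrix itself
        d1 <- igraph::distances(igraph::simplify(g), mode = "out")
        d2 <- igraph::distances(igraph::simplify(g2), mode = "out")
        expect_true(all(d2 <= d1))
      }
    }
  })
})

test_that("discrete power-law fit recovers known exponents", {
  # continuous closed form on a tiny hand sample: alpha = 1 + n / sum(log(x/0.5))
  x <- c(1, 2, 4, 8, 16, 1, 2, 1, 3, 5)
  fit <- fit_power_law(x, xmin = 1, method = "continuous")
  expect_equal(fit$alpha, 1 + 10 / sum(log(x / 0.5)))
  # degenerate inputs
  expect_error(fit_power_law(rep(1, 20)), "constant")
  expect_error(fit_power_law(c(1, 2, 3)), "at least 10")
  # simulated truth alpha = 2.5 at n = 1e5
  x2 <- withr::with_seed(12, rpowerlaw(1e5, 2.5, 1))
  fit2 <- fit_power_law(x2)
  expect_lt(abs(fit2$alpha - 2.5), 0.05)
  expect_gte(fit2$xmin, 1)
  # deterministic for fixed input
  fit3 <- fit_power_law(x2)
  expect_identical(fit2$alpha, fit3$alpha)
})

test_that("power-law estimator bias shrinks with sample size and matches igraph", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    est <- vapply(1:3, function(s) {
      x <- withr::with_seed(n + s, rpowerlaw(n, 2.3, 1))
      fit_power_law(x, xmin = 1)$alpha
    }, numeric(1))
    abs(mean(est) - 2.3)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.02)
  expect_lt(errs[3], 0.03)
  # independent cross-check: igraph's plfit on the same sample, same xmin
  x <- withr::with_seed(7, rpowerlaw(2e4, 2.6, 1))
  ours <- fit_power_law(x, xmin = 1)$alpha
  theirs <- igraph::fit_power_law(x, xmin = 1, implementation = "plfit")$alpha
  expect_lt(abs(ours - theirs), 0.02)
})

test_that("network_summary assembles the comparison row with scalings", {
  co <- make_toy_corpus()
  g <- strip_self_loops(build_conversation_graph(co))
  ns <- network_summary(g, "toy")
  expect_equal(ns$n_edges, 4)
  expect_equal(ns$density_1e5, graph_density(g) * 1e5)
  expect_equal(ns$reciprocity_1e2, as.numeric(graph_reciprocity(g)) * 100)
  tab <- summary_table(list(ns))
  expect_equal(tab$edges, 4)
  expect_equal(tab$clustering_1e2, 100 * ns$clustering)
})
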