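test_that("the member feature table joins topology and language by hand", {
  co <- make_toy_corpus()
  lex <- toy_lexicon()
  g <- build_conversation_graph(co)
  ft <- member_feature_table(co, g, lex)
  expect_equal(nrow(ft), 3)
  fs <- attr(ft, "feature_sets")
  expect_length(fs$topological, 6)
  expect_length(fs$linguistic, 13)
  expect_equal(ncol(ft), 20)  # member id + 19 features
  # hand-checked topology (non-loop edges B->A, C->B, A->B, B->A)
  expect_equal(ft$in_degree[ft$member == "A"], 2)
  expect_equal(ft$out_degree[ft$member == "B"], 2)
  expect_equal(ft$n_threads_created, c(1, 1, 1))
  # C reaches B (1 hop) and A (2 hops): per-node ASP 1.5
  expect_equal(ft$asp[ft$member == "C"], 1.5)
  # hand-checked language: A posted "i feel sad" + "" -> WC 3, sad rate 100/3
  expect_equal(ft$word_count[ft$member == "A"], 3)
  expect_equal(ft$negemo[ft$member == "A"], 100 / 3)
  # no negative values anywhere
  expect_true(all(as.matrix(ft[, -1]) >= 0, na.rm = TRUE))
})

test_that("members with no reachable nodes get missing ASP, not zero", {
  th <- data.frame(thread_id = c("t1", "t2"), initiator = c("A", "B"),
                   created_time = 1:2, title = c("", ""))
  ms <- data.frame(message_id = c("m1", "m2"), thread_id = c("t1", "t2"),
                   author = c("A", "B"), timestamp = c(1L, 1L),
                   reply_to = c(NA, NA), stringsAsFactors = FALSE)
  ms$tokens <- list(c("i"), c("you"))
  co <- forum_corpus(th, ms)
  ft <- member_feature_table(co, build_conversation_graph(co), toy_lexicon())
  expect_true(all(is.na(ft$asp)))
  expect_equal(ft$in_degree, c(0, 0))
})

test_that("spearman_matrix matches a rank-then-Pearson oracle and is well formed", {
  withr::with_seed(8, {
    tab <- data.frame(a = rnorm(6), b = rnorm(6), c = sample(1:3, 6, TRUE),
                      d = rpowerlaw(6, 2.5))
  })
  sm <- spearman_matrix(tab)
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(sm$rho[i, j], spearman_oracle(tab[[i]], tab[[j]]),
                 tolerance = 1e-12)
  }
  # perfectly reversed ranks -> -1
  rev5 <- data.frame(x = 1:5, y = 5:1)
  expect_equal(spearman_matrix(rev5)$rho["x", "y"], -1)
  # constant column flagged, not zeroed
  cst <- data.frame(x = 1:6, y = rep(2, 6))
  smc <- spearman_matrix(cst)
  expect_equal(smc$flagged, "y")
  expect_true(is.na(smc$rho["x", "y"]))
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(21, {
    x <- rpowerlaw(50, 2.2) + stats::runif(50)
    y <- rnorm(50)
  })
  r0 <- spearman_matrix(data.frame(x, y))$rho["x", "y"]
  r_log <- spearman_matrix(data.frame(x = log(x), y))$rho["x", "y"]
  r_exp <- spearman_matrix(data.frame(x, y = exp(y)))$rho["x", "y"]
  expect_equal(r0, r_log)
  expect_equal(r0, r_exp)
})

test_that("pairwise deletion drops undefined ASP rows per pair only", {
  tab <- data.frame(asp = c(1, 2, NA, 4, 5, NA), z = c(2, 4, 6, 8, 10, 12),
                    w = c(1, 1, 2, 2, 3, 3))
  sm <- spearman_matrix(tab)
  expect_equal(sm$n["asp", "z"], 4)
  expect_equal(sm$n["z", "w"], 6)
  expect_equal(sm$rho["asp", "z"], spearman_oracle(tab$asp, tab$z))
})

test_that("affect comparison reports both t-test conventions", {
  pr <- data.frame(posemo = c(2, 3, 4, 5), negemo = c(4, 5, 6, 9))
  ac <- affect_comparison(pr)
  expect_equal(ac$n, 4)
  expect_equal(unname(ac$mean), c(3.5, 6))
  # hand-computed pooled two-sample t: means 3.5/6, var 5/3 and 14/3
  sp2 <- (3 * 5 / 3 + 3 * 14 / 3) / 6
  t_hand <- (6 - 3.5) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(ac$pooled$statistic, t_hand)
  expect_equal(ac$pooled$df, 6)
  # identical columns -> t = 0 under both conventions
  same <- data.frame(posemo = c(1, 2, 3), negemo = c(1, 2, 3))
  ac0 <- affect_comparison(same)
  expect_equal(ac0$welch$statistic, 0)
  expect_equal(ac0$pooled$statistic, 0)
  expect_error(affect_comparison(data.frame(posemo = 1, negemo = 1)), "at least 2")
})

test_that("the affect test detects an implanted negative excess on generated text", {
  co <- generate_corpus(generator_params(n_members = 250, n_threads = 200,
                                         deleted_fraction = 0, seed = 6))
  ac <- affect_comparison(member_profiles(co, toy_lexicon()))
  # generator implants negemo mixture weight 1.6x posemo
  expect_gt(ac$mean["negemo"], ac$mean["posemo"])
  expect_gt(ac$welch$statistic, 2)
  expect_lt(ac$welch$p_value, 0.05)
})

test_that("binned mean curves handle flat, monotone and hump-shaped relations", {
  expect_error(binned_mean_curve(1:5, 1:5, n_bins = 10), "fewer points")
  x <- 1:200
  flat <- binned_mean_curve(x, rep(3, 200), n_bins = 10)
  expect_true(all(flat$curve$y_mean == 3))
  mono <- binned_mean_curve(x, x, n_bins = 10)
  expect_true(all(diff(mono$curve$y_mean) > 0))
  expect_equal(mono$turning_bin, nrow(mono$curve))
  # hump with known turning point at x = 120 (bin 12 of 20)
  y <- -(x - 120)^2
  hump <- binned_mean_curve(x, y, n_bins = 20)
  expect_equal(hump$turning_bin, 12)
  expect_equal(sum(hump$curve$n), 200)
  # equal-occupancy bins under a heavy-tailed x
  withr::with_seed(3, xh <- rpowerlaw(500, 2.1))
  bc <- binned_mean_curve(xh, rnorm(500), n_bins = 10, log_x = TRUE)
  expect_true(all(bc$curve$n >= 1))
  expect_equal(sum(bc$curve$n), 500)
})

test_that("implanted activity-length coupling appears in the recovered correlation", {
  rho_at <- function(coupling, seed) {
    co <- generate_corpus(generator_params(
      n_members = 250, n_threads = 200, deleted_fraction = 0,
      length_coupling = coupling, seed = seed))
    ft <- member_feature_table(co, build_conversation_graph(co), toy_lexicon())
    spearman_matrix(ft[, c("out_degree", "word_count")])$rho["out_degree", "word_count"]
  }
  r0 <- mean(vapply(1:2, function(s) rho_at(0, s), numeric(1)))
  r1 <- mean(vapply(1:2, function(s) rho_at(1.2, s), numeric(1)))
  expect_gt(r0, 0)      # more messages already mean more words
  expect_gt(r1, r0)     # the implanted coupling strengthens the association
})

test_that("member universe mismatches are reported", {
  co <- make_toy_corpus()
  g <- igraph::make_empty_graph(1, directed = TRUE)
  igraph::V(g)$name <- "A"
  expect_error(member_feature_table(co, g, toy_lexicon()), "universe mismatch")
})
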