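#' Member-level feature table: topology joined with language
#'
#' One row per member with available text, joining six topological
#' properties measured on the conversation graph (in-degree, out-degree,
#' number of threads created, per-node average shortest path length over the
#' member's reachable set, normalized betweenness, local clustering on the
#' undirected projection) with thirteen linguistic properties from the
#' member's pooled messages (word count, the seven main-category occurrence
#' rates, positive and negative emotion rates, and first-/second-/
#' third-person pronoun rates). Members who can reach no other node have
#' `asp = NA` (missing, never zero).
#'
#' @param corpus a `forum_corpus`.
#' @param graph the conversation graph built from the same corpus
#'   ([build_conversation_graph()]); self-loops may still be present.
#' @param lexicon a `liwc_lexicon`.
#' @return A data.frame of class `member_feature_table` with attribute
#'   `feature_sets` naming the topological and linguistic columns.
#' @export
member_feature_table <- function(corpus, graph, lexicon) {
  profs <- member_profiles(corpus, lexicon)
  nodes <- igraph::V(graph)$name
  missing <- setdiff(profs$unit, nodes)
  if (length(missing)) {
    stop("member universe mismatch: ", missing[1], " has text but no node")
  }
  dr <- degree_records(graph)
  gs <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  d <- igraph::distances(gs, mode = "out")
  diag(d) <- Inf
  asp_node <- apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r)) mean(r) else NA_real_
  })
  btw <- betweenness_centrality(graph, normalized = TRUE)
  u <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"),
                        remove.multiple = TRUE, remove.loops = TRUE)
  cc <- igraph::transitivity(u, type = "local", isolates = "zero")
  names(cc) <- igraph::V(u)$name
  idx <- match(profs$unit, dr$node)
  topo_cols <- c("in_degree", "out_degree", "n_threads_created", "asp",
                 "betweenness", "clustering")
  ling_cols <- c("word_count", main_categories(), "posemo", "negemo",
                 "first_person", "second_person", "third_person")
  out <- data.frame(
    member = profs$unit,
    in_degree = dr$in_degree[idx],
    out_degree = dr$out_degree[idx],
    n_threads_created = dr$n_threads_created[idx],
    asp = unname(asp_node[match(profs$unit, nodes)]),
    betweenness = unname(btw[profs$unit]),
    clustering = unname(cc[profs$unit]),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, profs[, ling_cols])
  attr(out, "feature_sets") <- list(topological = topo_cols, linguistic = ling_cols)
  class(out) <- c("member_feature_table", "data.frame")
  out
}

#' Spearman rank-correlation matrix of member features
#'
#' Rank correlation (average ranks on ties) over all pairs of numeric
#' feature columns, using pairwise-complete observations so members with
#' undefined per-node path length are dropped per pair, not listwise.
#' Constant columns have undefined correlations; they are flagged and their
#' entries set to `NA` rather than silently zeroed.
#'
#' @param table a [member_feature_table()] or any data.frame of numeric
#'   columns (non-numeric columns are ignored).
#' @return A list of class `spearman_matrix`: `rho` (symmetric,
#'   unit-diagonal), `n` (pairwise sample sizes), `flagged` (constant
#'   columns).
#' @export
spearman_matrix <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least two numeric columns")
  complete_n <- vapply(num, function(c) sum(!is.na(c)), integer(1))
  if (any(complete_n < 3)) stop("need at least 3 observations per column")
  m <- as.matrix(num)
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  flagged <- names(num)[vapply(num, function(c) {
    v <- c[!is.na(c)]
    length(unique(v)) < 2
  }, logical(1))]
  rho[flagged, ] <- NA_real_
  rho[, flagged] <- NA_real_
  diag(rho) <- 1
  nn <- crossprod(!is.na(m))
  structure(list(rho = rho, n = nn, flagged = flagged),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman correlation matrix over", ncol(x$rho), "features\n")
  print(round(x$rho, 2))
  if (length(x$flagged)) cat("constant columns flagged:",
                             paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Compare positive and negative affect rates
#'
#' Among members using both positive and negative emotion words, compares
#' the mean occurrence rates of the two categories. The motivating analysis
#' prints a t statistic whose degrees of freedom match neither the paired
#' nor the pooled two-sample convention exactly, so both two-sample
#' conventions are reported: Welch (unequal variance, the headline) and
#' pooled variance.
#'
#' @param profiles data.frame from [member_profiles()].
#' @return A list of class `affect_comparison`: per-category `mean` and
#'   `sd`, `n`, and for each convention the `statistic`, `df`, `p_value`.
#' @export
affect_comparison <- function(profiles) {
  both <- profiles[profiles$posemo > 0 & profiles$negemo > 0, , drop = FALSE]
  if (nrow(both) < 2) stop("need at least 2 members using both affect categories")
  pos <- both$posemo
  neg <- both$negemo
  welch <- stats::t.test(neg, pos, var.equal = FALSE)
  pooled <- stats::t.test(neg, pos, var.equal = TRUE)
  structure(list(
    n = nrow(both),
    mean = c(posemo = mean(pos), negemo = mean(neg)),
    sd = c(posemo = stats::sd(pos), negemo = stats::sd(neg)),
    welch = list(statistic = unname(welch$statistic),
                 df = unname(welch$parameter), p_value = welch$p.value),
    pooled = list(statistic = unname(pooled$statistic),
                  df = unname(pooled$parameter), p_value = pooled$p.value)
  ), class = "affect_comparison")
}

#' @export
print.affect_comparison <- function(x, ...) {
  cat(sprintf("Affect comparison on %d members using both categories\n", x$n))
  cat(sprintf("  positive: mean %.2f (SD %.2f)   negative: mean %.2f (SD %.2f)\n",
              x$mean["posemo"], x$sd["posemo"], x$mean["negemo"], x$sd["negemo"]))
  cat(sprintf("  Welch:  t(%.1f) = %.2f, p = %.3g\n",
              x$welch$df, x$welch$statistic, x$welch$p_value))
  cat(sprintf("  pooled: t(%d) = %.2f, p = %.3g\n",
              as.integer(x$pooled$df), x$pooled$statistic, x$pooled$p_value))
  invisible(x)
}

#' Binned mean (convergence) curve of one feature over another
#'
#' Sorts members into equal-occupancy (quantile) bins of `x` -- heavy-tailed
#' topological features make equal-width bins degenerate -- optionally after
#' a log transform, and reports the mean of `y` per bin. The two-phase
#' (rise-then-fall) structure seen in convergence plots is operationalized
#' by the split of the bin-mean sequence into an increasing phase and a
#' decreasing phase with the fewest monotonicity violations.
#'
#' @param x,y paired numeric member columns (pairs with `NA` are dropped).
#' @param n_bins number of quantile bins (default 20).
#' @param log_x log-transform `x` before binning (`log(x + 1)` to keep
#'   zeros; Spearman-type analyses are unaffected by this monotone
#'   transform, only the bin placement is).
#' @return A list of class `binned_curve`: data.frame `curve` (`bin`,
#'   `x_mean`, `y_mean`, `n`), `turning_bin`, `phase_lengths`, and
#'   `n_points`.
#' @export
binned_mean_curve <- function(x, y, n_bins = 20, log_x = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < n_bins) stop("fewer points than bins")
  xs <- if (log_x) log(x + 1) else x
  br <- unique(stats::quantile(xs, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(xs, breaks = br, include.lowest = TRUE, labels = FALSE)
  xm <- tapply(xs, bin, mean)
  ym <- tapply(y, bin, mean)
  cnt <- tapply(y, bin, length)
  b <- as.numeric(ym)
  nb <- length(b)
  viol <- vapply(seq_len(nb), function(t) {
    up <- if (t > 1) sum(diff(b[1:t]) < 0) else 0
    down <- if (t < nb) sum(diff(b[t:nb]) > 0) else 0
    up + down
  }, numeric(1))
  turn <- which.min(viol)
  structure(list(
    curve = data.frame(bin = as.integer(names(ym)), x_mean = as.numeric(xm),
                       y_mean = b, n = as.integer(cnt)),
    turning_bin = turn,
    phase_lengths = c(increasing = turn, decreasing = nb - turn + 1L),
    n_points = length(x)
  ), class = "binned_curve")
}
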