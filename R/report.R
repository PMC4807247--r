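#' End-to-end analysis run
#'
#' Orchestrates the full pipeline on one corpus: corpus summary, linguistic
#' profiles and affect analysis, conversation and friendship graphs,
#' topology summaries for the observed network and each requested null
#' model, Bow-Tie comparison table, member feature table and Spearman
#' matrix. All randomness flows from explicit seeds in the configuration;
#' rerunning the same configuration reproduces every number.
#'
#' @param config a named list, or the path to a YAML file holding one, with
#'   fields:
#'   \describe{
#'     \item{corpus}{either `list(path = "corpus.jsonl")` or
#'       `list(generator = <args for [generator_params()]>)`;}
#'     \item{lexicon}{path to a lexicon file, or `"toy"` (default) for the
#'       shipped toy lexicon;}
#'     \item{models}{named list of null models to simulate; each element
#'       has a `model` field (`"er_directed"`, `"er_undirected"`,
#'       `"ba_directed"` or `"ws"`), its parameters (`n`, `m`, `seed_size`,
#'       `edges_per_step`, `k`, `p` as the model requires; when omitted,
#'       `n`/`m` default to the observed graph's), and `seeds`, a vector of
#'       RNG seeds (one simulated network per seed);}
#'     \item{out_dir}{optional directory; when given, every table is also
#'       written there as a delimited file;}
#'     \item{seed}{base seed recorded with the bundle.}
#'   }
#' @return A list of class `replynet_report` with elements
#'   `corpus_summary`, `tag_rate`, `affect_subgroups`, `affect_comparison`,
#'   `word_frequencies`, `network_table`, `bowtie_table`, `feature_table`,
#'   `spearman`, and `config`. Any stage failure aborts with the stage name.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  lex <- stage("lexicon", {
    if (is.null(config$lexicon) || identical(config$lexicon, "toy")) toy_lexicon()
    else load_lexicon(config$lexicon)
  })
  corpus <- stage("corpus", {
    cc <- config$corpus
    if (!is.null(cc$path)) read_corpus(cc$path)
    else if (!is.null(cc$generator)) generate_corpus(do.call(generator_params, cc$generator))
    else stop("config$corpus needs a 'path' or 'generator' field")
  })
  summ <- stage("corpus_summary", corpus_summary(corpus))
  profs <- stage("profiles", member_profiles(corpus, lex))
  tagr <- stage("tag_rate", corpus_tag_rate(corpus, lex))
  aff <- stage("affect_subgroups", affect_subgroups(profs))
  affcmp <- stage("affect_comparison", affect_comparison(profs))
  wfreq <- stage("word_frequencies", word_frequencies(corpus, top = 100))

  g <- stage("build_network", build_conversation_graph(corpus))
  gns <- stage("strip_self_loops", strip_self_loops(g))
  fr <- stage("friend_graph", to_friend_graph(g))
  summaries <- list(stage("metrics_observed", network_summary(gns, "observed")),
                    stage("metrics_friend", network_summary(fr, "observed_friend")))
  bows <- list(observed = stage("bowtie_observed", bowtie_decompose(gns)))

  for (nm in names(config$models)) {
    spec <- config$models[[nm]]
    seeds <- spec$seeds
    if (is.null(seeds)) seeds <- 1L
    for (s in seeds) {
      label <- if (length(seeds) > 1) paste0(nm, "_seed", s) else nm
      gg <- stage(paste0("simulate_", label), switch(
        spec$model,
        er_directed = er_graph(spec[["n"]] %||% igraph::vcount(gns),
                               spec[["m"]] %||% igraph::ecount(gns),
                               directed = TRUE, seed = s),
        er_undirected = er_graph(spec[["n"]] %||% igraph::vcount(fr),
                                 spec[["m"]] %||% igraph::ecount(fr),
                                 directed = FALSE, seed = s),
        ba_directed = ba_graph(spec[["n"]] %||% igraph::vcount(gns),
                               seed_size = spec[["seed_size"]] %||% 5,
                               edges_per_step = spec[["edges_per_step"]] %||% 7,
                               seed = s),
        ws = ws_graph(spec[["n"]] %||% igraph::vcount(fr), k = spec[["k"]] %||% 6,
                      p = spec[["p"]] %||% 0.45, seed = s),
        stop("unknown model: ", spec$model)
      ))
      summaries[[length(summaries) + 1L]] <-
        stage(paste0("metrics_", label), network_summary(gg, label))
      if (igraph::is_directed(gg)) {
        bows[[label]] <- stage(paste0("bowtie_", label), bowtie_decompose(gg))
      }
    }
  }

  feats <- stage("feature_table", member_feature_table(corpus, g, lex))
  sp <- stage("spearman", spearman_matrix(feats))

  out <- structure(list(
    corpus_summary = summ, tag_rate = tagr, affect_subgroups = aff,
    affect_comparison = affcmp, word_frequencies = wfreq,
    network_table = summary_table(summaries),
    bowtie_table = bowtie_table(bows, include_reference = TRUE),
    feature_table = feats, spearman = sp, config = config
  ), class = "replynet_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(out$network_table, "network_summary.tsv")
    wt(out$bowtie_table, "bowtie.tsv")
    wt(as.data.frame(feats), "member_features.tsv")
    utils::write.table(out$spearman$rho, file.path(config$out_dir, "spearman.tsv"),
                       sep = "\t", quote = FALSE)
    wt(wfreq, "word_frequencies.tsv")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.replynet_report <- function(x, ...) {
  cat("replynet analysis bundle\n")
  print(x$corpus_summary)
  cat(sprintf("  corpus tag rate: %.2f%%\n", x$tag_rate))
  cat("  networks analyzed:", paste(x$network_table$network, collapse = ", "), "\n")
  invisible(x)
}
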