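#' Published reference values for the motivating depression group
#'
#' The package is motivated by the analysis of a large Chinese
#' depression-support group ("MDD group") whose raw data are not publicly
#' deposited. The values published for that group, and for the comparison
#' networks it was contrasted with (a Myspace conversation network, the
#' MedHelp friendship network, a Java developer forum, and the Web graph),
#' are carried here as documented constants so that outputs of this package
#' can be laid side by side with them. None of these constants is ever
#' recomputed by the package; they are reference points only.
#'
#' @return A list with components:
#' \describe{
#'   \item{corpus}{scale of the group: threads, messages, members, max
#'     thread participants, words, members with available text, threads with
#'     available text.}
#'   \item{linguistic}{tag rate, affect-subgroup proportions and counts,
#'     positive/negative mean occurrence rates among members using both.}
#'   \item{network}{headline topology of the group's reply network and its
#'     undirected friendship projection (edge counts, density, diameter,
#'     reciprocity, clustering, average shortest path, power-law exponents,
#'     largest weak component), plus the published values for the comparison
#'     networks, on the published scales (densities x 1e-5; reciprocity and
#'     clustering x 1e-2).}
#'   \item{bowtie}{Bow-Tie class percentages for the group and the published
#'     comparison columns (Myspace, Java forum, Web, Erdos-Renyi,
#'     Barabasi-Albert).}
#' }
#' @export
mdd_reference <- function() {
  list(
    corpus = list(
      n_threads = 3700L, n_messages = 40357L, n_members = 5050L,
      max_participants = 276L, n_words = 2281678L,
      n_members_with_text = 5013L, n_threads_with_text = 3565L
    ),
    linguistic = list(
      tag_rate = 74.82, tagged_words = 1707151L, total_words = 2281678L,
      affect_subgroups = c(negative_only = 11.87, positive_only = 11.03,
                           both = 58.51, neither = 18.59),
      affect_counts = c(negative_only = 595L, positive_only = 553L,
                        both = 2933L, neither = 932L),
      posemo_mean = 4.06, posemo_sd = 2.67,
      negemo_mean = 4.48, negemo_sd = 2.99
    ),
    network = list(
      mdd = list(nodes = 5050L, edges = 36657L, components = 162L,
                 largest_wcc = 4881L, density_1e5 = 143.8, diameter = 10,
                 reciprocity_1e2 = 34.0, clustering_1e2 = 4.47, asp = 4.11,
                 alpha_in = 2.13, alpha_out = 2.20,
                 zero_indegree_pct = 36.03),
      mdd_friend = list(nodes = 5050L, edges = 17401L, density_1e5 = 136.5,
                        diameter = 11, clustering_1e2 = 4.47, asp = 3.80,
                        alpha = 2.29),
      er_directed = list(nodes = 5050L, edges = 36657L, density_1e5 = 143.8,
                         diameter = 8, reciprocity_1e2 = 0.08,
                         clustering_1e2 = 0.29, asp = 4.53),
      ba_directed = list(nodes = 5050L, edges = 36657L, density_1e5 = 138.6,
                         diameter = 11, reciprocity_1e2 = 0.03,
                         clustering_1e2 = 0.64, asp = 2.83,
                         alpha_in = 2.15, alpha_out = 3.01),
      myspace = list(nodes = 36459L, edges = 80675L, density_1e5 = 6.07,
                     diameter = 11, reciprocity_1e2 = 1.45,
                     clustering_1e2 = 0.031, asp = 5.14,
                     alpha_in = 2.65, alpha_out = 1.99),
      medhelp = list(nodes = 30915L, edges = 113273L, density_1e5 = 23.7,
                     clustering_1e2 = 3.1, asp = 3.81, alpha = 2.12),
      er_friend = list(nodes = 5050L, edges = 17401L, density_1e5 = 136.5,
                       diameter = 8, clustering_1e2 = 0.13, asp = 4.64),
      ws = list(nodes = 5050L, edges = 17401L, density_1e5 = 136.5,
                diameter = 8, clustering_1e2 = 1.19, asp = 4.69)
    ),
    bowtie = list(
      mdd = c(SCC = 54.53, IN = 29.27, OUT = 7.80, TENDRILS = 4.22,
              TUBES = 0.04, DISC = 4.22),
      myspace = c(SCC = 1.17, IN = 0, OUT = 81.50, TENDRILS = 0.027,
                  TUBES = 0, DISC = 17.30),
      java_forum = c(SCC = 12.30, IN = 54.90, OUT = 13.00, TENDRILS = 17.50,
                     TUBES = 0.40, DISC = 1.90),
      web = c(SCC = 27.70, IN = 21.20, OUT = 21.20, TENDRILS = 21.50,
              TUBES = 0.40, DISC = 8.00),
      er_directed = c(SCC = 99.91, IN = 0.04, OUT = 0.04, TENDRILS = 0,
                      TUBES = 0, DISC = 0.01),
      ba_directed = c(SCC = 0.10, IN = 98.10, OUT = 0, TENDRILS = 0.61,
                      TUBES = 0, DISC = 1.21)
    )
  )
}
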