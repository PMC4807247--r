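#' Parameters for the synthetic forum generator
#'
#' The generator emulates the structure of the motivating depression-support
#' group: a fixed member roster with heavy-tailed activity, threads whose
#' participant counts peak at two with a heavy tail up to a cap, reply
#' messages that either address the thread at large or a specific earlier
#' message, lognormal message lengths, and per-member category-mixture text
#' drawn from the toy lexicon (function words around half of all tokens,
#' more negative than positive affect words, first-person-dominant
#' pronouns, roughly a quarter of tokens outside the dictionary). A small
#' fraction of members are "deleted accounts": their messages keep their
#' place in the reply record but carry unavailable text.
#'
#' @param n_members number of members on the roster.
#' @param n_threads number of discussion threads.
#' @param participant_alpha power-law exponent of the (participants - 1)
#'   draw; mode of the participant count is forced to 2.
#' @param participant_cap maximum participants in one thread (the motivating
#'   group observed 276).
#' @param p_single probability a thread keeps a single participant.
#' @param activity_alpha Pareto exponent of member activity propensities.
#' @param reply_prob probability a reply targets a specific earlier message
#'   rather than the thread at large.
#' @param msg_geom_p geometric success probability; each replier posts
#'   `1 + Geom(msg_geom_p)` messages in a thread.
#' @param follow_up_prob probability a single-participant thread gets
#'   follow-up messages from its initiator.
#' @param msg_meanlog,msg_sdlog lognormal parameters of message token
#'   counts.
#' @param p_empty_message probability a message has zero tokens.
#' @param mixture_concentration Dirichlet-style concentration of per-member
#'   jitter around the base category mixture (larger = more homogeneous).
#' @param length_coupling exponent coupling a member's realized message
#'   volume to their message length (0 = none); implants a tunable
#'   monotone association between out-degree and word count by amplifying
#'   the deterministic part of the word count relative to per-message
#'   length noise.
#' @param deleted_fraction fraction of members with deleted accounts.
#' @param seed integer random seed.
#' @param preset `"custom"` or `"mdd-scale"`, the scale of the motivating
#'   group (5,050 members, 3,700 threads, about 40,000 messages).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_members = 200, n_threads = 150,
                             participant_alpha = 2.2, participant_cap = 276,
                             p_single = 0.08,
                             activity_alpha = 2.4,
                             reply_prob = 0.3,
                             msg_geom_p = 0.234,
                             follow_up_prob = 0.5,
                             msg_meanlog = 3.58, msg_sdlog = 1.0,
                             p_empty_message = 0.02,
                             mixture_concentration = 150,
                             length_coupling = 0,
                             deleted_fraction = 37 / 5050,
                             seed = 1L,
                             preset = c("custom", "mdd-scale")) {
  preset <- match.arg(preset)
  if (preset == "mdd-scale") {
    n_members <- 5050L
    n_threads <- 3700L
  }
  p <- list(n_members = as.integer(n_members), n_threads = as.integer(n_threads),
            participant_alpha = participant_alpha,
            participant_cap = as.integer(participant_cap),
            p_single = p_single, activity_alpha = activity_alpha,
            reply_prob = reply_prob, msg_geom_p = msg_geom_p,
            follow_up_prob = follow_up_prob,
            msg_meanlog = msg_meanlog, msg_sdlog = msg_sdlog,
            p_empty_message = p_empty_message,
            mixture_concentration = mixture_concentration,
            length_coupling = length_coupling,
            deleted_fraction = deleted_fraction,
            seed = as.integer(seed), preset = preset)
  if (p$n_members < 1) stop("n_members must be >= 1")
  if (p$n_threads < 0) stop("n_threads must be >= 0")
  probs <- c(p$p_single, p$reply_prob, p$msg_geom_p, p$follow_up_prob,
             p$p_empty_message, p$deleted_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$participant_alpha <= 1) stop("participant_alpha must exceed 1")
  if (p$participant_cap < 1) stop("participant_cap must be >= 1")
  structure(p, class = "generator_params")
}

# heavy-tailed discrete draw, xmin = 1 (standard continuous-inversion
# approximation of the zeta distribution)
rpowerlaw_discrete <- function(n, alpha, xmin = 1) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

# base token-pool mixture used by the generator; pools keyed by the toy
# lexicon's leaf categories plus an out-of-dictionary pool
base_token_mixture <- function() {
  c(first_person = 0.085, second_person = 0.015, third_person = 0.025,
    funct_other = 0.325,
    social = 0.030,
    posemo = 0.022, sad = 0.018, anx = 0.010, anger = 0.007,
    cogmech = 0.115, percept = 0.020, bio = 0.025, relativ = 0.053,
    unknown = 0.250)
}

# map toy-lexicon words into the generator's pools (a word's first direct
# label decides its pool)
generator_token_pools <- function(lexicon = toy_lexicon()) {
  h <- lexicon$hierarchy
  first_lab <- vapply(lexicon$entries, function(l) l[1], character(1))
  main_of <- vapply(first_lab, function(l) {
    cl <- category_closure(l, h)
    cl[length(cl)]
  }, character(1))
  pool <- character(length(first_lab))
  pool[first_lab %in% c("first_person")] <- "first_person"
  pool[first_lab %in% c("second_person")] <- "second_person"
  pool[first_lab %in% c("third_person")] <- "third_person"
  pool[main_of == "funct" & pool == ""] <- "funct_other"
  pool[first_lab == "posemo"] <- "posemo"
  pool[first_lab == "sad"] <- "sad"
  pool[first_lab == "anx"] <- "anx"
  pool[first_lab == "anger"] <- "anger"
  pool[main_of == "social" & pool == ""] <- "social"
  pool[main_of == "cogmech" & pool == ""] <- "cogmech"
  pool[main_of == "percept" & pool == ""] <- "percept"
  pool[main_of == "bio" & pool == ""] <- "bio"
  pool[main_of == "relativ" & pool == ""] <- "relativ"
  pools <- split(names(lexicon$entries), pool)
  pools$unknown <- sprintf("w%03d", 1:60)
  pools
}

#' Generate a synthetic forum corpus
#'
#' Deterministic for a fixed seed. See [generator_params()] for what the
#' generator emulates. The first message of every thread is the initiator's
#' opening post; replies either address the thread at large or a uniformly
#' chosen earlier message of the same thread.
#'
#' @param params a [generator_params()] object.
#' @return A [forum_corpus()].
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  nm <- params$n_members
  members <- sprintf("m%05d", seq_len(nm))
  # heavy-tailed activity propensity (continuous Pareto)
  w <- (1 - stats::runif(nm))^(-1 / (params$activity_alpha - 1))
  deleted <- rep(FALSE, nm)
  n_del <- round(params$deleted_fraction * nm)
  if (n_del > 0) deleted[sample.int(nm, n_del)] <- TRUE

  threads <- data.frame(thread_id = character(), initiator = character(),
                        created_time = integer(), title = character(),
                        stringsAsFactors = FALSE)
  msg_thread <- character(); msg_author <- integer()
  msg_ts <- integer(); msg_reply_idx <- integer()  # index into thread-local order
  th_ids <- sprintf("t%05d", seq_len(params$n_threads))
  th_init <- character(params$n_threads)
  msg_rows <- vector("list", params$n_threads)

  cap <- min(params$participant_cap, nm)
  for (t in seq_len(params$n_threads)) {
    init <- sample.int(nm, 1, prob = w)
    if (stats::runif(1) < params$p_single || nm == 1) {
      part <- integer()
    } else {
      x <- rpowerlaw_discrete(1, params$participant_alpha)
      p_count <- min(1 + x, cap)
      others <- setdiff(seq_len(nm), init)
      part <- others[sample.int(length(others), min(p_count - 1, length(others)),
                                prob = w[others])]
    }
    authors <- init
    if (length(part)) {
      n_each <- 1L + stats::rgeom(length(part), params$msg_geom_p)
      authors <- c(authors, rep(part, times = n_each))
    } else if (stats::runif(1) < params$follow_up_prob) {
      n_extra <- 1L + stats::rgeom(1, params$msg_geom_p)
      authors <- c(authors, rep(init, n_extra))
    }
    k <- length(authors)
    if (k > 1) {
      ord <- c(1L, 1L + sample.int(k - 1))  # opening post first, replies shuffled
      authors <- authors[ord]
    }
    # reply targets: position 1 is the opening post (no target)
    reply_idx <- rep(NA_integer_, k)
    if (k > 1) {
      targeted <- which(stats::runif(k - 1) < params$reply_prob) + 1L
      if (length(targeted)) {
        reply_idx[targeted] <- vapply(targeted, function(j) sample.int(j - 1L, 1),
                                      integer(1))
      }
    }
    th_init[t] <- members[init]
    msg_rows[[t]] <- list(authors = authors, reply_idx = reply_idx)
  }

  n_msgs_per_thread <- vapply(msg_rows, function(r) length(r$authors), integer(1))
  total_msgs <- sum(n_msgs_per_thread)
  message_id <- sprintf("s%07d", seq_len(total_msgs))
  thread_of <- rep(th_ids, times = n_msgs_per_thread)
  author_idx <- unlist(lapply(msg_rows, `[[`, "authors"), use.names = FALSE)
  ts <- unlist(lapply(n_msgs_per_thread, seq_len), use.names = FALSE)
  offset <- rep(c(0L, cumsum(n_msgs_per_thread))[seq_len(params$n_threads)],
                times = n_msgs_per_thread)
  reply_local <- unlist(lapply(msg_rows, `[[`, "reply_idx"), use.names = FALSE)
  reply_to <- ifelse(is.na(reply_local), NA_character_,
                     message_id[offset + reply_local])

  # message lengths: lognormal, optionally amplified by the member's realized
  # message volume so the out-degree/word-count association is tunable
  len_mult <- if (params$length_coupling != 0) {
    mcount <- tabulate(author_idx, nbins = nm)
    mult <- (1 + mcount)^params$length_coupling
    mult / mean(mult[mcount > 0])
  } else rep(1, nm)
  n_tok <- pmax(1L, as.integer(round(stats::rlnorm(
    total_msgs, meanlog = params$msg_meanlog + log(len_mult[author_idx]),
    sdlog = params$msg_sdlog))))
  n_tok[stats::runif(total_msgs) < params$p_empty_message] <- 0L

  # per-member category-mixture text from the toy lexicon's pools
  pools <- generator_token_pools()
  base <- base_token_mixture()
  base <- base[names(base) %in% names(pools)]
  base <- base / sum(base)
  conc <- params$mixture_concentration
  tokens <- vector("list", total_msgs)
  by_member <- split(seq_len(total_msgs), author_idx)
  for (mi_chr in names(by_member)) {
    mi <- as.integer(mi_chr)
    idx <- by_member[[mi_chr]]
    need <- n_tok[idx]
    tot <- sum(need)
    if (deleted[mi]) {
      tokens[idx] <- rep(list(NA), length(idx))
      next
    }
    if (tot == 0) {
      tokens[idx] <- rep(list(character()), length(idx))
      next
    }
    mix <- stats::rgamma(length(base), shape = conc * base)
    mix <- mix / sum(mix)
    pool_draw <- sample.int(length(base), tot, replace = TRUE, prob = mix)
    toks <- character(tot)
    for (pl in seq_along(base)) {
      sel <- pool_draw == pl
      np <- sum(sel)
      if (np) {
        p <- pools[[names(base)[pl]]]
        toks[sel] <- p[sample.int(length(p), np, replace = TRUE)]
      }
    }
    tokens[idx] <- split(toks, rep(seq_along(idx), times = need))[
      as.character(seq_along(idx))]
    tokens[idx][need == 0] <- list(character())
  }

  threads <- data.frame(thread_id = th_ids, initiator = th_init,
                        created_time = seq_len(params$n_threads),
                        title = paste("discussion", th_ids),
                        stringsAsFactors = FALSE)
  messages <- data.frame(message_id = message_id, thread_id = thread_of,
                         author = members[author_idx], timestamp = ts,
                         reply_to = reply_to, stringsAsFactors = FALSE)
  messages$tokens <- tokens
  forum_corpus(threads, messages, members = members)
}
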