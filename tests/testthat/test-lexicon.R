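local_lexicon_file <- function(lines, env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, f)
  f
}

test_that("load_lexicon parses, merges duplicates and validates labels", {
  f <- local_lexicon_file(c("glad\tposemo", "cry\tsad", "know\tinsight"))
  lex <- load_lexicon(f)
  expect_length(lex$entries, 3)
  expect_setequal(lex$closure[["cry"]], c("sad", "negemo", "affect"))
  # duplicate word under a different label: one entry, two labels
  f2 <- local_lexicon_file(c("warm\tposemo", "warm\tfeel"))
  lex2 <- load_lexicon(f2)
  expect_length(lex2$entries, 1)
  expect_setequal(lex2$entries[["warm"]], c("posemo", "feel"))
  expect_error(load_lexicon(local_lexicon_file("word\tnotacategory")),
               "unknown category label")
  expect_error(load_lexicon(local_lexicon_file(character())), "empty")
})

test_that("the shipped toy lexicon covers exactly the seven main categories", {
  lex <- toy_lexicon()
  reached <- sort(unique(unlist(lapply(lex$closure, function(cl) {
    cl[is.na(lex$hierarchy[cl])]
  }))))
  expect_setequal(reached, main_categories())
  expect_gt(length(lex$entries), 100)
})

test_that("tag_tokens rolls counts up the hierarchy and counts tagged tokens once", {
  lex <- toy_lexicon()
  z <- tag_tokens(character(), lex)
  expect_equal(z$word_count, 0)
  expect_true(all(z$counts == 0))
  # 10-token message, hand-counted: i(first) feel(feel) sad(sad) you(second)
  # warm(feel+posemo) w001(unknown) not(negate) cry(sad) the(article) know(insight)
  toks <- c("i", "feel", "sad", "you", "warm", "w001", "not", "cry", "the", "know")
  tg <- tag_tokens(toks, lex)
  expect_equal(tg$word_count, 10)
  expect_equal(tg$tagged_count, 9)          # all but w001; warm counts once
  expect_equal(unname(tg$counts["first_person"]), 1)
  expect_equal(unname(tg$counts["sad"]), 2)
  expect_equal(unname(tg$counts["negemo"]), 2)
  expect_equal(unname(tg$counts["affect"]), 3)   # sad, cry, warm(posemo)
  expect_equal(unname(tg$counts["percept"]), 2)  # feel, warm
  expect_equal(unname(tg$counts["funct"]), 4)    # i, you, not, the
  all_unknown <- tag_tokens(rep("zzz", 10), lex)
  expect_equal(all_unknown$tagged_count, 0)
  expect_equal(all_unknown$word_count, 10)
})

test_that("tag_tokens matches a naive per-token oracle on random inputs", {
  lex <- toy_lexicon()
  vocab <- c(names(lex$entries), sprintf("u%02d", 1:20))
  withr::with_seed(42, {
    for (i in 1:20) {
      toks <- sample(vocab, sample(0:80, 1), replace = TRUE)
      got <- tag_tokens(toks, lex)
      want <- tag_oracle(toks, lex)
      expect_equal(got$counts, want$counts)
      expect_equal(got$tagged_count, want$tagged_count)
    }
  })
})

test_that("roll-up conserves counts on a leaf-labeled lexicon", {
  f <- local_lexicon_file(c("glad\tposemo", "shiny\tposemo", "cry\tsad",
                            "fret\tanx", "fume\tanger"))
  lex <- load_lexicon(f)
  toks <- c("glad", "cry", "fret", "fume", "glad", "shiny", "cry")
  tg <- tag_tokens(toks, lex)
  expect_equal(unname(tg$counts["negemo"]),
               unname(tg$counts["anx"] + tg$counts["anger"] + tg$counts["sad"]))
  expect_equal(unname(tg$counts["affect"]),
               unname(tg$counts["posemo"] + tg$counts["negemo"]))
})

test_that("profiles pool a unit's messages and standardize to rates", {
  co <- make_toy_corpus()
  lex <- toy_lexicon()
  # single-message member: profile equals tag_tokens of that message
  pa <- profile_unit(co, lex, "A", type = "member")
  toks_a <- unlist(co$messages$tokens[co$messages$author == "A"])
  tg <- tag_tokens(toks_a, lex)
  expect_equal(pa$word_count, tg$word_count)
  expect_equal(pa$counts, tg$counts)
  expect_equal(unname(pa$rates["sad"]), 100 * tg$counts[["sad"]] / tg$word_count)
  # rates bounded and thread profiles work too
  pt <- profile_unit(co, lex, "t1", type = "thread")
  expect_true(all(pt$rates >= 0 & pt$rates <= 100))
  expect_error(profile_unit(co, lex, "nobody"), "unknown member")
  # 50-token pooled text with 20 function hits -> rate 40
  th <- data.frame(thread_id = "t", initiator = "M", created_time = 1, title = "")
  ms <- data.frame(message_id = "m1", thread_id = "t", author = "M",
                   timestamp = 1, reply_to = NA, stringsAsFactors = FALSE)
  ms$tokens <- list(c(rep("the", 20), rep("zzz", 30)))
  p <- profile_unit(forum_corpus(th, ms), lex, "M")
  expect_equal(unname(p$rates["funct"]), 40)
})

test_that("rate invariance: profiles ignore message concatenation order", {
  co <- generate_corpus(generator_params(n_members = 30, n_threads = 25,
                                         deleted_fraction = 0, seed = 9))
  lex <- toy_lexicon()
  pr1 <- member_profiles(co, lex)
  # permute message rows; pooled member rates must not change
  co2 <- co
  perm <- withr::with_seed(1, sample(nrow(co2$messages)))
  co2$messages <- co2$messages[perm, , drop = FALSE]
  pr2 <- member_profiles(co2, lex)
  pr2 <- pr2[match(pr1$unit, pr2$unit), ]
  expect_equal(pr1$funct, pr2$funct)
  expect_equal(pr1$word_count, pr2$word_count)
  expect_true(all(as.matrix(pr1[main_categories()]) <= 100))
})

test_that("corpus tag rate is the tagged share of all available tokens", {
  co <- make_toy_corpus()
  lex <- toy_lexicon()
  toks <- unlist(co$messages$tokens)
  expect_equal(corpus_tag_rate(co, lex),
               100 * sum(toks %in% names(lex$closure)) / length(toks))
  # saturation: lexicon covering every token -> 100
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(unique(toks), "time", sep = "\t"), f)
  expect_equal(corpus_tag_rate(co, load_lexicon(f)), 100)
})

test_that("affect subgroups partition members and match a brute-force pass", {
  # all-neither corner
  pr0 <- data.frame(posemo = c(0, 0), negemo = c(0, 0))
  expect_equal(unname(affect_subgroups(pr0)$percent), c(0, 0, 0, 100))
  # randomized profiles vs brute force
  withr::with_seed(5, {
    pr <- data.frame(posemo = sample(c(0, 0, 1.5, 3), 200, replace = TRUE),
                     negemo = sample(c(0, 2, 4), 200, replace = TRUE))
  })
  got <- affect_subgroups(pr)
  brute <- table(factor(apply(pr, 1, function(r) {
    if (r["negemo"] > 0 && r["posemo"] == 0) "negative_only"
    else if (r["posemo"] > 0 && r["negemo"] == 0) "positive_only"
    else if (r["posemo"] > 0) "both" else "neither"
  }), levels = c("negative_only", "positive_only", "both", "neither")))
  expect_equal(unname(got$counts), as.integer(brute))
  expect_equal(sum(got$percent), 100)
  expect_error(affect_subgroups(pr[0, ]), "no member profiles")
})

test_that("word frequencies rank available tokens in descending order", {
  expect_equal(nrow(word_frequencies(forum_corpus(
    data.frame(thread_id = character(), initiator = character(),
               created_time = integer(), title = character()),
    replynet:::empty_messages()))), 0)
  wf <- word_frequencies(make_toy_corpus())
  expect_true(all(diff(wf$count) <= 0))
  expect_equal(sum(wf$count), length(unlist(make_toy_corpus()$messages$tokens)))
})
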