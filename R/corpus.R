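#' Construct a forum corpus
#'
#' A `forum_corpus` is the raw conversational record of a threaded forum:
#' discussion threads, their messages, and the member roster. Each thread is
#' opened by an initiator; every message belongs to a thread, carries an
#' ordinal timestamp, and may reply to a specific earlier message in the same
#' thread (absent `reply_to` means the message is addressed to the thread at
#' large, i.e. to the initiator). Message text is stored pre-tokenized; a
#' message whose author deleted their account keeps its place in the record
#' (so the reply network is intact) but has unavailable text, encoded as a
#' single `NA` in its token slot.
#'
#' @param threads data.frame with columns `thread_id`, `initiator`,
#'   `created_time` (integer ordinal), `title`.
#' @param messages data.frame with columns `message_id`, `thread_id`,
#'   `author`, `timestamp` (integer ordinal), `reply_to` (`NA` when addressed
#'   to the thread at large), and `tokens`, a list column of character
#'   vectors (`NA` marks unavailable text).
#' @param members character vector of member ids; must contain every author
#'   and initiator. Defaults to exactly the posting members.
#' @param validate logical; run [validate_corpus()] on the result.
#' @return An object of class `forum_corpus`.
#' @seealso [read_corpus()], [write_corpus()], [generate_corpus()],
#'   [corpus_summary()]
#' @export
forum_corpus <- function(threads, messages, members = NULL, validate = TRUE) {
  threads <- as.data.frame(threads, stringsAsFactors = FALSE)
  messages <- as.data.frame(messages, stringsAsFactors = FALSE)
  if (nrow(messages) > 0 && !is.list(messages$tokens)) {
    messages$tokens <- as.list(messages$tokens)
  }
  posters <- unique(c(threads$initiator, messages$author))
  if (is.null(members)) members <- posters
  members <- sort(unique(as.character(members)))
  x <- structure(
    list(threads = threads, messages = messages, members = members),
    class = "forum_corpus"
  )
  if (validate) validate_corpus(x)
  x
}

#' Validate forum-corpus invariants
#'
#' Checks the structural invariants of the record: unique thread and message
#' ids; every message's thread exists; threads are opened by their initiator
#' (the earliest message in a thread is the initiator's); `reply_to` points
#' to an earlier message in the same thread; the member roster covers all
#' authors and initiators. Violations raise an error naming the offending
#' thread or message id.
#'
#' @param corpus a `forum_corpus`.
#' @return The corpus, invisibly.
#' @export
validate_corpus <- function(corpus) {
  th <- corpus$threads
  ms <- corpus$messages
  if (anyDuplicated(th$thread_id)) {
    stop("duplicate thread_id: ", th$thread_id[duplicated(th$thread_id)][1])
  }
  if (anyDuplicated(ms$message_id)) {
    stop("duplicate message_id: ", ms$message_id[duplicated(ms$message_id)][1])
  }
  bad <- setdiff(ms$thread_id, th$thread_id)
  if (length(bad)) {
    id <- ms$message_id[match(bad[1], ms$thread_id)]
    stop("message ", id, " references unknown thread ", bad[1])
  }
  posters <- unique(c(th$initiator, ms$author))
  missing_members <- setdiff(posters, corpus$members)
  if (length(missing_members)) {
    stop("member roster missing poster(s): ",
         paste(utils::head(missing_members, 3), collapse = ", "))
  }
  if (nrow(ms) > 0) {
    idx_by_thread <- split(seq_len(nrow(ms)), ms$thread_id)
    for (tid in names(idx_by_thread)) {
      sub <- ms[idx_by_thread[[tid]], , drop = FALSE]
      sub <- sub[order(sub$timestamp), , drop = FALSE]
      init <- th$initiator[match(tid, th$thread_id)]
      if (sub$author[1] != init) {
        stop("thread ", tid, ": first message ", sub$message_id[1],
             " not authored by initiator ", init)
      }
      rt <- sub$reply_to
      has_rt <- !is.na(rt)
      if (any(has_rt)) {
        idx <- match(rt[has_rt], sub$message_id)
        if (anyNA(idx)) {
          off <- sub$message_id[has_rt][is.na(idx)][1]
          stop("message ", off, " replies to a message outside thread ", tid)
        }
        if (any(sub$timestamp[idx] >= sub$timestamp[has_rt])) {
          off <- sub$message_id[has_rt][sub$timestamp[idx] >= sub$timestamp[has_rt]][1]
          stop("message ", off, " replies to a message not strictly earlier")
        }
      }
    }
  }
  invisible(corpus)
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat("<forum_corpus> ", nrow(x$threads), " threads, ",
      nrow(x$messages), " messages, ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' @export
all.equal.forum_corpus <- function(target, current, ...) {
  canon <- function(c) {
    ms <- c$messages[order(c$messages$message_id), , drop = FALSE]
    rownames(ms) <- NULL
    ms$tokens <- lapply(ms$tokens, function(t) if (length(t) == 1 && is.na(t)) NA else as.character(t))
    th <- c$threads[order(c$threads$thread_id), , drop = FALSE]
    rownames(th) <- NULL
    list(threads = th, messages = ms, members = sort(c$members))
  }
  all.equal(canon(target), canon(current), ...)
}

# TRUE for messages whose text survives (author not deleted)
text_available <- function(tokens) {
  !(length(tokens) == 1L && is.logical(tokens) && is.na(tokens))
}

#' Read a forum corpus from its line-record file
#'
#' The on-disk format is one JSON record per line (JSON Lines). Records are
#' self-describing via a `type` field: a single `members` record (the
#' roster), `thread` records (`thread_id`, `initiator`, `created_time`,
#' `title`) and `message` records (`message_id`, `thread_id`, `author`,
#' `timestamp`, `reply_to` or null, `tokens` as an array of strings, or null
#' when the text is unavailable). Malformed records and invariant violations
#' are errors, never silently dropped.
#'
#' @param path path to a `.jsonl` corpus file.
#' @return A [forum_corpus()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(forum_corpus(
      threads = data.frame(thread_id = character(), initiator = character(),
                           created_time = integer(), title = character(),
                           stringsAsFactors = FALSE),
      messages = empty_messages(),
      members = character()
    ))
  }
  recs <- lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e) stop("malformed record on line ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    if (is.null(r$type)) stop("record on line ", i, " has no 'type' field")
    r
  })
  types <- vapply(recs, function(r) r$type, character(1))
  need <- function(r, f, i) {
    if (is.null(r[[f]])) stop("record on line ", i, " missing field '", f, "'")
    r[[f]]
  }
  ti <- which(types == "thread")
  threads <- data.frame(
    thread_id = vapply(ti, function(i) as.character(need(recs[[i]], "thread_id", i)), character(1)),
    initiator = vapply(ti, function(i) as.character(need(recs[[i]], "initiator", i)), character(1)),
    created_time = vapply(ti, function(i) as.integer(need(recs[[i]], "created_time", i)), integer(1)),
    title = vapply(ti, function(i) as.character(need(recs[[i]], "title", i)), character(1)),
    stringsAsFactors = FALSE
  )
  mi <- which(types == "message")
  messages <- data.frame(
    message_id = vapply(mi, function(i) as.character(need(recs[[i]], "message_id", i)), character(1)),
    thread_id = vapply(mi, function(i) as.character(need(recs[[i]], "thread_id", i)), character(1)),
    author = vapply(mi, function(i) as.character(need(recs[[i]], "author", i)), character(1)),
    timestamp = vapply(mi, function(i) as.integer(need(recs[[i]], "timestamp", i)), integer(1)),
    reply_to = vapply(mi, function(i) {
      rt <- recs[[i]]$reply_to
      if (is.null(rt)) NA_character_ else as.character(rt)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  messages$tokens <- lapply(mi, function(i) {
    tk <- recs[[i]]$tokens
    if (is.null(tk)) NA else as.character(tk)
  })
  members <- character()
  memi <- which(types == "members")
  if (length(memi)) members <- as.character(recs[[memi[1]]]$ids)
  unknown <- setdiff(types, c("thread", "message", "members"))
  if (length(unknown)) stop("unknown record type: ", unknown[1])
  messages <- messages[order(messages$thread_id, messages$timestamp,
                             messages$message_id), , drop = FALSE]
  rownames(messages) <- NULL
  forum_corpus(threads, messages,
               members = union(members, c(threads$initiator, messages$author)))
}

empty_messages <- function() {
  m <- data.frame(message_id = character(), thread_id = character(),
                  author = character(), timestamp = integer(),
                  reply_to = character(), stringsAsFactors = FALSE)
  m$tokens <- list()
  m
}

#' Write a forum corpus to its line-record file
#'
#' Inverse of [read_corpus()]: writes one JSON record per line (a `members`
#' roster record, then `thread` records, then `message` records in timestamp
#' order). `read_corpus(write_corpus(x))` reproduces `x` exactly, including
#' empty-token and unavailable-text messages.
#'
#' @param corpus a `forum_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  wr <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null"),
               con, useBytes = TRUE)
  }
  wr(list(type = "members", ids = as.list(corpus$members)))
  th <- corpus$threads
  for (i in seq_len(nrow(th))) {
    wr(list(type = "thread", thread_id = th$thread_id[i],
            initiator = th$initiator[i],
            created_time = th$created_time[i], title = th$title[i]))
  }
  ms <- corpus$messages
  if (nrow(ms) > 0) {
    ms <- ms[order(ms$thread_id, ms$timestamp, ms$message_id), , drop = FALSE]
    for (i in seq_len(nrow(ms))) {
      tk <- ms$tokens[[i]]
      wr(list(type = "message", message_id = ms$message_id[i],
              thread_id = ms$thread_id[i], author = ms$author[i],
              timestamp = ms$timestamp[i],
              reply_to = if (is.na(ms$reply_to[i])) NULL else ms$reply_to[i],
              tokens = if (!text_available(tk)) NULL else as.list(as.character(tk))))
    }
  }
  invisible(path)
}

#' Descriptive summary of a forum corpus
#'
#' Thread/message/member counts, the thread-participant histogram (number of
#' distinct user ids posting in each thread -- the quantity whose empirical
#' distribution in the motivating depression-group data peaks at two
#' participants), and the maximum participants observed in any thread. The
#' returned object also carries, as documented reference constants, the
#' corresponding values of the motivating study group (3,700 threads, 40,357
#' messages, 5,050 members, max 276 participants); these are reference
#' points, never recomputed.
#'
#' @param corpus a `forum_corpus`.
#' @return A list of class `corpus_summary` with elements `n_threads`,
#'   `n_messages`, `n_members`, `participant_histogram` (named integer
#'   vector: participants -> number of threads), `max_participants`,
#'   `messages_per_thread` (named integer), and `reference`.
#' @export
corpus_summary <- function(corpus) {
  ms <- corpus$messages
  if (nrow(ms) > 0) {
    pc <- vapply(split(ms$author, ms$thread_id), function(a) length(unique(a)), integer(1))
    hist <- table(factor(pc, levels = seq_len(max(pc))))
    hist <- stats::setNames(as.integer(hist), names(hist))
    mpt <- vapply(split(ms$message_id, ms$thread_id), length, integer(1))
  } else {
    pc <- integer()
    hist <- integer()
    mpt <- integer()
  }
  structure(list(
    n_threads = nrow(corpus$threads),
    n_messages = nrow(ms),
    n_members = length(corpus$members),
    participant_histogram = hist,
    max_participants = if (length(pc)) max(pc) else 0L,
    messages_per_thread = mpt,
    reference = mdd_reference()$corpus
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("Corpus summary\n")
  cat("  threads:  ", x$n_threads, "\n")
  cat("  messages: ", x$n_messages, "\n")
  cat("  members:  ", x$n_members, "\n")
  cat("  max participants in a thread: ", x$max_participants, "\n")
  if (length(x$participant_histogram)) {
    mode_p <- names(x$participant_histogram)[which.max(x$participant_histogram)]
    cat("  modal participant count: ", mode_p, "\n")
  }
  invisible(x)
}
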