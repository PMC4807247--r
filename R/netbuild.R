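#' Build the directed conversation multigraph of a corpus
#'
#' Every message contributes exactly one directed edge, by three rules:
#' the thread-opening post adds a self-loop at the initiator (marking thread
#' initiation); a message addressed to the thread at large adds an edge from
#' its author to the thread initiator; a message replying to a specific
#' earlier message adds an edge from its author to that message's author (a
#' self-loop when replying to oneself). The result is a directed multigraph
#' with self-loops whose edge count equals the corpus's message count.
#'
#' @param corpus a `forum_corpus`.
#' @return An `igraph` directed multigraph. Vertices are named by member id
#'   and cover every member who posted. Edge attributes: `message_id`, and
#'   `opening` (`TRUE` for thread-opening self-loops, distinguishing thread
#'   initiation from initiators' untargeted follow-up self-loops and
#'   self-replies).
#' @export
build_conversation_graph <- function(corpus) {
  ms <- corpus$messages
  th <- corpus$threads
  posters <- sort(unique(c(th$initiator, ms$author)))
  if (nrow(ms) == 0) {
    g <- igraph::make_empty_graph(n = length(posters), directed = TRUE)
    igraph::V(g)$name <- posters
    return(g)
  }
  ord <- order(ms$thread_id, ms$timestamp, ms$message_id)
  ms <- ms[ord, , drop = FALSE]
  init_of <- stats::setNames(th$initiator, th$thread_id)
  opening <- !duplicated(ms$thread_id)  # earliest message per thread
  # addressee: replied-to author, else thread initiator
  target <- unname(init_of[ms$thread_id])
  has_rt <- !is.na(ms$reply_to)
  if (any(has_rt)) {
    idx <- match(ms$reply_to[has_rt], ms$message_id)
    if (anyNA(idx)) {
      stop("message ", ms$message_id[has_rt][is.na(idx)][1],
           " replies to an unknown message")
    }
    same_thread <- ms$thread_id[idx] == ms$thread_id[has_rt]
    if (!all(same_thread)) {
      stop("message ", ms$message_id[has_rt][!same_thread][1],
           " replies outside its thread")
    }
    target[has_rt] <- ms$author[idx]
  }
  el <- rbind(match(ms$author, posters), match(target, posters))
  g <- igraph::make_empty_graph(n = length(posters), directed = TRUE)
  igraph::V(g)$name <- posters
  g <- igraph::add_edges(g, as.vector(el),
                         message_id = ms$message_id, opening = opening)
  g
}

#' Remove self-loops from a conversation graph
#'
#' Self-loops (thread initiations, untargeted initiator follow-ups, and
#' self-replies) are removed before structural analysis, which concerns
#' conversations *between* members. The number removed, split by provenance
#' where the `opening` edge attribute is present, is recorded on the result.
#'
#' @param g a directed `igraph` (typically from
#'   [build_conversation_graph()]).
#' @return The graph without self-loops, with graph attributes
#'   `removed_self_loops`, and (when provenance is known)
#'   `removed_opening` / `removed_other`.
#' @export
strip_self_loops <- function(g) {
  loops <- igraph::which_loop(g)
  out <- igraph::delete_edges(g, igraph::E(g)[loops])
  out <- igraph::set_graph_attr(out, "removed_self_loops", sum(loops))
  if ("opening" %in% igraph::edge_attr_names(g)) {
    op <- igraph::E(g)$opening
    out <- igraph::set_graph_attr(out, "removed_opening", sum(loops & op))
    out <- igraph::set_graph_attr(out, "removed_other", sum(loops & !op))
  }
  out
}

#' Undirected friendship projection
#'
#' Two members are "friends" (weak social relation) if they ever exchanged
#' messages in either direction. Direction and multiplicity are discarded
#' and self-loops dropped; applying the projection twice is a no-op.
#'
#' @param g a directed `igraph` conversation graph.
#' @return An undirected simple `igraph`.
#' @export
to_friend_graph <- function(g) {
  u <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(u, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Export a graph as a weighted edge list or GraphML
#'
#' The edge-list export collapses multi-edges to `(source, target,
#' multiplicity)` rows; GraphML preserves the multigraph.
#'
#' @param g an `igraph`.
#' @param path output file.
#' @param format `"edgelist"` (tab-separated source/target/multiplicity) or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el)) {
      key <- paste(el[, 1], el[, 2], sep = "\r")
      tab <- table(key)
      parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
      df <- data.frame(source = parts[, 1], target = parts[, 2],
                       multiplicity = as.integer(tab), stringsAsFactors = FALSE)
      df <- df[order(df$source, df$target), , drop = FALSE]
    } else {
      df <- data.frame(source = character(), target = character(),
                       multiplicity = integer(), stringsAsFactors = FALSE)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
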