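# Shared fixtures and independent brute-force oracles.

# --- corpus fixtures --------------------------------------------------------

# Three-thread toy corpus, hand-checkable.
#   t1: A opens; B posts (thread at large); C replies to B's message.
#   t2: B opens; A replies to the opening post; B replies to A (self-thread).
#   t3: C opens alone.
make_toy_corpus <- function() {
  threads <- data.frame(
    thread_id = c("t1", "t2", "t3"),
    initiator = c("A", "B", "C"),
    created_time = 1:3,
    title = c("one", "two", "three"),
    stringsAsFactors = FALSE
  )
  messages <- data.frame(
    message_id = c("x1", "x2", "x3", "y1", "y2", "y3", "z1"),
    thread_id = c("t1", "t1", "t1", "t2", "t2", "t2", "t3"),
    author = c("A", "B", "C", "B", "A", "B", "C"),
    timestamp = c(1L, 2L, 3L, 1L, 2L, 3L, 1L),
    reply_to = c(NA, NA, "x2", NA, "y1", "y2", NA),
    stringsAsFactors = FALSE
  )
  messages$tokens <- list(
    c("i", "feel", "sad"), c("you", "hear", "me"), c("we", "hope"),
    c("sleep", "now"), character(), c("go", "home"), c("w001", "w002")
  )
  forum_corpus(threads, messages)
}

# Small digraph from an edge matrix (rows from, to), named a, b, c, ...
graph_from_pairs <- function(from, to, n = max(c(from, to))) {
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  igraph::V(g)$name <- letters[seq_len(n)]
  igraph::add_edges(g, as.vector(rbind(from, to)))
}

random_digraph <- function(n, p = 0.25) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  diag(a) <- FALSE
  idx <- which(a, arr.ind = TRUE)
  graph_from_pairs(idx[, 1], idx[, 2], n = n)
}

# --- brute-force oracles ----------------------------------------------------

# boolean reachability closure (paths of length >= 1) by repeated squaring
reach_closure <- function(a) {
  n <- nrow(a)
  r <- a
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1)) {
    r <- r | (r %*% r > 0)
  }
  r
}

# Bow-Tie by exhaustive reachability matrices; paths for TENDRILS/TUBES are
# required to avoid the SCC, per the component definitions.
bowtie_oracle <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  a[el[el[, 1] != el[, 2], , drop = FALSE]] <- TRUE
  r <- reach_closure(a)
  mutual <- (r & t(r)) | diag(TRUE, n)
  comp_id <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp_id[i] == 0) {
      cid <- cid + 1
      comp_id[mutual[i, ]] <- cid
    }
  }
  sizes <- table(comp_id)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    firsts <- vapply(big, function(ci) min(which(comp_id == ci)), integer(1))
    big <- big[which.min(firsts)]
  }
  scc <- comp_id == big
  in_set <- !scc & apply(r[, scc, drop = FALSE], 1, any)
  out_set <- !scc & apply(r[scc, , drop = FALSE], 2, any)
  rest <- !(scc | in_set | out_set)
  # closure on the graph with SCC removed
  a2 <- a
  a2[scc, ] <- FALSE
  a2[, scc] <- FALSE
  r2 <- reach_closure(a2)
  from_in <- rest & apply(r2[in_set, , drop = FALSE], 2, any)
  to_out <- rest & apply(r2[, out_set, drop = FALSE], 1, any)
  tubes <- from_in & to_out
  tendrils <- (from_in | to_out) & !tubes
  cls <- rep("DISC", n)
  cls[scc] <- "SCC"; cls[in_set] <- "IN"; cls[out_set] <- "OUT"
  cls[tendrils] <- "TENDRILS"; cls[tubes] <- "TUBES"
  factor(cls, levels = c("SCC", "IN", "OUT", "TENDRILS", "TUBES", "DISC"))
}

# simple-projection adjacency (no loops, no multiplicity)
simple_adj <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  a[el] <- TRUE
  a
}

# Floyd-Warshall shortest paths on the simple digraph
floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

asp_oracle <- function(g) {
  d <- floyd_warshall(simple_adj(g))
  diag(d) <- Inf
  vals <- d[is.finite(d)]
  list(asp = mean(vals), diameter = max(vals))
}

clustering_oracle <- function(g) {
  a <- simple_adj(g)
  u <- a | t(a)
  n <- nrow(u)
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(u[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    sum(u[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

reciprocity_oracle <- function(g) {
  a <- simple_adj(g)
  sum(a & t(a)) / sum(a)
}

# normalized directed betweenness by exhaustive shortest-path enumeration
betweenness_oracle <- function(g) {
  a <- simple_adj(g)
  n <- nrow(a)
  d <- floyd_warshall(a)
  count_paths <- function(s, t) {
    # number of shortest s->t paths through each node
    if (!is.finite(d[s, t]) || s == t) return(list(total = 0, through = numeric(n)))
    through <- numeric(n)
    total <- 0
    walk <- function(v, path) {
      if (v == t) {
        total <<- total + 1
        inner <- setdiff(path, c(s, t))
        through[inner] <<- through[inner] + 1
        return(invisible())
      }
      for (w in which(a[v, ])) {
        if (d[v, t] == d[w, t] + 1) walk(w, c(path, w))
      }
    }
    walk(s, s)
    list(total = total, through = through)
  }
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(d[s, t])) {
      cp <- count_paths(s, t)
      if (cp$total > 0) b <- b + cp$through / cp$total
    }
  }
  b / ((n - 1) * (n - 2))
}

# naive per-token tagger with its own recursive ancestor walk
tag_oracle <- function(tokens, lexicon) {
  h <- lexicon$hierarchy
  counts <- stats::setNames(integer(length(h)), names(h))
  tagged <- 0L
  up <- function(lab) {
    out <- character()
    while (!is.na(lab)) { out <- c(out, lab); lab <- unname(h[lab]) }
    out
  }
  for (tk in tokens) {
    labs <- lexicon$entries[[tk]]
    if (is.null(labs)) next
    tagged <- tagged + 1L
    cats <- unique(unlist(lapply(labs, up)))
    counts[cats] <- counts[cats] + 1L
  }
  list(word_count = length(tokens), tagged_count = tagged, counts = counts)
}

# Spearman via explicit average ranks + product-moment formula
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(rank(x[ok]), rank(y[ok]), method = "pearson")
}
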