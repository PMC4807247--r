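#' Bow-Tie decomposition of a directed graph
#'
#' Partitions every node into exactly one of six reachability classes
#' around the largest strongly connected component (Broder-style):
#' \describe{
#'   \item{SCC}{the largest strongly connected component -- every member
#'     reaches every other along directed paths (ties between equally
#'     large components broken by the smallest contained node id);}
#'   \item{IN}{nodes outside SCC that can reach it (members whose replies
#'     flow into the core but who get no response from it);}
#'   \item{OUT}{nodes outside SCC reachable from it;}
#'   \item{TUBES}{remaining nodes on a directed path from IN to OUT that
#'     avoids SCC;}
#'   \item{TENDRILS}{remaining nodes reachable from IN or reaching OUT;}
#'   \item{DISC}{everything else, including smaller strongly connected
#'     components meeting none of the criteria above.}
#' }
#' Self-loops are ignored. The classes are mutually exclusive and
#' exhaustive, and fractions sum to one.
#'
#' @param g a directed `igraph` with at least one node.
#' @return A list of class `bowtie_decomposition`: `membership` (named
#'   factor over nodes with levels SCC/IN/OUT/TENDRILS/TUBES/DISC),
#'   `counts`, `fractions`, `n_nodes`.
#' @export
bowtie_decompose <- function(g) {
  if (!igraph::is_directed(g)) stop("Bow-Tie decomposition needs a directed graph")
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(gs, mode = "strong")
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # tie-break: component containing the smallest node index
    first_node <- vapply(biggest, function(ci) min(which(comp$membership == ci)),
                         integer(1))
    biggest <- biggest[which.min(first_node)]
  }
  scc <- comp$membership == biggest

  # forward/backward closures of the SCC via one BFS each from an auxiliary
  # super-vertex
  reach_from <- function(graph, seeds, mode) {
    if (!length(seeds)) return(logical(igraph::vcount(graph)))
    aux <- igraph::add_vertices(graph, 1)
    s <- igraph::vcount(graph) + 1L
    edges <- if (mode == "out") rbind(s, seeds) else rbind(seeds, s)
    aux <- igraph::add_edges(aux, as.vector(edges))
    r <- igraph::subcomponent(aux, s, mode = mode)
    out <- logical(igraph::vcount(graph))
    r <- as.integer(r)
    out[r[r <= igraph::vcount(graph)]] <- TRUE
    out
  }

  scc_nodes <- which(scc)
  fwd <- reach_from(gs, scc_nodes, "out")   # SCC + everything it reaches
  bwd <- reach_from(gs, scc_nodes, "in")    # SCC + everything reaching it
  out_set <- fwd & !scc
  in_set <- bwd & !scc
  rest <- !(scc | in_set | out_set)

  # among the rest: reachable from IN, and reaching OUT. Paths from IN to a
  # rest node cannot pass through SCC (they would land in SCC/OUT), so plain
  # reachability on the full graph is already SCC-avoiding.
  from_in <- reach_from(gs, which(in_set), "out") & rest
  to_out <- reach_from(gs, which(out_set), "in") & rest
  tubes <- from_in & to_out
  tendrils <- (from_in | to_out) & !tubes

  cls <- rep("DISC", n)
  cls[scc] <- "SCC"
  cls[in_set] <- "IN"
  cls[out_set] <- "OUT"
  cls[tendrils] <- "TENDRILS"
  cls[tubes] <- "TUBES"
  lev <- c("SCC", "IN", "OUT", "TENDRILS", "TUBES", "DISC")
  membership <- factor(cls, levels = lev)
  nm <- igraph::V(g)$name
  if (!is.null(nm)) names(membership) <- nm
  counts <- table(membership)
  structure(list(membership = membership,
                 counts = stats::setNames(as.integer(counts), lev),
                 fractions = stats::setNames(as.numeric(counts) / n, lev),
                 n_nodes = n),
            class = "bowtie_decomposition")
}

#' @export
print.bowtie_decomposition <- function(x, ...) {
  cat("Bow-Tie decomposition of", x$n_nodes, "nodes\n")
  for (cl in names(x$fractions)) {
    cat(sprintf("  %-8s %6.2f%%  (%d)\n", cl, 100 * x$fractions[cl], x$counts[cl]))
  }
  invisible(x)
}

#' Bow-Tie comparison table
#'
#' Lays out one percentage row per decomposed network, in the conventional
#' comparison format, optionally appending the published reference columns
#' (Myspace, a Java developer forum, the Web graph) from [mdd_reference()]
#' as documented constants -- those rows are never recomputed.
#'
#' @param decompositions named list of `bowtie_decomposition` objects.
#' @param include_reference logical; append the published reference rows.
#' @return data.frame with columns `network`, `SCC`, `IN`, `OUT`,
#'   `TENDRILS`, `TUBES`, `DISC` (percentages summing to 100 per row) and
#'   `source` (`"computed"` or `"published"`).
#' @export
bowtie_table <- function(decompositions, include_reference = FALSE) {
  rows <- lapply(names(decompositions), function(nm) {
    fr <- 100 * decompositions[[nm]]$fractions
    cbind(data.frame(network = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(fr)), data.frame(source = "computed"))
  })
  out <- do.call(rbind, rows)
  if (include_reference) {
    ref <- mdd_reference()$bowtie
    for (nm in c("myspace", "java_forum", "web")) {
      out <- rbind(out, cbind(data.frame(network = nm, stringsAsFactors = FALSE),
                              as.data.frame(as.list(ref[[nm]])),
                              data.frame(source = "published")))
    }
  }
  rownames(out) <- NULL
  out
}
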