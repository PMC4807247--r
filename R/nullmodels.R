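# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

#' Erdős–Rényi random graph G(n, m)
#'
#' Exactly `m` distinct edges (no self-loops) drawn uniformly over all such
#' graphs, directed or undirected; the baseline null model for comparing
#' observed reply networks (at the motivating group's scale: 5,050 nodes
#' with 36,657 directed or 17,401 undirected edges).
#'
#' @param n number of nodes.
#' @param m number of edges.
#' @param directed logical.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return An `igraph`.
#' @export
er_graph <- function(n, m, directed = TRUE, seed = NULL) {
  max_m <- if (directed) n * (n - 1) else n * (n - 1) / 2
  if (m < 0 || m > max_m) stop("m out of range [0, ", max_m, "]")
  with_local_seed(seed, igraph::sample_gnm(n, m, directed = directed))
}

#' Barabási–Albert variant with directed reply edges
#'
#' Grows a directed graph the way a forum's reply network accumulates:
#' start from a complete directed clique of `seed_size` nodes (20 edges for
#' the default 5), then each arriving node posts `edges_per_step` directed
#' edges to *existing* nodes (replier to earlier poster), targets sampled
#' with probability proportional to current total degree, distinct within a
#' step. While fewer than `edges_per_step` nodes exist (only the first
#' arrivals for the 5-node seed), targets are drawn with multiplicity so the
#' edge-count contract `seed_size*(seed_size-1) + edges_per_step*(n -
#' seed_size)` holds exactly (35,335 edges at n = 5,050). Because no edge
#' ever points from an older node to a newer one, the largest strongly
#' connected component is exactly the seed clique, for every n and seed.
#'
#' @param n total number of nodes (>= `seed_size`).
#' @param seed_size size of the initial complete clique.
#' @param edges_per_step out-edges added by each arriving node.
#' @param seed optional integer RNG seed.
#' @return A directed `igraph` (possibly with multi-edges at the first
#'   arrivals).
#' @export
ba_graph <- function(n, seed_size = 5, edges_per_step = 7, seed = NULL) {
  if (seed_size < 1 || n < seed_size) stop("need n >= seed_size >= 1")
  with_local_seed(seed, {
    deg <- numeric(n)
    # complete directed clique on the seed
    sidx <- seq_len(seed_size)
    from0 <- rep(sidx, each = seed_size - 1)
    to0 <- unlist(lapply(sidx, function(i) sidx[sidx != i]), use.names = FALSE)
    deg[sidx] <- 2 * (seed_size - 1)
    n_new <- n - seed_size
    from_l <- vector("list", n_new + 1L)
    to_l <- vector("list", n_new + 1L)
    from_l[[1]] <- from0; to_l[[1]] <- to0
    if (n_new > 0) {
      for (v in (seed_size + 1):n) {
        existing <- v - 1L
        replace <- existing < edges_per_step
        targets <- sample.int(existing, edges_per_step, replace = replace,
                              prob = deg[seq_len(existing)])
        k <- v - seed_size + 1L
        from_l[[k]] <- rep.int(v, edges_per_step)
        to_l[[k]] <- targets
        tb <- tabulate(targets, nbins = existing)
        deg[seq_len(existing)] <- deg[seq_len(existing)] + tb
        deg[v] <- edges_per_step
      }
    }
    el <- rbind(unlist(from_l, use.names = FALSE), unlist(to_l, use.names = FALSE))
    igraph::make_graph(as.vector(el), n = n, directed = TRUE)
  })
}

#' Watts–Strogatz small-world graph
#'
#' Ring lattice on `n` nodes with `k` nearest neighbours per node (`k`
#' even), each edge rewired independently with probability `p`, avoiding
#' self-loops and duplicate edges. At `p = 0` the local clustering equals
#' the lattice closed form `3 (k - 2) / (4 (k - 1))`; moderate `p` gives the
#' small-world regime (short paths, clustering far above the random-graph
#' level). The default neighbourhood is `k = 6`: the motivating comparison
#' names seven neighbours, which no even-degree ring realizes and which
#' contradicts its own edge count, so the nearest even value is used and
#' `k` is left as a parameter.
#'
#' @param n nodes.
#' @param k even number of neighbours per node (`k < n`).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed optional integer RNG seed.
#' @return An undirected `igraph`.
#' @export
ws_graph <- function(n, k = 6, p = 0.45, seed = NULL) {
  if (k >= n) stop("k must be smaller than n")
  if (k %% 2 != 0) stop("k must be even (ring lattice with k/2 neighbours a side)")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  with_local_seed(seed, {
    igraph::sample_smallworld(dim = 1, size = n, nei = k / 2, p = p,
                              loops = FALSE, multiple = FALSE)
  })
}
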