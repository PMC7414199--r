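# All-pairs BFS on an undirected, unweighted igraph: geodesic distance matrix
# D and shortest-path count matrix S (S[s, t] = number of distinct shortest
# s-t paths; S[s, s] = 1). O(n * m) time, O(n^2) memory.
sp_dist_sigma <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, as.integer)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- d + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == d + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
      d <- d + 1
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  list(D = D, S = S)
}

# Betweenness and stress for every node from the (D, S) pair.
# betweenness(v) = sum over unordered pairs {s,t}, s,t != v, of
#   sigma_st(v) / sigma_st;  stress(v) drops the division.
betweenness_stress <- function(D, S) {
  n <- nrow(D)
  bet <- numeric(n); str_ <- numeric(n)
  if (n < 3L) return(list(betweenness = bet, stress = str_))
  upper <- upper.tri(D)
  for (v in seq_len(n)) {
    through <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    through[v, ] <- FALSE; through[, v] <- FALSE
    diag(through) <- FALSE
    sig_v <- outer(S[, v], S[v, ])
    mask <- through & upper
    str_[v] <- sum(sig_v[mask])
    bet[v] <- sum(sig_v[mask] / S[mask])
  }
  list(betweenness = bet, stress = str_)
}

# Harmonic-free component-wise closeness: (n_c - 1) / sum of distances to the
# other members of v's component; 0 for isolated nodes.
closeness_from_dist <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) return(0)
    length(reach) / sum(D[v, reach])
  }, numeric(1))
}

#' Edge-percolated-component (EPC) centrality
#'
#' Monte-Carlo percolation centrality: in each realization every edge is kept
#' independently with probability `retain_p`; a node's score in that
#' realization is the number of other nodes it remains connected to. EPC is
#' the mean over realizations. With `retain_p = 1` on a connected graph this
#' is exactly `n - 1` for every node; with `retain_p = 0` it is 0.
#'
#' @param graph An igraph (undirected).
#' @param reps Number of percolation realizations.
#' @param retain_p Per-edge retention probability in \[0, 1\].
#' @param rng_seed Optional seed; when given, results are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of EPC scores, one per vertex.
#' @export
epc_centrality <- function(graph, reps = 1000, retain_p = 0.5, rng_seed = NULL) {
  stopifnot(reps >= 1, retain_p >= 0, retain_p <= 1)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  run <- function() {
    acc <- numeric(n)
    for (r in seq_len(reps)) {
      if (m > 0 && retain_p > 0) {
        keep <- stats::runif(m) < retain_p
        gs <- igraph::subgraph_from_edges(graph, which(keep), delete.vertices = FALSE)
      } else {
        gs <- igraph::delete_edges(graph, seq_len(m))
      }
      comp <- igraph::components(gs)
      acc <- acc + (comp$csize[comp$membership] - 1)
    }
    acc / reps
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Five-centrality table for a network
#'
#' Computes degree, betweenness, stress, closeness and edge-percolated
#' component for every node, plus a dense rank per measure (rank 1 is the
#' highest value; ties share a rank). Definitions: degree is the incident edge
#' count; betweenness sums, over unordered node pairs, the fraction of shortest
#' paths passing through the node (unnormalized); stress counts those shortest
#' paths without the fraction; closeness is component-wise,
#' `(n_c - 1) / sum(d(v, w))`, 0 for isolated nodes; EPC as in
#' [epc_centrality()].
#'
#' @param network A `ppi_network` from [build_ppi()], or any igraph.
#' @param epc_reps,epc_retain_p,rng_seed EPC Monte-Carlo parameters.
#' @return A tibble with columns `node`, the five measures, and
#'   `rank_<measure>` dense ranks.
#' @export
compute_centralities <- function(network, epc_reps = 1000, epc_retain_p = 0.5,
                                 rng_seed = NULL) {
  graph <- if (inherits(network, "ppi_network")) network$graph else network
  stopifnot(igraph::vcount(graph) > 0)
  sp <- sp_dist_sigma(graph)
  bs <- betweenness_stress(sp$D, sp$S)
  res <- tibble::tibble(
    node = igraph::V(graph)$name,
    degree = as.numeric(igraph::degree(graph)),
    betweenness = bs$betweenness,
    stress = bs$stress,
    closeness = closeness_from_dist(sp$D),
    epc = epc_centrality(graph, reps = epc_reps, retain_p = epc_retain_p,
                         rng_seed = rng_seed)
  )
  for (m in c("degree", "betweenness", "stress", "closeness", "epc")) {
    res[[paste0("rank_", m)]] <- dense_rank_desc(res[[m]])
  }
  res
}

# dense rank, 1 = largest value, ties share a rank
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

# top-n selection under dense ranking: all ties at the cutoff rank included
top_n_dense <- function(nodes, values, n) {
  if (n >= length(nodes)) {
    if (n > length(nodes)) {
      warning(sprintf("top-n %d exceeds node count %d; clamped", n, length(nodes)),
              call. = FALSE)
    }
    return(nodes)
  }
  r <- dense_rank_desc(values)
  cutoff <- r[order(-values)][n]
  nodes[r <= cutoff]
}
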