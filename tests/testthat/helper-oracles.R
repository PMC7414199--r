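# Brute-force oracles, independent of the package's implementations.

# all shortest paths between s and t by exhaustive simple-path DFS
bf_shortest_paths <- function(adj, s, t) {
  best <- list()
  bestlen <- Inf
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      if (length(path) < bestlen) {
        bestlen <<- length(path)
        best <<- list(path)
      } else if (length(path) == bestlen) {
        best[[length(best) + 1L]] <<- path
      }
      return(invisible())
    }
    if (length(path) + 1L > bestlen) return(invisible())
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  list(paths = best, dist = if (is.infinite(bestlen)) Inf else bestlen - 1L)
}

# betweenness, stress and closeness of every node by path enumeration
bf_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  bet <- numeric(n); str_ <- numeric(n)
  D <- matrix(Inf, n, n); diag(D) <- 0
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      sp <- bf_shortest_paths(adj, s, t)
      D[s, t] <- D[t, s] <- sp$dist
      if (length(sp$paths) == 0) next
      sigma <- length(sp$paths)
      inner <- unlist(lapply(sp$paths, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        cnt <- table(inner)
        idx <- as.integer(names(cnt))
        str_[idx] <- str_[idx] + as.numeric(cnt)
        bet[idx] <- bet[idx] + as.numeric(cnt) / sigma
      }
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) 0 else length(reach) / sum(D[v, reach])
  }, numeric(1))
  list(betweenness = bet, stress = str_, closeness = clo, dist = D)
}

# feed-forward loops by scanning every (miRNA, TF, gene) triple
bf_ffls <- function(edges) {
  has <- function(s, t, type) {
    any(edges$source == s & edges$target == t & edges$edge_type == type)
  }
  ms <- unique(edges$source[edges$edge_type %in% c("mirna_gene", "mirna_tf")])
  ts <- unique(c(edges$target[edges$edge_type == "mirna_tf"],
                 edges$source[edges$edge_type == "tf_gene"]))
  gs <- unique(edges$target[edges$edge_type %in% c("mirna_gene", "tf_gene")])
  out <- list()
  for (m in ms) for (tf in ts) for (g in gs) {
    if (has(m, tf, "mirna_tf") && has(m, g, "mirna_gene") && has(tf, g, "tf_gene")) {
      out[[length(out) + 1L]] <- tibble::tibble(mirna = m, tf = tf, gene = g)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), tf = character(), gene = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), mirna, tf, gene)
}

# literal Benjamini-Hochberg step-up rule
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# explicit hypergeometric upper-tail sum P(X >= a)
bf_hyper_tail <- function(a, N, K, n) {
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random connected undirected graph with named vertices
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
}

# random tripartite typed edge set
random_tripartite_edges <- function(n_m, n_t, n_g, p = 0.25) {
  ms <- paste0("m", seq_len(n_m)); ts <- paste0("T", seq_len(n_t))
  gs <- paste0("g", seq_len(n_g))
  pick <- function(ss, tt, type) {
    grid <- expand.grid(source = ss, target = tt, stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
    if (nrow(grid) == 0) return(NULL)
    tibble::tibble(source = grid$source, target = grid$target, edge_type = type,
                   species = "human", dialect = "mirwalk")
  }
  out <- dplyr::bind_rows(pick(ms, ts, "mirna_tf"), pick(ms, gs, "mirna_gene"),
                          pick(ts, gs, "tf_gene"))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(source = character(), target = character(),
                          edge_type = character(), species = character(),
                          dialect = character())
  }
  out
}
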