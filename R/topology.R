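#' Topology statistics of a merged regulatory network
#'
#' All statistics are computed on the undirected projection of the merged
#' graph (direction is retained in the motif list itself). Per node: degree,
#' local clustering coefficient \eqn{C_v = 2 e_v / (k_v (k_v - 1))} (0 when
#' \eqn{k_v < 2}), topological coefficient
#' \eqn{T_v = \mathrm{avg}_u J(v, u) / k_v} over nodes u sharing at least one
#' neighbor with v, where \eqn{J(v, u)} is the shared-neighbor count plus 1 if
#' u is adjacent to v, and betweenness and closeness as in
#' [compute_centralities()]. Distributions: the degree histogram, mean
#' clustering and mean topological coefficient per degree class, and the
#' shortest-path-length histogram over connected pairs. The degree histogram
#' is summarized by a power-law fit: least-squares slope and intercept of
#' log10(count) versus log10(degree) over nonzero bins, with R-squared.
#'
#' @param network An `ffl_network` from [build_ffl_network()], or any igraph.
#' @return An `ffl_topology` list: `node_stats` (tibble), `degree_dist`,
#'   `clustering_by_degree`, `topological_by_degree`, `path_length_dist`
#'   (tibbles) and `power_law` (one-row tibble `slope` / `intercept` /
#'   `r_squared` / `n_bins`).
#' @export
topology_stats <- function(network) {
  graph <- if (inherits(network, "ffl_network")) network$graph else network
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty network", call. = FALSE)
  sp <- sp_dist_sigma(graph)
  bs <- betweenness_stress(sp$D, sp$S)
  deg <- as.numeric(igraph::degree(graph))
  clust <- as.numeric(igraph::transitivity(graph, type = "local", isolates = "zero"))

  node_stats <- tibble::tibble(
    node = igraph::V(graph)$name %||% as.character(seq_len(n)),
    degree = deg,
    clustering = clust,
    topological_coefficient = topological_coefficient(graph),
    betweenness = bs$betweenness,
    closeness = closeness_from_dist(sp$D)
  )

  degree_dist <- node_stats |>
    dplyr::count(.data$degree, name = "n_nodes") |>
    dplyr::arrange(.data$degree)
  clustering_by_degree <- node_stats |>
    dplyr::summarise(mean_clustering = mean(.data$clustering), .by = "degree") |>
    dplyr::arrange(.data$degree)
  topological_by_degree <- node_stats |>
    dplyr::summarise(mean_topological = mean(.data$topological_coefficient),
                     .by = "degree") |>
    dplyr::arrange(.data$degree)

  finite <- sp$D[upper.tri(sp$D)]
  finite <- finite[is.finite(finite) & finite > 0]
  path_length_dist <- if (length(finite) > 0) {
    tibble::tibble(length = sort(unique(finite))) |>
      dplyr::mutate(n_pairs = vapply(.data$length,
                                     function(l) sum(finite == l), numeric(1)))
  } else {
    tibble::tibble(length = numeric(), n_pairs = numeric())
  }

  structure(
    list(node_stats = node_stats, degree_dist = degree_dist,
         clustering_by_degree = clustering_by_degree,
         topological_by_degree = topological_by_degree,
         path_length_dist = path_length_dist,
         power_law = power_law_fit(degree_dist)),
    class = "ffl_topology"
  )
}

# topological coefficient per node; 0 when the node has no partner sharing a
# neighbor (or no neighbors at all)
topological_coefficient <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  shared <- A %*% A          # shared[v, u] = common-neighbor count
  vapply(seq_len(n), function(v) {
    k <- sum(A[v, ])
    if (k == 0) return(0)
    partners <- which(shared[v, ] > 0 & seq_len(n) != v)
    if (length(partners) == 0L) return(0)
    j <- shared[v, partners] + A[v, partners]
    mean(j) / k
  }, numeric(1))
}

#' Log-log least-squares power-law fit of a degree histogram
#'
#' Fits `log10(count) ~ log10(degree)` by ordinary least squares over bins with
#' degree > 0 and count > 0 — the straight line drawn through a log-log degree
#' distribution. With fewer than two usable bins the fit is undefined and NAs
#' are returned; with exactly two bins the line interpolates them and
#' R-squared is 1 by construction.
#'
#' @param degree_dist Tibble with columns `degree`, `n_nodes`.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n_bins`.
#' @export
power_law_fit <- function(degree_dist) {
  use <- degree_dist$degree > 0 & degree_dist$n_nodes > 0
  k <- degree_dist$degree[use]; cnt <- degree_dist$n_nodes[use]
  if (length(k) < 2L) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_bins = length(k)))
  }
  fit <- stats::lm(log10(cnt) ~ log10(k))
  ss_tot <- sum((log10(cnt) - mean(log10(cnt)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_bins = length(k))
}

#' @export
print.ffl_topology <- function(x, ...) {
  cat(sprintf("<ffl_topology: %d nodes; mean degree %.2f; power-law slope %.3f (R^2 %.3f)>\n",
              nrow(x$node_stats), mean(x$node_stats$degree),
              x$power_law$slope, x$power_law$r_squared))
  invisible(x)
}

#' @describeIn topology_stats Per-node statistics tibble.
#' @param x An `ffl_topology`.
#' @param ... Unused.
#' @export
tidy.ffl_topology <- function(x, ...) x$node_stats

#' @describeIn topology_stats One-row network summary (size, mean degree,
#'   mean path length, power-law slope and fit).
#' @export
glance.ffl_topology <- function(x, ...) {
  pl <- x$path_length_dist
  tibble::tibble(
    n_nodes = nrow(x$node_stats),
    mean_degree = mean(x$node_stats$degree),
    median_degree = stats::median(x$node_stats$degree),
    mean_clustering = mean(x$node_stats$clustering),
    mean_path_length = if (nrow(pl) > 0) sum(pl$length * pl$n_pairs) / sum(pl$n_pairs)
                       else NA_real_,
    power_law_slope = x$power_law$slope,
    power_law_r_squared = x$power_law$r_squared
  )
}

#' Panel plot of network topology distributions
#'
#' Degree distribution, mean clustering coefficient and mean topological
#' coefficient per degree class, node betweenness and closeness against
#' degree, and the shortest-path-length histogram, as ggplot facets.
#'
#' @param object An `ffl_topology`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffl_topology <- function(object, ...) {
  panels <- dplyr::bind_rows(
    dplyr::transmute(object$degree_dist, panel = "degree distribution",
                     x = .data$degree, y = .data$n_nodes),
    dplyr::transmute(object$clustering_by_degree, panel = "clustering coeff.",
                     x = .data$degree, y = .data$mean_clustering),
    dplyr::transmute(object$topological_by_degree, panel = "topological coeff.",
                     x = .data$degree, y = .data$mean_topological),
    dplyr::transmute(object$node_stats, panel = "betweenness",
                     x = .data$degree, y = .data$betweenness),
    dplyr::transmute(object$node_stats, panel = "closeness",
                     x = .data$degree, y = .data$closeness),
    dplyr::transmute(object$path_length_dist, panel = "path length",
                     x = .data$length, y = .data$n_pairs)
  )
  ggplot2::ggplot(panels, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
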