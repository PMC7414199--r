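#' Build an evidence-filtered PPI network around seed genes
#'
#' Edges from the BioGRID-like table are kept when they have at least one
#' reported experimental evidence (`evidence_count >= 1`); edges from the
#' HIPPIE-like table are kept when their confidence score lies in
#' `[hippie_min_score, 1]` (default 0.63, medium-and-high confidence). Only
#' edges incident to at least one seed gene survive. The result is an
#' undirected simple graph: self-loops dropped, duplicate pairs merged with
#' their provenance concatenated, and every seed gene present even when
#' isolated.
#'
#' @param seed_genes Character vector, or a tibble with columns `gene` and
#'   `direction` (as from [enriched_union()]).
#' @param biogrid,hippie Interaction tibbles with columns `partner_a`,
#'   `partner_b` plus `evidence_count` (BioGRID-like) or `score`
#'   (HIPPIE-like). Either may be `NULL`.
#' @param hippie_min_score Minimum HIPPIE-style confidence (inclusive).
#' @return A `ppi_network`: list with `graph` (igraph), `nodes` tibble
#'   (`node`, `role` seed/interactor, `regulation` up/down/none) and `edges`
#'   tibble (`from`, `to`, `sources`, `score`, `evidence_count`).
#' @export
build_ppi <- function(seed_genes, biogrid = NULL, hippie = NULL,
                      hippie_min_score = 0.63) {
  if (is.data.frame(seed_genes)) {
    regulation <- stats::setNames(seed_genes$direction, seed_genes$gene)
    seed_genes <- seed_genes$gene
  } else {
    regulation <- stats::setNames(rep("none", length(seed_genes)), seed_genes)
  }
  if (length(seed_genes) == 0L) stop("no seed genes supplied", call. = FALSE)

  check_ppi_cols <- function(tab, score_col, label) {
    need <- c("partner_a", "partner_b", score_col)
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0) {
      stop(sprintf("%s table lacks column(s): %s", label,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  pieces <- list()
  if (!is.null(biogrid) && nrow(biogrid) > 0) {
    check_ppi_cols(biogrid, "evidence_count", "BioGRID-like")
    pieces$biogrid <- biogrid |>
      dplyr::filter(.data$evidence_count >= 1L) |>
      dplyr::transmute(a = .data$partner_a, b = .data$partner_b,
                       source = "biogrid",
                       score = NA_real_,
                       evidence_count = as.integer(.data$evidence_count))
  }
  if (!is.null(hippie) && nrow(hippie) > 0) {
    check_ppi_cols(hippie, "score", "HIPPIE-like")
    pieces$hippie <- hippie |>
      dplyr::filter(.data$score >= hippie_min_score, .data$score <= 1) |>
      dplyr::transmute(a = .data$partner_a, b = .data$partner_b,
                       source = "hippie",
                       score = .data$score, evidence_count = NA_integer_)
  }
  edges <- dplyr::bind_rows(pieces)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(a = character(), b = character(), source = character(),
                            score = numeric(), evidence_count = integer())
  }
  edges <- edges |>
    dplyr::filter(.data$a != .data$b,
                  .data$a %in% seed_genes | .data$b %in% seed_genes) |>
    dplyr::mutate(from = pmin(.data$a, .data$b), to = pmax(.data$a, .data$b)) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
      evidence_count = if (all(is.na(.data$evidence_count))) NA_integer_
                       else max(.data$evidence_count, na.rm = TRUE),
      .by = c("from", "to")
    ) |>
    dplyr::arrange(.data$from, .data$to)

  node_names <- sort(unique(c(seed_genes, edges$from, edges$to)))
  nodes <- tibble::tibble(
    node = node_names,
    role = ifelse(node_names %in% seed_genes, "seed", "interactor"),
    regulation = dplyr::coalesce(unname(regulation[node_names]), "none")
  )
  graph <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$node
  )
  structure(list(graph = graph, nodes = nodes, edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network: %d nodes (%d seeds), %d edges>\n",
              nrow(x$nodes), sum(x$nodes$role == "seed"), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_ppi Edge tibble of the network.
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @export
tidy.ppi_network <- function(x, ...) x$edges

#' @describeIn build_ppi One-row node/edge/seed summary.
#' @export
glance.ppi_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_seeds = sum(x$nodes$role == "seed"),
    n_isolated_seeds = sum(igraph::degree(x$graph)[x$nodes$role == "seed"] == 0)
  )
}

#' Call hub genes by top-n intersection across five centralities
#'
#' For each of the five measures, the top-n nodes by value are taken under
#' dense ranking (all ties at the cutoff rank included); the five sets are
#' intersected, and the intersection is then restricted to the seed genes when
#' `seeds` is supplied. The result may be empty.
#'
#' @param centralities A [compute_centralities()] table.
#' @param n Top-n cutoff (the analysis convention is n = number of seed DEGs
#'   in the network). Values above the node count are clamped with a warning.
#' @param seeds Optional character vector of seed genes to restrict to.
#' @return Sorted character vector of hub genes.
#' @export
identify_hubs <- function(centralities, n, seeds = NULL) {
  stopifnot(n >= 1)
  measures <- c("degree", "betweenness", "stress", "closeness", "epc")
  tops <- lapply(measures, function(m) {
    top_n_dense(centralities$node, centralities[[m]], n)
  })
  hubs <- Reduce(intersect, tops)
  if (!is.null(seeds)) hubs <- intersect(hubs, seeds)
  sort(hubs)
}

#' Per-measure top-n membership table
#'
#' Long table marking which nodes fall in each centrality's top-n set — the
#' tabular content behind a five-set Venn diagram of hub calling.
#'
#' @inheritParams identify_hubs
#' @return Tibble with columns `measure`, `node`.
#' @export
hub_membership <- function(centralities, n) {
  measures <- c("degree", "betweenness", "stress", "closeness", "epc")
  purrr::map_dfr(measures, function(m) {
    tibble::tibble(measure = m,
                   node = sort(top_n_dense(centralities$node, centralities[[m]], n)))
  })
}

#' Plot a PPI network
#'
#' Base igraph layout plot with seeds and interactors distinguished by color.
#'
#' @param x A `ppi_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.ppi_network <- function(x, ...) {
  cols <- ifelse(x$nodes$role == "seed",
                 ifelse(x$nodes$regulation == "down", "#00798c", "#d1495b"),
                 "grey80")
  igraph::plot.igraph(x$graph, vertex.color = cols, vertex.size = 12,
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}
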