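#' Gene-set over-representation by one-sided Fisher exact test
#'
#' For each set in the library, builds the 2x2 table (in query & in set, in
#' query & not in set, not in query & in set, neither) against a fixed gene
#' universe and computes the one-sided over-representation p — the upper
#' hypergeometric tail \eqn{P(X \ge a)} with \eqn{X \sim
#' \mathrm{Hypergeom}(N, K, n)} where N is the universe size, K the set size in
#' the universe and n the query size. P-values are BH-adjusted within the
#' library (never pooled across libraries).
#'
#' Sets are intersected with the universe before testing; sets disjoint from
#' the universe are skipped with a warning. Results are independent of the
#' order of sets in the library.
#'
#' @param query_genes Character vector of query genes (must be a subset of the
#'   universe).
#' @param gene_sets Library as returned by [read_gmt()] (long tibble
#'   `set_name`/`description`/`gene`) or a named list of character vectors.
#' @param universe Character vector: the background gene universe. The
#'   recommended default universe is all genes present in the expression data
#'   after probe collapse.
#' @param enrich_alpha BH threshold for the `significant` flag.
#' @return Tibble with one row per tested set: `set_name`, `a`, `b`, `c`, `d`,
#'   `p`, `bh_p`, `significant`, and list-column `overlap_genes`.
#' @examples
#' uni <- paste0("g", 1:100)
#' res <- fisher_enrich(paste0("g", 1:10),
#'                      list(S1 = paste0("g", c(1, 2, 3, 50, 60))),
#'                      uni)
#' res$p  # ~ 0.00665
#' @export
fisher_enrich <- function(query_genes, gene_sets, universe, enrich_alpha = 0.05) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(query_genes) == 0L) stop("empty query", call. = FALSE)
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(gene_sets)) {
    lib_name <- attr(gene_sets, "library_name")
    gene_sets <- split(gene_sets$gene, gene_sets$set_name)
  } else {
    lib_name <- NULL
  }
  n_univ <- length(universe)
  n_query <- length(query_genes)

  rows <- purrr::imap(gene_sets, function(genes, nm) {
    set_in_univ <- intersect(unique(genes), universe)
    if (length(set_in_univ) == 0L) {
      warning(sprintf("set \"%s\" is disjoint from the universe; skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    overlap <- intersect(query_genes, set_in_univ)
    a <- length(overlap)
    b <- n_query - a
    cc <- length(set_in_univ) - a
    d <- n_univ - a - b - cc
    # upper tail P(X >= a), X ~ Hypergeom(N = n_univ, K = |set|, n = n_query)
    p <- stats::phyper(a - 1L, length(set_in_univ), n_univ - length(set_in_univ),
                       n_query, lower.tail = FALSE)
    tibble::tibble(set_name = nm, a = a, b = b, c = cc, d = d, p = p,
                   overlap_genes = list(sort(overlap)))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(set_name = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), p = numeric(),
                          overlap_genes = list(), bh_p = numeric(),
                          significant = logical())
    attr(res, "library_name") <- lib_name
    return(res)
  }
  res <- dplyr::arrange(res, .data$set_name)
  res$bh_p <- bh_adjust(res$p)
  res$significant <- res$bh_p < enrich_alpha
  attr(res, "library_name") <- lib_name
  res
}

#' Union of query genes found in significantly enriched sets
#'
#' Takes the enrichment results of one or more libraries and returns the union,
#' over all significant sets, of each set's overlap with the query — the gene
#' set that seeds the downstream PPI stage. When a `deg_screen` is supplied the
#' result carries each gene's regulation direction.
#'
#' @param results A single [fisher_enrich()] result or a list of them (one per
#'   library).
#' @param screen Optional [screen_degs()] result used to annotate direction.
#' @return Tibble with columns `gene` and `direction` (`up`, `down`, or `NA`
#'   when no screen is given). May have zero rows.
#' @export
enriched_union <- function(results, screen = NULL) {
  if (is.data.frame(results)) results <- list(results)
  genes <- results |>
    purrr::map(function(res) {
      if (nrow(res) == 0L) return(character())
      unlist(res$overlap_genes[res$significant])
    }) |>
    unlist() |>
    unique() |>
    sort()
  direction <- rep(NA_character_, length(genes))
  if (!is.null(screen)) {
    direction[genes %in% screen$up] <- "up"
    direction[genes %in% screen$down] <- "down"
  }
  tibble::tibble(gene = genes, direction = direction)
}

#' Gene-to-pathway membership table for significant sets
#'
#' Long table (one row per gene x significant set association), the tabular
#' content behind circos-style membership plots.
#'
#' @param results A [fisher_enrich()] result.
#' @return Tibble with columns `set_name`, `gene`.
#' @export
membership_table <- function(results) {
  if (nrow(results) == 0L || !any(results$significant)) {
    return(tibble::tibble(set_name = character(), gene = character()))
  }
  results |>
    dplyr::filter(.data$significant) |>
    dplyr::select("set_name", "overlap_genes") |>
    tidyr::unnest_longer("overlap_genes", values_to = "gene") |>
    dplyr::arrange(.data$set_name, .data$gene)
}
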