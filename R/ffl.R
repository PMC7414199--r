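#' Normalize a miRNA identifier to its species-free base name
#'
#' Strips a three-letter species prefix (`hsa-`, `mmu-`, ...) and lowercases,
#' so human and mouse forms of the same miRNA compare equal. The arm suffix
#' (`-5p` / `-3p`) is kept by default — the stricter identity — and can be
#' dropped with `keep_arm = FALSE`.
#'
#' @param x Character vector of miRNA identifiers.
#' @param keep_arm Keep the `-5p`/`-3p` arm suffix when comparing?
#' @return Character vector of base names.
#' @examples
#' mirna_base_name(c("hsa-miR-34b-5p", "mmu-miR-34b-5p"))
#' @export
mirna_base_name <- function(x, keep_arm = TRUE) {
  out <- tolower(sub("^[a-z]{3}-", "", x, ignore.case = TRUE))
  if (!keep_arm) out <- sub("-[35]p$", "", out)
  out
}

#' Filter typed regulatory edges by source-specific thresholds
#'
#' Applies each source dialect's retention rule and unions the survivors:
#' miRWalk-like edges need `score >= mirna_score_min`, a 3'-UTR binding region
#' and a binding gap of 1; miRSearch-like edges need the categorical
#' high-confidence flag; Starbase-like edges need `score >= mirna_score_min`;
#' ChIPBase-like TF edges need a binding site within `upstream_window_bp` of
#' the TSS; Enrichr-TF-like edges need `evidence_p < tf_p_max`; ITFP-like
#' edges are curated and kept as-is. Duplicate (source, target, type, species)
#' edges across dialects are merged with their provenance concatenated.
#'
#' @param edges Regulatory edge tibble as returned by [read_reg_edges()].
#' @param mirna_score_min Minimum miRNA-target score (inclusive).
#' @param tf_p_max Maximum TF-library evidence p (strict).
#' @param upstream_window_bp TF binding-site window in bp (inclusive).
#' @return Tibble of retained edges with columns `source`, `target`,
#'   `edge_type`, `species`, `dialects`.
#' @export
filter_reg_edges <- function(edges, mirna_score_min = 0.95, tf_p_max = 0.05,
                             upstream_window_bp = 1000) {
  edges <- validate_reg_edges(edges)
  col_or_na <- function(nm, default = NA) {
    if (nm %in% names(edges)) edges[[nm]] else rep(default, nrow(edges))
  }
  score <- col_or_na("score", NA_real_)
  region <- col_or_na("region", NA_character_)
  binding_gap <- col_or_na("binding_gap", NA_integer_)
  high_conf <- col_or_na("high_conf", NA)
  upstream_bp <- col_or_na("upstream_bp", NA_integer_)
  evidence_p <- col_or_na("evidence_p", NA_real_)

  keep <- dplyr::case_when(
    edges$dialect == "mirwalk" ~ score >= mirna_score_min & region == "3UTR" &
      binding_gap == 1L,
    edges$dialect == "mirsearch" ~ as.logical(high_conf),
    edges$dialect == "starbase" ~ score >= mirna_score_min,
    edges$dialect == "chipbase" ~ upstream_bp <= upstream_window_bp,
    edges$dialect == "itfp" ~ TRUE,
    edges$dialect == "enrichr_tf" ~ evidence_p < tf_p_max
  )
  edges[keep, ] |>
    dplyr::summarise(dialects = paste(sort(unique(.data$dialect)), collapse = ";"),
                     .by = c("source", "target", "edge_type", "species")) |>
    dplyr::arrange(.data$edge_type, .data$source, .data$target)
}

#' Human-mouse miRNA conservation filter
#'
#' A miRNA is "final" when its species-free base name appears as the source of
#' at least one filtered miRNA edge in both the human and the mouse edge sets.
#' All miRNA-to-gene and miRNA-to-TF edges from non-final miRNAs are pruned
#' from the human set; TF-to-gene edges are left untouched. The operation is
#' idempotent.
#'
#' @param human_edges,mouse_edges Filtered edge tibbles ([filter_reg_edges()]).
#' @param keep_arm Passed to [mirna_base_name()].
#' @return List with `final_mirnas` (tibble `mirna` / `base_name`, human
#'   identifiers) and `edges` (the pruned human edge set).
#' @export
conservation_filter <- function(human_edges, mouse_edges, keep_arm = TRUE) {
  is_mirna_edge <- function(e) e$edge_type %in% c("mirna_gene", "mirna_tf")
  h_mirnas <- unique(human_edges$source[is_mirna_edge(human_edges)])
  m_bases <- unique(mirna_base_name(
    mouse_edges$source[is_mirna_edge(mouse_edges)], keep_arm = keep_arm))
  h_bases <- mirna_base_name(h_mirnas, keep_arm = keep_arm)
  final <- h_mirnas[h_bases %in% m_bases]

  pruned <- human_edges |>
    dplyr::filter(!(.data$edge_type %in% c("mirna_gene", "mirna_tf")) |
                    .data$source %in% final)
  list(
    final_mirnas = tibble::tibble(
      mirna = sort(final),
      base_name = mirna_base_name(sort(final), keep_arm = keep_arm)
    ),
    edges = pruned
  )
}

#' Enumerate 3-node miRNA feed-forward loops
#'
#' A feed-forward loop is a triple (miRNA m, TF T, gene g) whose three edges
#' m->T (`mirna_tf`), m->g (`mirna_gene`) and T->g (`tf_gene`) are all present
#' in the edge set. The output is exactly that set of triples, sorted
#' lexicographically; it is invariant to edge order and to duplicate edges.
#'
#' @param edges Filtered (and typically conservation-pruned) edge tibble.
#' @return Tibble with columns `mirna`, `tf`, `gene`, one row per motif
#'   instance.
#' @export
enumerate_ffls <- function(edges) {
  ded <- dplyr::distinct(edges, .data$source, .data$target, .data$edge_type)
  mt <- ded |> dplyr::filter(.data$edge_type == "mirna_tf") |>
    dplyr::select(mirna = "source", tf = "target")
  tg <- ded |> dplyr::filter(.data$edge_type == "tf_gene") |>
    dplyr::select(tf = "source", gene = "target")
  mg <- ded |> dplyr::filter(.data$edge_type == "mirna_gene") |>
    dplyr::select(mirna = "source", gene = "target")
  mt |>
    dplyr::inner_join(tg, by = "tf", relationship = "many-to-many") |>
    dplyr::semi_join(mg, by = c("mirna", "gene")) |>
    dplyr::arrange(.data$mirna, .data$tf, .data$gene)
}

#' Build the merged feed-forward-loop network
#'
#' Merges the edges participating in at least one motif instance into a single
#' typed network and reports its composition: per-class node counts (miRNAs,
#' TFs, genes) and per-type edge counts, the identity behind the summary-table
#' layout `relationship x {edges, miRNAs, TFs, genes}`. Set
#' `include_all_edges = TRUE` to keep every filtered edge instead of only
#' motif-participating ones.
#'
#' @param ffls Motif table from [enumerate_ffls()].
#' @param edges The edge set the motifs were enumerated from.
#' @param include_all_edges Keep edges that belong to no motif?
#' @return An `ffl_network`: list with `ffls`, `nodes` (tibble `node`/`class`),
#'   `edges` (typed, deduplicated) and `graph` (undirected igraph projection).
#' @export
build_ffl_network <- function(ffls, edges, include_all_edges = FALSE) {
  ded <- dplyr::distinct(edges, .data$source, .data$target, .data$edge_type)
  if (!include_all_edges) {
    in_ffl <- dplyr::bind_rows(
      dplyr::distinct(ffls, source = .data$mirna, target = .data$tf) |>
        dplyr::mutate(edge_type = "mirna_tf"),
      dplyr::distinct(ffls, source = .data$mirna, target = .data$gene) |>
        dplyr::mutate(edge_type = "mirna_gene"),
      dplyr::distinct(ffls, source = .data$tf, target = .data$gene) |>
        dplyr::mutate(edge_type = "tf_gene")
    )
    ded <- dplyr::semi_join(ded, in_ffl, by = c("source", "target", "edge_type"))
  }
  ded <- dplyr::arrange(ded, .data$edge_type, .data$source, .data$target)
  mirnas <- sort(unique(c(ded$source[ded$edge_type %in% c("mirna_gene", "mirna_tf")])))
  tfs <- sort(unique(c(ded$target[ded$edge_type == "mirna_tf"],
                       ded$source[ded$edge_type == "tf_gene"])))
  genes <- sort(unique(ded$target[ded$edge_type %in% c("mirna_gene", "tf_gene")]))
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = mirnas, class = "mirna"),
    tibble::tibble(node = tfs, class = "tf"),
    tibble::tibble(node = genes, class = "gene")
  )
  if (anyDuplicated(nodes$node)) {
    stop("node appears in more than one class (miRNA/TF/gene); check edge types",
         call. = FALSE)
  }
  graph <- if (nrow(nodes) > 0) {
    igraph::graph_from_data_frame(ded[, c("source", "target")], directed = FALSE,
                                  vertices = nodes$node) |> igraph::simplify()
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(list(ffls = ffls, nodes = nodes, edges = ded, graph = graph),
            class = "ffl_network")
}

#' @export
print.ffl_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ffl_network: %d motifs; %d nodes (%d miRNAs, %d TFs, %d genes); %d edges (%d miRNA-gene, %d TF-gene, %d miRNA-TF)>\n",
              g$n_ffls, g$n_nodes, g$n_mirnas, g$n_tfs, g$n_genes,
              g$n_edges, g$n_mirna_gene, g$n_tf_gene, g$n_mirna_tf))
  invisible(x)
}

#' @describeIn build_ffl_network Typed edge tibble of the merged network.
#' @param x An `ffl_network`.
#' @param ... Unused.
#' @export
tidy.ffl_network <- function(x, ...) x$edges

#' @describeIn build_ffl_network One-row composition summary (node and edge
#'   counts overall, per class and per type).
#' @export
glance.ffl_network <- function(x, ...) {
  tibble::tibble(
    n_ffls = nrow(x$ffls),
    n_nodes = nrow(x$nodes),
    n_mirnas = sum(x$nodes$class == "mirna"),
    n_tfs = sum(x$nodes$class == "tf"),
    n_genes = sum(x$nodes$class == "gene"),
    n_edges = nrow(x$edges),
    n_mirna_gene = sum(x$edges$edge_type == "mirna_gene"),
    n_tf_gene = sum(x$edges$edge_type == "tf_gene"),
    n_mirna_tf = sum(x$edges$edge_type == "mirna_tf")
  )
}

#' Relationship summary table of an FFL network
#'
#' One row per relationship type with its edge count and the numbers of
#' miRNAs, TFs and genes involved in edges of that type.
#'
#' @param network An `ffl_network`.
#' @return Tibble with columns `relationship`, `n_edges`, `n_mirnas`, `n_tfs`,
#'   `n_genes`.
#' @export
ffl_summary_table <- function(network) {
  e <- network$edges
  row_for <- function(type, label) {
    sub <- e[e$edge_type == type, ]
    tibble::tibble(
      relationship = label,
      n_edges = nrow(sub),
      n_mirnas = if (type == "tf_gene") NA_integer_ else length(unique(sub$source)),
      n_tfs = dplyr::case_when(type == "mirna_tf" ~ length(unique(sub$target)),
                               type == "tf_gene" ~ length(unique(sub$source)),
                               TRUE ~ NA_integer_),
      n_genes = if (type == "mirna_tf") NA_integer_ else length(unique(sub$target))
    )
  }
  dplyr::bind_rows(
    row_for("mirna_gene", "miRNA-gene"),
    row_for("tf_gene", "TF-gene"),
    row_for("mirna_tf", "miRNA-TF")
  )
}

#' Export an FFL network to GraphML
#'
#' @param network An `ffl_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(name = network$nodes$node, class = network$nodes$class)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
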