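#' Run the full analysis pipeline on a directory of inputs
#'
#' Chains the five analysis stages — differential-expression meta-analysis,
#' gene-set over-representation, PPI hub calling on the up- and down-regulated
#' networks, feed-forward-loop mining with the human-mouse conservation
#' filter, and merged-network topology statistics — and writes one primary
#' tab-separated report per stage plus a manifest to `out_dir`. Output is a
#' pure function of (inputs, config): rerunning with the same `rng_seed`
#' reproduces every report byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param inputs Either a directory containing the standard input file names
#'   (as written by [write_synthetic_inputs()]) or a named list of paths with
#'   elements `expression`, `annotation`, `gmt` (character vector), both PPI
#'   tables `ppi_biogrid` / `ppi_hippie`, `reg_human`, `reg_mouse`, and
#'   optionally `probe_map`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log messages?
#' @return Invisibly, a list with the in-memory stage results (`deg_table`,
#'   `screen`, `enrichment`, `seeds`, `hubs`, `ffl_network`, `topology`) and
#'   the `manifest` tibble.
#' @export
run_pipeline <- function(config, inputs, out_dir, quiet = FALSE) {
  validate_config(config)
  if (is.character(inputs) && length(inputs) == 1L) {
    d <- inputs
    inputs <- list(
      expression = file.path(d, "expression.tsv"),
      annotation = file.path(d, "annotation.tsv"),
      probe_map = file.path(d, "probe_map.tsv"),
      gmt = Sys.glob(file.path(d, "*.gmt")),
      ppi_biogrid = file.path(d, "ppi_biogrid.tsv"),
      ppi_hippie = file.path(d, "ppi_hippie.tsv"),
      reg_human = file.path(d, "reg_human.tsv"),
      reg_mouse = file.path(d, "reg_mouse.tsv")
    )
    if (!file.exists(inputs$probe_map)) inputs$probe_map <- NULL
  }
  need <- c("expression", "annotation", "gmt", "ppi_biogrid", "ppi_hippie",
            "reg_human", "reg_mouse")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in) > 0) {
    stop("missing input(s): ", paste(missing_in, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage \"%s\" failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list()
  record <- function(stage_name, file, n) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage_name, report = basename(file), n_records = n)
  }

  ## stage 1: DEG meta-analysis -----------------------------------------------
  res_deg <- stage("meta_deg", {
    studies <- read_expression(inputs$expression, inputs$annotation)
    if (!is.null(inputs$probe_map)) {
      pm <- read_tsv_quiet(inputs$probe_map)
      studies <- lapply(studies, collapse_probes, probe_map = pm)
    }
    deg <- meta_deg(studies, test_mode = config$test_mode)
    scr <- screen_degs(deg, config$de_alpha, config$lfc_cut)
    list(deg = deg, screen = scr,
         universe = deg$gene)
  })
  deg_path <- file.path(out_dir, "01_deg_table.tsv")
  readr::write_tsv(tibble::as_tibble(res_deg$deg), deg_path, progress = FALSE)
  record("meta_deg", deg_path, nrow(res_deg$deg))
  log_line("stage meta_deg: %d genes in, %d up / %d down DEGs out",
           nrow(res_deg$deg), length(res_deg$screen$up), length(res_deg$screen$down))

  ## stage 2: over-representation ---------------------------------------------
  res_enr <- stage("enrichment", {
    query <- c(res_deg$screen$up, res_deg$screen$down)
    if (length(inputs$gmt) == 0L) stop("no GMT gene-set libraries supplied")
    libs <- lapply(inputs$gmt, read_gmt)
    results <- lapply(libs, function(lib) {
      fisher_enrich(query, lib, res_deg$universe,
                    enrich_alpha = config$enrich_alpha)
    })
    names(results) <- vapply(libs, attr, character(1), "library_name")
    seeds <- enriched_union(results, res_deg$screen)
    list(results = results, seeds = seeds)
  })
  enr_tab <- purrr::imap_dfr(res_enr$results, function(res, lib) {
    if (nrow(res) == 0L) return(NULL)
    res |>
      dplyr::mutate(library = lib,
                    overlap_genes = vapply(.data$overlap_genes, paste,
                                           character(1), collapse = ";")) |>
      dplyr::relocate("library")
  })
  enr_path <- file.path(out_dir, "02_enrichment.tsv")
  readr::write_tsv(enr_tab, enr_path, progress = FALSE)
  record("enrichment", enr_path, nrow(enr_tab))
  n_sig <- if ("significant" %in% names(enr_tab)) sum(enr_tab$significant) else 0L
  log_line("stage enrichment: %d sets tested, %d significant, %d seed genes",
           nrow(enr_tab), n_sig, nrow(res_enr$seeds))

  ## stage 3: PPI networks and hub calling ------------------------------------
  res_ppi <- stage("ppi_hubs", {
    biogrid <- read_ppi_table(inputs$ppi_biogrid)
    hippie <- read_ppi_table(inputs$ppi_hippie)
    one_side <- function(direction, seed_offset) {
      seeds <- res_enr$seeds$gene[res_enr$seeds$direction == direction]
      if (length(seeds) == 0L) return(NULL)
      net <- build_ppi(res_enr$seeds[res_enr$seeds$direction == direction, ],
                       biogrid, hippie,
                       hippie_min_score = config$hippie_min_score)
      cent <- compute_centralities(
        net, epc_reps = config$epc_reps, epc_retain_p = config$epc_retain_p,
        rng_seed = (config$rng_seed + seed_offset) %% 2147483647L)
      n <- if (config$top_n_mode == "explicit") {
        if (direction == "up") config$top_n_up else config$top_n_down
      } else {
        length(seeds)
      }
      list(network = net, centralities = cent,
           hubs = identify_hubs(cent, n, seeds = seeds))
    }
    list(up = one_side("up", 1L), down = one_side("down", 2L))
  })
  cent_tab <- purrr::imap_dfr(res_ppi[!vapply(res_ppi, is.null, logical(1))],
                              function(side, nm) {
                                dplyr::mutate(side$centralities, network = nm,
                                              .before = 1)
                              })
  hubs <- sort(unique(c(res_ppi$up$hubs, res_ppi$down$hubs)))
  cent_path <- file.path(out_dir, "03_centralities.tsv")
  readr::write_tsv(cent_tab, cent_path, progress = FALSE)
  readr::write_tsv(tibble::tibble(hub = hubs),
                   file.path(out_dir, "03_hubs.tsv"), progress = FALSE)
  record("ppi_hubs", cent_path, nrow(cent_tab))
  log_line("stage ppi_hubs: %d network nodes ranked, %d hub genes",
           nrow(cent_tab), length(hubs))

  ## stage 4: FFL mining ------------------------------------------------------
  res_ffl <- stage("ffl_mining", {
    human <- filter_reg_edges(read_reg_edges(inputs$reg_human),
                              mirna_score_min = config$mirna_score_min,
                              tf_p_max = config$tf_p_max,
                              upstream_window_bp = config$upstream_window_bp)
    mouse <- filter_reg_edges(read_reg_edges(inputs$reg_mouse),
                              mirna_score_min = config$mirna_score_min,
                              tf_p_max = config$tf_p_max,
                              upstream_window_bp = config$upstream_window_bp)
    cons <- conservation_filter(human, mouse)
    # the gene class of the motif search is the hub-gene set
    edges <- cons$edges |>
      dplyr::filter(.data$edge_type == "mirna_tf" | .data$target %in% hubs)
    ffls <- enumerate_ffls(edges)
    build_ffl_network(ffls, edges)
  })
  ffl_path <- file.path(out_dir, "04_ffl_motifs.tsv")
  readr::write_tsv(res_ffl$ffls, ffl_path, progress = FALSE)
  readr::write_tsv(ffl_summary_table(res_ffl),
                   file.path(out_dir, "04_ffl_summary.tsv"), progress = FALSE)
  readr::write_tsv(res_ffl$edges, file.path(out_dir, "04_ffl_edges.tsv"),
                   progress = FALSE)
  record("ffl_mining", ffl_path, nrow(res_ffl$ffls))
  log_line("stage ffl_mining: %d motifs over %d nodes / %d edges",
           nrow(res_ffl$ffls), nrow(res_ffl$nodes), nrow(res_ffl$edges))

  ## stage 5: topology statistics ---------------------------------------------
  res_topo <- stage("topology", {
    if (nrow(res_ffl$nodes) == 0L) stop("merged FFL network is empty")
    topology_stats(res_ffl)
  })
  topo_path <- file.path(out_dir, "05_topology_nodes.tsv")
  readr::write_tsv(res_topo$node_stats, topo_path, progress = FALSE)
  readr::write_tsv(glance(res_topo), file.path(out_dir, "05_topology_summary.tsv"),
                   progress = FALSE)
  record("topology", topo_path, nrow(res_topo$node_stats))
  log_line("stage topology: %d nodes, power-law slope %.3f",
           nrow(res_topo$node_stats), res_topo$power_law$slope)

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  invisible(list(
    deg_table = res_deg$deg, screen = res_deg$screen,
    enrichment = res_enr$results, seeds = res_enr$seeds,
    centralities = cent_tab, hubs = hubs,
    ffl_network = res_ffl, topology = res_topo, manifest = manifest
  ))
}
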