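#' Specification for the synthetic data generator
#'
#' Fixes every parameter of the synthetic inputs: a two-study expression
#' experiment with planted differentially expressed genes, a scale-free-like
#' PPI layer around seed genes, and a tripartite miRNA/TF/gene regulatory
#' layer with planted feed-forward loops, matched human/mouse versions and
#' decoy edges. Defaults are the package's reference study conditions: 500
#' genes, 25 up- and 25 down-regulated planted at an additive log2 effect of
#' 1.5 with Gaussian noise SD 0.5, two studies of 10 cases vs 10 controls,
#' and a regulatory layer at the scale of the asthma network (26 miRNAs, 20
#' TFs, 5 target genes).
#'
#' @param n_genes Number of genes per study.
#' @param n_case,n_control Per-study sample counts (each >= 2).
#' @param n_studies Number of studies sharing the planted genes.
#' @param n_de_up,n_de_down Planted up-/down-regulated gene counts.
#' @param effect_lfc Additive log2 effect magnitude on case means.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param ppi_extra_partners Mean interactors per seed gene in the PPI layer.
#' @param n_mirna,n_tf,n_target_genes Regulatory-layer node counts.
#' @param n_planted_ffl Number of planted 3-node feed-forward loops.
#' @param decoy_edge_frac Decoy edges as a fraction of planted edges.
#' @param conserved_frac Fraction of human miRNAs mirrored in the mouse set
#'   (a conserved miRNA has all its edges mirrored).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 500, n_case = 10, n_control = 10,
                           n_studies = 2, n_de_up = 25, n_de_down = 25,
                           effect_lfc = 1.5, noise_sd = 0.5,
                           ppi_extra_partners = 4,
                           n_mirna = 26, n_tf = 20, n_target_genes = 5,
                           n_planted_ffl = 10, decoy_edge_frac = 0.3,
                           conserved_frac = 1, seed = 7L) {
  spec <- structure(
    list(n_genes = n_genes, n_case = n_case, n_control = n_control,
         n_studies = n_studies, n_de_up = n_de_up, n_de_down = n_de_down,
         effect_lfc = effect_lfc, noise_sd = noise_sd,
         ppi_extra_partners = ppi_extra_partners,
         n_mirna = n_mirna, n_tf = n_tf, n_target_genes = n_target_genes,
         n_planted_ffl = n_planted_ffl, decoy_edge_frac = decoy_edge_frac,
         conserved_frac = conserved_frac, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  counts <- c("n_genes", "n_case", "n_control", "n_studies", "n_de_up",
              "n_de_down", "n_mirna", "n_tf", "n_target_genes", "n_planted_ffl")
  for (nm in counts) {
    if (spec[[nm]] < 0) stop("synthetic_spec: `", nm, "` must be >= 0", call. = FALSE)
  }
  if (spec$n_de_up + spec$n_de_down > spec$n_genes) {
    stop("synthetic_spec: n_de_up + n_de_down must not exceed n_genes", call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("synthetic_spec: noise_sd must be > 0", call. = FALSE)
  for (nm in c("decoy_edge_frac", "conserved_frac")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) {
      stop("synthetic_spec: `", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (spec$ppi_extra_partners < 0) {
    stop("synthetic_spec: ppi_extra_partners must be >= 0", call. = FALSE)
  }
  if (spec$n_planted_ffl > spec$n_mirna * spec$n_tf * spec$n_target_genes) {
    stop("synthetic_spec: n_planted_ffl exceeds the number of possible triples",
         call. = FALSE)
  }
  spec
}

planted_gene_names <- function(spec) {
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  list(genes = genes,
       up = genes[seq_len(spec$n_de_up)],
       down = genes[spec$n_de_up + seq_len(spec$n_de_down)])
}

#' Simulate multi-study expression data with planted DE genes
#'
#' Baseline per-gene means are drawn once from Normal(7, 2) on the log2 scale
#' (a typical post-normalization intensity range) and shared across studies.
#' Planted up/down genes get `+effect_lfc` / `-effect_lfc` added to their case
#' means in every study; i.i.d. Gaussian noise with SD `noise_sd` is added to
#' every value. Sample identifiers are disjoint across studies.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `studies` (list of [expression_study()]) and `truth`
#'   (tibble `gene` / `direction` of the planted genes).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_case < 2 || spec$n_control < 2) {
    stop("need n_case >= 2 and n_control >= 2 (downstream variance undefined)",
         call. = FALSE)
  }
  nm <- planted_gene_names(spec)
  withr::with_seed(spec$seed, {
    baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 2)
    studies <- lapply(seq_len(spec$n_studies), function(k) {
      id <- paste0("study", k)
      n_s <- spec$n_case + spec$n_control
      group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
      mu <- matrix(baseline, spec$n_genes, n_s)
      shift <- numeric(spec$n_genes)
      shift[nm$genes %in% nm$up] <- spec$effect_lfc
      shift[nm$genes %in% nm$down] <- -spec$effect_lfc
      mu[, group == "case"] <- mu[, group == "case"] + shift
      vals <- mu + matrix(stats::rnorm(spec$n_genes * n_s, sd = spec$noise_sd),
                          spec$n_genes, n_s)
      dimnames(vals) <- list(nm$genes, paste0(id, "_", group, "_",
                                              c(seq_len(spec$n_case),
                                                seq_len(spec$n_control))))
      expression_study(id, vals, group)
    })
    names(studies) <- vapply(studies, function(s) s$study_id, character(1))
    truth <- tibble::tibble(gene = c(nm$up, nm$down),
                            direction = rep(c("up", "down"),
                                            c(spec$n_de_up, spec$n_de_down)))
    list(studies = studies, truth = truth)
  })
}

#' Simulate BioGRID-like and HIPPIE-like PPI tables around seed genes
#'
#' The first seed gene is wired to every other seed with high-confidence edges
#' (present in both tables), giving the layer a clear central hub; every seed
#' additionally receives its own interactor partners (on average
#' `ppi_extra_partners` each, at least one when the mean is positive). Partner
#' edges are split between the two dialects with HIPPIE-like scores drawn
#' uniformly on \[0, 1\] and BioGRID-like evidence counts drawn from a Poisson,
#' so a subset of edges deliberately falls below the downstream filters.
#'
#' @param seed_genes Character vector of seed genes (non-empty).
#' @param spec A [synthetic_spec()].
#' @param rng_seed Optional seed override (defaults to `spec$seed`).
#' @return List with tibbles `biogrid` (`partner_a`, `partner_b`,
#'   `evidence_count`) and `hippie` (`partner_a`, `partner_b`, `score`).
#' @export
simulate_ppi <- function(seed_genes, spec, rng_seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(seed_genes) == 0L) stop("seed_genes must be non-empty", call. = FALSE)
  seed <- if (is.null(rng_seed)) spec$seed else rng_seed
  withr::with_seed(seed, {
    biogrid <- list(); hippie <- list()
    if (length(seed_genes) > 1L) {
      spine <- tibble::tibble(partner_a = seed_genes[1], partner_b = seed_genes[-1])
      biogrid$spine <- dplyr::mutate(spine, evidence_count = 2L)
      hippie$spine <- dplyr::mutate(spine,
                                    score = round(stats::runif(nrow(spine), 0.8, 0.99), 3))
    }
    mean_part <- spec$ppi_extra_partners
    # the central seed keeps only its spine so the satellite seeds' leaf
    # partners stay clearly below every seed on all centralities
    satellite <- if (length(seed_genes) > 1L) seed_genes[-1] else seed_genes
    for (gene in satellite) {
      n_part <- if (mean_part > 0) 1L + stats::rpois(1, max(mean_part - 1, 0)) else 0L
      if (n_part == 0L) next
      partners <- sprintf("INT_%s_%02d", gene, seq_len(n_part))
      tab <- tibble::tibble(partner_a = gene, partner_b = partners)
      # first partner always passes the evidence filter; the rest draw random
      # scores and deliberately exercise the downstream thresholds
      biogrid[[paste0("g", gene)]] <- tab[1, ] |>
        dplyr::mutate(evidence_count = 1L + stats::rpois(1, 0.5))
      if (n_part > 1L) {
        rest <- tab[-1, ]
        to_biogrid <- stats::runif(n_part - 1L) < 0.5
        if (any(to_biogrid)) {
          biogrid[[paste0("b", gene)]] <- rest[to_biogrid, ] |>
            dplyr::mutate(evidence_count = stats::rpois(sum(to_biogrid), 1.2))
        }
        if (any(!to_biogrid)) {
          hippie[[paste0("h", gene)]] <- rest[!to_biogrid, ] |>
            dplyr::mutate(score = round(stats::runif(sum(!to_biogrid)), 3))
        }
      }
    }
    empty_bg <- tibble::tibble(partner_a = character(), partner_b = character(),
                               evidence_count = integer())
    empty_hp <- tibble::tibble(partner_a = character(), partner_b = character(),
                               score = numeric())
    list(biogrid = if (length(biogrid)) dplyr::bind_rows(biogrid) else empty_bg,
         hippie = if (length(hippie)) dplyr::bind_rows(hippie) else empty_hp)
  })
}

reg_edge_row <- function(source, target, edge_type, species, dialect,
                         passing = TRUE) {
  is_mirna <- edge_type %in% c("mirna_gene", "mirna_tf")
  tibble::tibble(
    source = source, target = target, edge_type = edge_type, species = species,
    dialect = dialect,
    score = dplyr::case_when(dialect %in% c("mirwalk", "starbase") & passing ~ 0.99,
                             dialect %in% c("mirwalk", "starbase") ~ 0.80,
                             TRUE ~ NA_real_),
    region = dplyr::case_when(dialect == "mirwalk" & passing ~ "3UTR",
                              dialect == "mirwalk" ~ "CDS",
                              TRUE ~ NA_character_),
    binding_gap = ifelse(dialect == "mirwalk", 1L, NA_integer_),
    high_conf = ifelse(dialect == "mirsearch", passing, NA),
    upstream_bp = dplyr::case_when(dialect == "chipbase" & passing ~ 500L,
                                   dialect == "chipbase" ~ 5000L,
                                   TRUE ~ NA_integer_),
    evidence_p = dplyr::case_when(dialect == "enrichr_tf" & passing ~ 0.01,
                                  dialect == "enrichr_tf" ~ 0.2,
                                  TRUE ~ NA_real_)
  )
}

#' Simulate human and mouse regulatory edge tables with planted FFLs
#'
#' Plants `n_planted_ffl` distinct (miRNA, TF, gene) triples, each contributing
#' its three edges (miRNA->TF, miRNA->gene, TF->gene) with metadata that passes
#' the source-specific filters. Decoy edges are then added — half with failing
#' metadata to exercise the filters, half passing but sampled with rejection so
#' they never complete an unplanted motif (disable with
#' `allow_accidental_ffls = TRUE`). A `conserved_frac` fraction of the human
#' miRNAs (always including the planted ones first) is mirrored into the mouse
#' set with an `mmu-` species prefix.
#'
#' @param spec A [synthetic_spec()].
#' @param genes Optional character vector of target gene names (defaults to
#'   `GENE01`, ..., of length `n_target_genes`).
#' @param allow_accidental_ffls Skip the rejection step for decoy edges?
#' @return List with tibbles `human`, `mouse` and `truth_ffls` (`mirna`, `tf`,
#'   `gene`).
#' @export
simulate_regulatory <- function(spec, genes = NULL, allow_accidental_ffls = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mirnas <- sprintf("hsa-miR-%d-5p", 100 + seq_len(spec$n_mirna))
  tfs <- sprintf("TF%02d", seq_len(spec$n_tf))
  if (is.null(genes)) genes <- sprintf("GENE%02d", seq_len(spec$n_target_genes))
  if (length(genes) != spec$n_target_genes) {
    stop("`genes` must have length n_target_genes", call. = FALSE)
  }
  withr::with_seed(spec$seed + 1L, {
    triples <- expand.grid(m = mirnas, t = tfs, g = genes,
                           stringsAsFactors = FALSE)
    planted <- triples[sample.int(nrow(triples), spec$n_planted_ffl), ]
    mt <- unique(planted[, c("m", "t")])
    mg <- unique(planted[, c("m", "g")])
    tg <- unique(planted[, c("t", "g")])
    human <- dplyr::bind_rows(
      reg_edge_row(mt$m, mt$t, "mirna_tf", "human", "mirwalk"),
      reg_edge_row(mg$m, mg$g, "mirna_gene", "human", "mirwalk"),
      reg_edge_row(tg$t, tg$g, "tf_gene", "human", "chipbase")
    )

    has_edge <- function(tab, s, t, type) {
      any(tab$source == s & tab$target == t & tab$edge_type == type)
    }
    completes_new_ffl <- function(tab, s, t, type) {
      if (type == "mirna_tf") {
        gs <- tab$target[tab$edge_type == "tf_gene" & tab$source == t]
        any(vapply(gs, function(g) has_edge(tab, s, g, "mirna_gene"), logical(1)))
      } else if (type == "mirna_gene") {
        ts <- tab$source[tab$edge_type == "tf_gene" & tab$target == t]
        any(vapply(ts, function(tf) has_edge(tab, s, tf, "mirna_tf"), logical(1)))
      } else {
        ms <- tab$source[tab$edge_type == "mirna_tf" & tab$target == s]
        any(vapply(ms, function(m) has_edge(tab, m, t, "mirna_gene"), logical(1)))
      }
    }
    n_decoy <- round(spec$decoy_edge_frac * 3 * spec$n_planted_ffl)
    added <- 0L; tries <- 0L
    while (added < n_decoy && tries < 50L * max(n_decoy, 1L)) {
      tries <- tries + 1L
      type <- sample(c("mirna_tf", "mirna_gene", "tf_gene"), 1)
      s <- switch(type, mirna_tf = sample(mirnas, 1), mirna_gene = sample(mirnas, 1),
                  tf_gene = sample(tfs, 1))
      t <- switch(type, mirna_tf = sample(tfs, 1), mirna_gene = sample(genes, 1),
                  tf_gene = sample(genes, 1))
      if (has_edge(human, s, t, type)) next
      passing <- added %% 2L == 0L
      if (passing && !allow_accidental_ffls && completes_new_ffl(human, s, t, type)) next
      dialect <- if (type == "tf_gene") {
        sample(c("chipbase", "enrichr_tf"), 1)
      } else {
        sample(c("mirwalk", "mirsearch", "starbase"), 1)
      }
      human <- dplyr::bind_rows(human, reg_edge_row(s, t, type, "human", dialect,
                                                    passing = passing))
      added <- added + 1L
    }

    used_mirnas <- unique(human$source[human$edge_type != "tf_gene"])
    planted_mirnas <- unique(planted$m)
    n_cons <- ceiling(spec$conserved_frac * length(used_mirnas))
    conserved <- unique(c(planted_mirnas, used_mirnas))[seq_len(n_cons)]
    mouse <- human |>
      dplyr::filter(.data$edge_type != "tf_gene", .data$source %in% conserved) |>
      dplyr::mutate(source = sub("^hsa-", "mmu-", .data$source),
                    species = "mouse")

    list(human = human, mouse = mouse,
         truth_ffls = tibble::tibble(mirna = planted$m, tf = planted$t,
                                     gene = planted$g) |>
           dplyr::arrange(.data$mirna, .data$tf, .data$gene))
  })
}

#' Deterministic regulatory layer reproducing an exact composition
#'
#' Constructs a tripartite regulatory edge set with exact per-class node counts
#' and per-type edge counts in which every edge participates in at least one
#' feed-forward loop — so the merged motif network reports exactly the
#' requested composition. The defaults are the asthma-network composition:
#' 26 miRNAs, 20 TFs, 5 genes with 32 miRNA-gene, 21 TF-gene and 144 miRNA-TF
#' edges (51 nodes, 197 edges in total).
#'
#' The layout is constructive: one "dense" gene is targeted by every miRNA and
#' by `n_tf - (n_gene - 1)` dense TFs; each remaining gene gets one satellite
#' TF and one supporting miRNA; surplus miRNA-gene and TF-gene edges are
#' routed through a designated dense TF; the remaining miRNA-TF budget is
#' filled over the miRNA x dense-TF grid in diagonal order, which covers every
#' miRNA and every dense TF. Infeasible count combinations raise an error
#' explaining the violated constraint.
#'
#' @param n_mirna,n_tf,n_gene Node counts per class.
#' @param n_mirna_gene,n_tf_gene,n_mirna_tf Per-type edge counts.
#' @param genes Optional gene names (length `n_gene`).
#' @return List with `human` and `mouse` edge tibbles (mouse mirrors every
#'   miRNA edge) — ready for [filter_reg_edges()] and downstream mining.
#' @export
simulate_regulatory_exact <- function(n_mirna = 26, n_tf = 20, n_gene = 5,
                                      n_mirna_gene = 32, n_tf_gene = 21,
                                      n_mirna_tf = 144, genes = NULL) {
  mirnas <- sprintf("hsa-miR-%d-5p", 100 + seq_len(n_mirna))
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  if (is.null(genes)) genes <- sprintf("GENE%02d", seq_len(n_gene))
  n_sat <- n_gene - 1                       # satellite genes g2..g_n
  n_dense_tf <- n_tf - n_sat                # TFs targeting the dense gene g1
  if (n_dense_tf < 1) {
    stop("infeasible: need n_tf >= n_gene (one satellite TF per extra gene ",
         "plus >=1 dense TF)", call. = FALSE)
  }
  extras_tg <- n_tf_gene - n_tf
  if (extras_tg < 0) {
    stop("infeasible: n_tf_gene < n_tf leaves some TF without a gene edge, ",
         "so it cannot join any FFL", call. = FALSE)
  }
  extras_mg <- n_mirna_gene - n_mirna - n_sat
  if (extras_mg < 0) {
    stop("infeasible: need n_mirna_gene >= n_mirna + n_gene - 1 so every ",
         "miRNA and every satellite gene is covered", call. = FALSE)
  }
  if (extras_tg > extras_mg) {
    stop("infeasible: surplus TF-gene edges (", extras_tg, ") exceed surplus ",
         "miRNA-gene edges (", extras_mg, ") available to support them", call. = FALSE)
  }
  if (extras_tg > n_sat) {
    stop("infeasible: surplus TF-gene edges (", extras_tg, ") exceed the ",
         n_sat, " satellite gene(s) they can target", call. = FALSE)
  }
  if (extras_mg > 0 && n_sat < 1) {
    stop("infeasible: surplus miRNA-gene edges need >=2 genes (duplicates of ",
         "the dense-gene edges are not allowed)", call. = FALSE)
  }
  if (n_mirna < n_sat + extras_mg) {
    stop("infeasible: not enough miRNAs to support the satellite genes and ",
         "surplus edges", call. = FALSE)
  }
  dense_gene <- genes[1]
  sat_genes <- genes[-1]
  dense_tfs <- tfs[seq_len(n_dense_tf)]
  sat_tfs <- if (n_sat > 0) tfs[n_dense_tf + seq_len(n_sat)] else character()
  anchor_tf <- dense_tfs[n_dense_tf]        # carries the surplus TF-gene edges

  # TF-gene: dense TFs -> g1, one satellite TF per satellite gene, surplus via
  # the anchor TF into the first surplus genes (g2, g3, ...)
  tg <- dplyr::bind_rows(
    tibble::tibble(source = dense_tfs, target = dense_gene),
    if (n_sat > 0) tibble::tibble(source = sat_tfs, target = sat_genes),
    if (extras_tg > 0) tibble::tibble(source = anchor_tf,
                                      target = sat_genes[seq_len(extras_tg)])
  )
  # miRNA-gene: every miRNA -> g1; satellite support m_k -> g_{k+1}; surplus
  # miRNAs -> the anchor TF's surplus gene (g2)
  surplus_mirnas <- if (extras_mg > 0) mirnas[n_sat + seq_len(extras_mg)] else character()
  mg <- dplyr::bind_rows(
    tibble::tibble(source = mirnas, target = dense_gene),
    if (n_sat > 0) tibble::tibble(source = mirnas[seq_len(n_sat)], target = sat_genes),
    if (extras_mg > 0) tibble::tibble(source = surplus_mirnas, target = sat_genes[1])
  )
  # miRNA-TF special edges: satellite support, plus surplus support through a
  # TF that targets the surplus gene (the anchor TF when it carries surplus
  # TF-gene edges, otherwise the first satellite TF)
  support_tf <- if (extras_tg > 0) anchor_tf else if (n_sat > 0) sat_tfs[1] else anchor_tf
  mt_special <- dplyr::bind_rows(
    if (n_sat > 0) tibble::tibble(source = mirnas[seq_len(n_sat)], target = sat_tfs),
    if (extras_mg > 0) tibble::tibble(source = surplus_mirnas, target = support_tf)
  )
  n_fill <- n_mirna_tf - nrow(mt_special)
  if (n_fill < max(n_mirna, n_dense_tf)) {
    stop("infeasible: n_mirna_tf too small to cover every miRNA and every ",
         "dense TF after the ", nrow(mt_special), " support edges", call. = FALSE)
  }
  grid_cap <- n_mirna * n_dense_tf -
    (if (identical(support_tf, anchor_tf)) length(surplus_mirnas) else 0L)
  if (n_fill > grid_cap) {
    stop("infeasible: n_mirna_tf exceeds the miRNA x dense-TF grid capacity (",
         grid_cap + nrow(mt_special), " total)", call. = FALSE)
  }
  # diagonal fill of the miRNA x dense-TF grid: index k -> (k mod n_mirna,
  # k mod n_dense_tf); distinct pairs for k < lcm, covering every row and
  # column within the first max(n_mirna, n_dense_tf) steps
  used <- paste(mt_special$source, mt_special$target)
  fill <- tibble::tibble(source = character(n_fill), target = character(n_fill))
  k <- 0L; taken <- 0L
  seen <- character(0)
  while (taken < n_fill) {
    s <- mirnas[(k %% n_mirna) + 1L]
    t <- dense_tfs[(k %% n_dense_tf) + 1L]
    k <- k + 1L
    key <- paste(s, t)
    if (key %in% used || key %in% seen) next
    taken <- taken + 1L
    seen <- c(seen, key)
    fill$source[taken] <- s; fill$target[taken] <- t
  }
  mt <- dplyr::bind_rows(mt_special, fill)

  human <- dplyr::bind_rows(
    reg_edge_row(mg$source, mg$target, "mirna_gene", "human", "mirwalk"),
    reg_edge_row(tg$source, tg$target, "tf_gene", "human", "chipbase"),
    reg_edge_row(mt$source, mt$target, "mirna_tf", "human", "mirwalk")
  )
  mouse <- human |>
    dplyr::filter(.data$edge_type != "tf_gene") |>
    dplyr::mutate(source = sub("^hsa-", "mmu-", .data$source), species = "mouse")
  list(human = human, mouse = mouse)
}

#' Simulate GMT gene-set libraries enriched for planted genes
#'
#' Builds one library whose sets are stacked with planted genes (so an
#' over-representation test on the recovered DEG list flags them) plus decoy
#' sets of background genes.
#'
#' @param truth Ground-truth tibble from [simulate_expression()].
#' @param universe All gene names in the expression data.
#' @param n_signal_sets,n_decoy_sets Set counts.
#' @param set_size Genes per set.
#' @param rng_seed Seed.
#' @return Long gene-set tibble as from [read_gmt()].
#' @export
simulate_gene_sets <- function(truth, universe, n_signal_sets = 4,
                               n_decoy_sets = 6, set_size = 25, rng_seed = 11L) {
  background <- setdiff(universe, truth$gene)
  withr::with_seed(rng_seed, {
    planted_pool <- split(truth$gene,
                          rep(seq_len(n_signal_sets), length.out = nrow(truth)))
    sets <- purrr::imap_dfr(planted_pool, function(g, i) {
      n_bg <- min(max(set_size - length(g), 0), length(background))
      tibble::tibble(
        set_name = sprintf("signal_set_%02d", as.integer(i)),
        description = "planted-gene set",
        gene = c(g, sample(background, n_bg))
      )
    })
    decoys <- purrr::map_dfr(seq_len(n_decoy_sets), function(i) {
      tibble::tibble(set_name = sprintf("decoy_set_%02d", i),
                     description = "background set",
                     gene = sample(background, min(set_size, length(background))))
    })
    out <- dplyr::bind_rows(sets, decoys)
    attr(out, "library_name") <- "synthetic_pathways"
    out
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates every file the pipeline consumes — expression matrix, sample
#' annotation, probe map, two GMT libraries, BioGRID-like and HIPPIE-like PPI
#' tables, human and mouse regulatory edge tables — plus ground-truth tables
#' (planted DE genes and planted motifs) that only tests may read.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written, invisibly.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  expr <- simulate_expression(spec)
  write_expression(expr$studies, p("expression.tsv"), p("annotation.tsv"))
  genes <- rownames(expr$studies[[1]]$values)
  readr::write_tsv(tibble::tibble(probe = genes, gene = genes),
                   p("probe_map.tsv"), progress = FALSE)
  readr::write_tsv(expr$truth, p("truth_de.tsv"), progress = FALSE)

  sets1 <- simulate_gene_sets(expr$truth, genes, rng_seed = spec$seed + 11L)
  sets2 <- simulate_gene_sets(expr$truth, genes, n_signal_sets = 2,
                              n_decoy_sets = 8, rng_seed = spec$seed + 12L)
  write_gmt(sets1, p("genesets_pathways.gmt"))
  write_gmt(sets2, p("genesets_go.gmt"))

  truth <- expr$truth
  ppi_up <- simulate_ppi(truth$gene[truth$direction == "up"], spec,
                         rng_seed = spec$seed + 21L)
  ppi_down <- simulate_ppi(truth$gene[truth$direction == "down"], spec,
                           rng_seed = spec$seed + 22L)
  readr::write_tsv(dplyr::bind_rows(ppi_up$biogrid, ppi_down$biogrid),
                   p("ppi_biogrid.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(ppi_up$hippie, ppi_down$hippie),
                   p("ppi_hippie.tsv"), progress = FALSE)

  n_up_t <- ceiling(spec$n_target_genes / 2)
  target_genes <- c(utils::head(truth$gene[truth$direction == "up"], n_up_t),
                    utils::head(truth$gene[truth$direction == "down"],
                                spec$n_target_genes - n_up_t))
  reg <- simulate_regulatory(spec, genes = target_genes)
  readr::write_tsv(reg$human, p("reg_human.tsv"), progress = FALSE)
  readr::write_tsv(reg$mouse, p("reg_mouse.tsv"), progress = FALSE)
  readr::write_tsv(reg$truth_ffls, p("truth_ffl.tsv"), progress = FALSE)

  invisible(list(
    expression = p("expression.tsv"), annotation = p("annotation.tsv"),
    probe_map = p("probe_map.tsv"),
    gmt = c(p("genesets_pathways.gmt"), p("genesets_go.gmt")),
    ppi_biogrid = p("ppi_biogrid.tsv"), ppi_hippie = p("ppi_hippie.tsv"),
    reg_human = p("reg_human.tsv"), reg_mouse = p("reg_mouse.tsv"),
    truth_de = p("truth_de.tsv"), truth_ffl = p("truth_ffl.tsv")
  ))
}
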