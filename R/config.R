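#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline into a validated list.
#' Defaults are the thresholds the analysis is built around: a
#' Benjamini-Hochberg significance level of 0.05 on the combined p-value, an
#' absolute log2 fold-change cut of 0.5 (both strict inequalities), HIPPIE-style
#' PPI confidence in \[0.63, 1\], a miRNA-target score of at least 0.95, a TF
#' evidence p-value below 0.05, and a 1 kb upstream binding-site window.
#'
#' @param de_alpha Significance threshold on the BH-adjusted combined p-value.
#' @param lfc_cut Absolute log2 fold-change threshold (strict).
#' @param test_mode Per-study two-group test: `"moderated"` (empirical-Bayes
#'   variance shrinkage, the default) or `"student"` (pooled-variance t).
#' @param enrich_alpha BH threshold for gene-set over-representation.
#' @param hippie_min_score Minimum HIPPIE-style PPI confidence score (edges kept
#'   when `hippie_min_score <= score <= 1`).
#' @param mirna_score_min Minimum miRNA-target score (kept when `score >=`).
#' @param tf_p_max Maximum p-value for TF-library evidence (strict `<`).
#' @param upstream_window_bp TF binding-site window upstream of the TSS, in bp.
#' @param epc_reps Monte-Carlo realizations for edge-percolated-component
#'   centrality.
#' @param epc_retain_p Edge retention probability per percolation realization.
#' @param rng_seed Integer seed driving every stochastic stage.
#' @param top_n_mode `"n_seed_degs"` (top-n equals the number of seed DEGs in
#'   each PPI network) or `"explicit"` (use `top_n_up` / `top_n_down`).
#' @param top_n_up,top_n_down Explicit top-n cutoffs, used only when
#'   `top_n_mode = "explicit"`.
#'
#' @return A validated list of class `"mirffl_config"`.
#' @examples
#' cfg <- pipeline_config(rng_seed = 1)
#' cfg$de_alpha
#' @export
pipeline_config <- function(de_alpha = 0.05,
                            lfc_cut = 0.5,
                            test_mode = c("moderated", "student"),
                            enrich_alpha = 0.05,
                            hippie_min_score = 0.63,
                            mirna_score_min = 0.95,
                            tf_p_max = 0.05,
                            upstream_window_bp = 1000,
                            epc_reps = 1000,
                            epc_retain_p = 0.5,
                            rng_seed = 1L,
                            top_n_mode = c("n_seed_degs", "explicit"),
                            top_n_up = NULL,
                            top_n_down = NULL) {
  test_mode <- match.arg(test_mode)
  top_n_mode <- match.arg(top_n_mode)
  cfg <- structure(
    list(
      de_alpha = as.numeric(de_alpha),
      lfc_cut = as.numeric(lfc_cut),
      test_mode = test_mode,
      enrich_alpha = as.numeric(enrich_alpha),
      hippie_min_score = as.numeric(hippie_min_score),
      mirna_score_min = as.numeric(mirna_score_min),
      tf_p_max = as.numeric(tf_p_max),
      upstream_window_bp = as.integer(upstream_window_bp),
      epc_reps = as.integer(epc_reps),
      epc_retain_p = as.numeric(epc_retain_p),
      rng_seed = as.integer(rng_seed),
      top_n_mode = top_n_mode,
      top_n_up = if (is.null(top_n_up)) NULL else as.integer(top_n_up),
      top_n_down = if (is.null(top_n_down)) NULL else as.integer(top_n_down)
    ),
    class = "mirffl_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "mirffl_config"))
  prob_in <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= lo || x > hi) {
      stop(sprintf("config field `%s` must be a probability in (%g, %g], got %s",
                   name, lo, hi, format(x)), call. = FALSE)
    }
  }
  prob_in(cfg$de_alpha, "de_alpha")
  prob_in(cfg$enrich_alpha, "enrich_alpha")
  prob_in(cfg$hippie_min_score, "hippie_min_score")
  prob_in(cfg$mirna_score_min, "mirna_score_min")
  prob_in(cfg$tf_p_max, "tf_p_max")
  if (!is.numeric(cfg$lfc_cut) || cfg$lfc_cut < 0) {
    stop("config field `lfc_cut` must be a non-negative number", call. = FALSE)
  }
  if (cfg$upstream_window_bp <= 0L) {
    stop("config field `upstream_window_bp` must be > 0", call. = FALSE)
  }
  if (cfg$epc_reps < 1L) {
    stop("config field `epc_reps` must be >= 1", call. = FALSE)
  }
  if (cfg$epc_retain_p < 0 || cfg$epc_retain_p > 1) {
    stop("config field `epc_retain_p` must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(cfg$rng_seed)) stop("config field `rng_seed` must be an integer", call. = FALSE)
  if (cfg$top_n_mode == "explicit" &&
      (is.null(cfg$top_n_up) || is.null(cfg$top_n_down))) {
    stop("top_n_mode = \"explicit\" requires top_n_up and top_n_down", call. = FALSE)
  }
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' Serialization round-trips field-for-field: `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param cfg A [pipeline_config()] object.
#' @param path File path for the YAML document.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns a
#'   validated `mirffl_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @export
print.mirffl_config <- function(x, ...) {
  cat("<mirffl pipeline config>\n")
  flds <- unclass(x)
  flds <- flds[!vapply(flds, is.null, logical(1))]
  for (nm in names(flds)) cat(sprintf("  %-18s %s\n", nm, format(flds[[nm]])))
  invisible(x)
}
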