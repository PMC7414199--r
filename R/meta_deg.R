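#' Collapse probe-level rows to gene level
#'
#' Genes measured by more than one probe get the arithmetic mean of their
#' probes' values, per sample. Probes absent from the mapping, and probes
#' mapped ambiguously to more than one gene, are dropped; their counts are
#' recorded in the `collapse_log` attribute of the result.
#'
#' @param study An [expression_study()] whose rownames are probe identifiers.
#' @param probe_map Tibble with columns `probe`, `gene`.
#' @return A gene-level `expression_study`; attribute `collapse_log` is a
#'   one-row tibble with `n_probes`, `n_genes`, `dropped_unmapped`,
#'   `dropped_ambiguous`.
#' @export
collapse_probes <- function(study, probe_map) {
  stopifnot(inherits(study, "expression_study"))
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map needs columns `probe` and `gene`", call. = FALSE)
  }
  if (nrow(probe_map) == 0L) stop("probe_map is empty", call. = FALSE)
  probes <- rownames(study$values)
  ambiguous <- probe_map |>
    dplyr::distinct(.data$probe, .data$gene) |>
    dplyr::count(.data$probe) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull("probe")
  map <- probe_map |>
    dplyr::distinct(.data$probe, .data$gene) |>
    dplyr::filter(!.data$probe %in% ambiguous, .data$probe %in% probes)
  n_ambig <- sum(probes %in% ambiguous)
  n_unmapped <- sum(!probes %in% probe_map$probe)
  if (nrow(map) == 0L) stop("probe_map maps none of the study's probes", call. = FALSE)

  gene_of <- stats::setNames(map$gene, map$probe)
  keep <- probes[probes %in% names(gene_of)]
  grp <- factor(gene_of[keep], levels = unique(gene_of[keep]))
  collapsed <- rowsum(study$values[keep, , drop = FALSE], group = grp, reorder = FALSE) /
    as.vector(table(grp)[levels(grp)])
  out <- expression_study(study$study_id, collapsed, study$group)
  attr(out, "collapse_log") <- tibble::tibble(
    n_probes = length(probes), n_genes = nrow(collapsed),
    dropped_unmapped = n_unmapped, dropped_ambiguous = n_ambig
  )
  out
}

# Newton iteration for the inverse of the trigamma function, used by the
# moment-matching fit of the variance prior.
trigamma_inverse <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

# Moment-matching estimate of the scaled-inverse-chi-square variance prior
# (d0 prior df, s0sq prior variance) from gene-wise sample variances s2 with
# residual df `df` each, matching the mean and variance of log s2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s0sq = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0sq = exp(mean(e)))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Per-study two-group differential-expression test
#'
#' For every gene, the log2 fold change is `mean(case) - mean(control)` and the
#' p-value is the two-sided tail of a two-sample statistic. Two modes are
#' available: `"student"` is the classic pooled-variance two-sample t with
#' `n1 + n2 - 2` degrees of freedom; `"moderated"` (default) shrinks each
#' gene's pooled variance toward a prior fitted to the gene-wise variance
#' distribution by moment matching,
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}, and refers the statistic
#' to a t distribution with `d + d0` degrees of freedom — stabilizing the test
#' at small sample sizes the way empirical-Bayes microarray pipelines do.
#'
#' Genes with zero pooled variance and unequal group means cannot produce a
#' finite t; their p is clamped to the smallest representable positive value
#' and flagged in the `zero_variance` column.
#'
#' @param study An [expression_study()] with at least 2 case and 2 control
#'   samples.
#' @param test_mode `"moderated"` or `"student"`.
#' @param d0 Optional prior degrees of freedom override for the moderated mode;
#'   `d0 = 0` reduces it to the student mode exactly. `NULL` (default)
#'   estimates `d0` from the data.
#' @return Tibble with columns `gene`, `lfc`, `t`, `df`, `p`, `zero_variance`.
#' @examples
#' m <- rbind(g1 = c(2, 3, 4, 1, 2, 3))
#' colnames(m) <- paste0("s", 1:6)
#' st <- expression_study("ex", m[rep(1, 3), , drop = FALSE] + 0,
#'                        rep(c("case", "control"), each = 3))
#' @export
per_study_test <- function(study, test_mode = c("moderated", "student"), d0 = NULL) {
  test_mode <- match.arg(test_mode)
  stopifnot(inherits(study, "expression_study"))
  case <- study$values[, study$group == "case", drop = FALSE]
  ctrl <- study$values[, study$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) {
    stop("need >=2 case and >=2 control samples for a variance estimate", call. = FALSE)
  }
  lfc <- rowMeans(case) - rowMeans(ctrl)
  df <- n1 + n2 - 2
  s2 <- (rowSums((case - rowMeans(case))^2) + rowSums((ctrl - rowMeans(ctrl))^2)) / df
  sed2_scale <- 1 / n1 + 1 / n2

  if (test_mode == "moderated") {
    if (is.null(d0)) {
      prior <- fit_variance_prior(s2, df)
      d0 <- prior$d0; s0sq <- prior$s0sq
    } else if (d0 > 0) {
      s0sq <- fit_variance_prior(s2, df)$s0sq
    }
    if (d0 == 0 || is.na(s0sq)) {
      s2_post <- s2; df_total <- df
    } else if (is.infinite(d0)) {
      s2_post <- rep(s0sq, length(s2)); df_total <- Inf
    } else {
      s2_post <- (d0 * s0sq + df * s2) / (d0 + df); df_total <- df + d0
    }
  } else {
    s2_post <- s2; df_total <- df
  }

  tstat <- lfc / sqrt(s2_post * sed2_scale)
  zero_var <- s2_post == 0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  # zero posterior variance: t undefined; equal means -> no evidence (p = 1),
  # unequal means -> strongest representable evidence, flagged
  p[zero_var & lfc == 0] <- 1
  p[zero_var & lfc != 0] <- .Machine$double.xmin
  tstat[zero_var] <- ifelse(lfc[zero_var] == 0, 0, sign(lfc[zero_var]) * Inf)

  tibble::tibble(
    gene = rownames(study$values), lfc = unname(lfc), t = unname(tstat),
    df = df_total, p = unname(p), zero_variance = unname(zero_var)
  )
}

#' Fisher's sum-of-logs p-value combination
#'
#' Combines K independent per-study p-values through
#' \eqn{X = -2 \sum_i \ln p_i}, referred to the upper tail of a chi-square
#' distribution with 2K degrees of freedom. Symmetric in its arguments and
#' monotone: decreasing any p never increases the combined p.
#'
#' @param p Numeric vector of per-study p-values, each in (0, 1].
#' @return List with `chi2_stat` (X) and `p_comb`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p) {
  if (any(p <= 0)) stop("fisher_combine: p <= 0 (log undefined)", call. = FALSE)
  if (any(p > 1)) stop("fisher_combine: p > 1", call. = FALSE)
  x <- -2 * sum(log(p))
  list(chi2_stat = x,
       p_comb = stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE))
}

# row-wise Fisher combination over a genes x studies p-value matrix
fisher_combine_rows <- function(pmat) {
  if (any(pmat <= 0) || any(pmat > 1)) {
    stop("fisher_combine: all p must lie in (0, 1]", call. = FALSE)
  }
  x <- -2 * rowSums(log(pmat))
  tibble::tibble(chi2_stat = unname(x),
                 p_comb = stats::pchisq(x, df = 2 * ncol(pmat), lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, take
#' `adj_(i) = min_{j >= i} m p_(j) / j`, cap at 1, restore input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-study (or K-study) differential-expression meta-analysis
#'
#' Runs the per-study test on every study, combines per-study p-values for the
#' genes common to all studies with Fisher's sum of logs, BH-adjusts the
#' combined p, and summarizes effect size as the sample-size-weighted mean of
#' the per-study log2 fold changes. Genes whose per-study fold changes disagree
#' in sign are labeled `"conflict"`; genes found in only some studies are
#' reported in the `unshared_genes` attribute and never screened.
#'
#' @param studies List of [expression_study()] objects (K >= 1).
#' @inheritParams per_study_test
#' @return A `deg_table`: tibble with one row per common gene and columns
#'   `gene`, per-study `lfc_<id>` / `p_<id>`, `chi2_stat`, `p_comb`, `bh_p`,
#'   `mean_lfc`, `direction` (`up`, `down`, `conflict` or `ns`).
#' @export
meta_deg <- function(studies, test_mode = c("moderated", "student"), d0 = NULL) {
  test_mode <- match.arg(test_mode)
  stopifnot(length(studies) >= 1)
  per <- purrr::map(studies, per_study_test, test_mode = test_mode, d0 = d0)
  common <- Reduce(intersect, purrr::map(per, "gene"))
  all_genes <- unique(unlist(purrr::map(per, "gene")))
  per <- purrr::map(per, function(tb) tb[match(common, tb$gene), ])

  pmat <- do.call(cbind, purrr::map(per, "p"))
  lmat <- do.call(cbind, purrr::map(per, "lfc"))
  sizes <- vapply(studies, function(s) ncol(s$values), numeric(1))
  w <- sizes / sum(sizes)
  mean_lfc <- as.vector(lmat %*% w)

  comb <- fisher_combine_rows(pmat)
  signs <- sign(lmat)
  conflict <- apply(signs, 1L, function(s) any(s > 0) && any(s < 0))
  direction <- dplyr::case_when(
    conflict ~ "conflict",
    mean_lfc > 0 ~ "up",
    mean_lfc < 0 ~ "down",
    TRUE ~ "ns"
  )

  ids <- vapply(studies, function(s) s$study_id, character(1))
  out <- tibble::tibble(gene = common)
  for (k in seq_along(ids)) {
    out[[paste0("lfc_", ids[k])]] <- lmat[, k]
    out[[paste0("p_", ids[k])]] <- pmat[, k]
  }
  out$chi2_stat <- comb$chi2_stat
  out$p_comb <- comb$p_comb
  out$bh_p <- bh_adjust(comb$p_comb)
  out$mean_lfc <- mean_lfc
  out$direction <- direction
  attr(out, "unshared_genes") <- setdiff(all_genes, common)
  attr(out, "study_ids") <- ids
  class(out) <- c("deg_table", class(out))
  out
}

#' Screen a DEG table into up/down gene lists
#'
#' A gene is called up-regulated when its BH-adjusted combined p is strictly
#' below `de_alpha` and its weighted mean log2 fold change is strictly above
#' `lfc_cut` (and symmetrically for down-regulated). Genes whose per-study fold
#' changes conflict in sign are excluded from both lists and returned
#' separately.
#'
#' @param deg_table Result of [meta_deg()].
#' @param de_alpha BH threshold (strict `<`).
#' @param lfc_cut Absolute log2 fold-change threshold (strict `>`).
#' @return List of class `deg_screen` with character vectors `up`, `down` and
#'   `conflict_excluded` (conflicting genes that met the significance cut).
#' @export
screen_degs <- function(deg_table, de_alpha = 0.05, lfc_cut = 0.5) {
  stopifnot(all(c("bh_p", "mean_lfc", "direction", "gene") %in% names(deg_table)))
  sig <- deg_table$bh_p < de_alpha & abs(deg_table$mean_lfc) > lfc_cut
  up <- deg_table$gene[sig & deg_table$mean_lfc > 0 & deg_table$direction == "up"]
  down <- deg_table$gene[sig & deg_table$mean_lfc < 0 & deg_table$direction == "down"]
  conflict <- deg_table$gene[sig & deg_table$direction == "conflict"]
  structure(list(up = up, down = down, conflict_excluded = conflict),
            class = "deg_screen")
}

#' @export
print.deg_screen <- function(x, ...) {
  cat(sprintf("<deg_screen: %d up, %d down, %d conflicting excluded>\n",
              length(x$up), length(x$down), length(x$conflict_excluded)))
  invisible(x)
}

#' @describeIn meta_deg One-row summary of a DEG table at given thresholds.
#' @param x A `deg_table`.
#' @param de_alpha,lfc_cut Screening thresholds, as in [screen_degs()].
#' @param ... Unused.
#' @export
glance.deg_table <- function(x, de_alpha = 0.05, lfc_cut = 0.5, ...) {
  scr <- screen_degs(x, de_alpha, lfc_cut)
  tibble::tibble(
    n_genes = nrow(x),
    n_up = length(scr$up),
    n_down = length(scr$down),
    n_conflict = sum(x$direction == "conflict"),
    n_unshared = length(attr(x, "unshared_genes"))
  )
}

#' Volcano plot of a DEG table
#'
#' @param object A `deg_table` from [meta_deg()].
#' @param de_alpha,lfc_cut Thresholds drawn as guide lines and used to color
#'   the screened genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_table <- function(object, de_alpha = 0.05, lfc_cut = 0.5, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      .data$bh_p < de_alpha & .data$mean_lfc > lfc_cut & .data$direction == "up" ~ "up",
      .data$bh_p < de_alpha & .data$mean_lfc < -lfc_cut & .data$direction == "down" ~ "down",
      TRUE ~ "ns"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_lfc, -log10(.data$bh_p),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(de_alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#d1495b", down = "#00798c",
                                            ns = "grey70")) +
    ggplot2::labs(x = "weighted mean log2 fold change",
                  y = "-log10 BH-adjusted combined p", colour = NULL) +
    ggplot2::theme_minimal()
}
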