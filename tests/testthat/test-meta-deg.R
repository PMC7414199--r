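make_study <- function(mat, group, id = "S") {
  expression_study(id, mat, group)
}

test_that("probe collapse averages multi-probe genes and logs drops", {
  m <- rbind(p1 = c(1, 2, 3, 4), p2 = c(3, 4, 5, 6), p3 = c(10, 10, 10, 10),
             p4 = c(7, 7, 7, 7), p5 = c(0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  st <- make_study(m, c("case", "case", "control", "control"))
  pm <- tibble::tibble(probe = c("p1", "p2", "p3"), gene = c("G", "G", "H"))
  out <- collapse_probes(st, pm)
  expect_equal(rownames(out$values), c("G", "H"))
  expect_equal(out$values["G", "s1"], 2)         # mean of 1 and 3
  expect_equal(out$values["H", ], m["p3", ])     # single probe passes through
  log <- attr(out, "collapse_log")
  expect_equal(log$dropped_unmapped, 2L)
  expect_equal(log$n_genes, 2L)
})

test_that("ambiguous probes are dropped and counted, empty maps error", {
  m <- rbind(p1 = 1:4, p2 = 5:8); colnames(m) <- paste0("s", 1:4)
  st <- make_study(m + 0, c("case", "case", "control", "control"))
  pm <- tibble::tibble(probe = c("p1", "p1", "p2"), gene = c("G", "H", "K"))
  out <- collapse_probes(st, pm)
  expect_equal(rownames(out$values), "K")
  expect_equal(attr(out, "collapse_log")$dropped_ambiguous, 1L)
  expect_error(collapse_probes(st, pm[0, ]), "empty")
})

test_that("pooled-variance student t matches the hand-computed example", {
  m <- rbind(g = c(2, 3, 4, 1, 2, 3)); colnames(m) <- paste0("s", 1:6)
  st <- make_study(m, rep(c("case", "control"), each = 3))
  res <- per_study_test(st, test_mode = "student")
  expect_equal(res$lfc, 1)
  expect_equal(res$t, 1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.287864, tolerance = 1e-5)
  # independent check against the t CDF
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), df = 4), tolerance = 1e-12)
})

test_that("identical group means give t = 0, p = 1", {
  m <- rbind(g = c(1, 2, 3, 1, 2, 3)); colnames(m) <- paste0("s", 1:6)
  st <- make_study(m, rep(c("case", "control"), each = 3))
  res <- per_study_test(st, test_mode = "student")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("zero-variance genes with unequal means are clamped and flagged", {
  m <- rbind(flat = c(2, 2, 2, 1, 1, 1), ok = c(2, 3, 4, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  st <- make_study(m, rep(c("case", "control"), each = 3))
  res <- per_study_test(st, test_mode = "student")
  expect_true(res$zero_variance[res$gene == "flat"])
  expect_equal(res$p[res$gene == "flat"], .Machine$double.xmin)
  expect_false(res$zero_variance[res$gene == "ok"])
})

test_that("moderated mode with shrinkage weight zero reproduces student p-values", {
  spec <- synthetic_spec(n_genes = 40, n_de_up = 4, n_de_down = 4,
                         n_case = 4, n_control = 4, seed = 5)
  st <- simulate_expression(spec)$studies$study1
  expect_equal(per_study_test(st, "moderated", d0 = 0)$p,
               per_study_test(st, "student")$p)
})

test_that("moderated t agrees with the limma empirical-Bayes cross-check", {
  skip_if_not_installed("limma")
  spec <- synthetic_spec(n_genes = 200, n_de_up = 10, n_de_down = 10,
                         n_case = 5, n_control = 5, seed = 9)
  st <- simulate_expression(spec)$studies$study1
  mine <- per_study_test(st, "moderated")
  design <- cbind(1, as.integer(st$group == "case"))
  fit <- limma::eBayes(limma::lmFit(st$values, design))
  theirs <- fit$p.value[, 2]
  expect_equal(mine$p, unname(theirs), tolerance = 1e-6)
})

test_that("Fisher combination matches its definition and degenerate cases", {
  expect_equal(fisher_combine(c(1, 1)), list(chi2_stat = 0, p_comb = 1))
  expect_equal(fisher_combine(0.05)$p_comb, 0.05, tolerance = 1e-12)
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$chi2_stat, 11.98292909421596, tolerance = 1e-12)
  expect_equal(res$p_comb, 0.01747866136777, tolerance = 1e-10)
  expect_error(fisher_combine(c(0, 0.5)), "log undefined")
  expect_error(fisher_combine(c(0.5, 1.1)), "p > 1")
})

test_that("Fisher combination is symmetric and monotone", {
  withr::local_seed(1)
  for (i in 1:25) {
    p <- stats::runif(3, min = 1e-6)
    expect_equal(fisher_combine(p)$p_comb, fisher_combine(rev(p))$p_comb)
    p2 <- p; p2[1] <- p2[1] / 2
    expect_lte(fisher_combine(p2)$p_comb, fisher_combine(p)$p_comb)
  }
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  withr::local_seed(2)
  grid <- seq(0.01, 1, by = 0.01)
  for (i in 1:200) {
    p <- sample(grid, sample(1:8, 1), replace = TRUE)
    adj <- bh_adjust(p)
    expect_equal(adj, bf_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in raw-p order
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("screen applies strict thresholds and excludes conflicts", {
  deg <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    bh_p = c(0.04, 0.04, 0.04, 0.06, 0.01),
    mean_lfc = c(0.6, 0.5, -0.8, 0.9, 0.7),
    direction = c("up", "up", "down", "up", "conflict")
  )
  scr <- screen_degs(deg, de_alpha = 0.05, lfc_cut = 0.5)
  expect_equal(scr$up, "a")              # b at exactly 0.5 excluded (strict >)
  expect_equal(scr$down, "c")
  expect_equal(scr$conflict_excluded, "e")
  expect_length(intersect(scr$up, scr$down), 0)
})

test_that("meta-analysis recovers planted genes on the reference fixture", {
  spec <- synthetic_spec()   # 500 genes, 25+25 planted, lfc 1.5, sd 0.5, seed 7
  ex <- simulate_expression(spec)
  deg <- meta_deg(ex$studies)
  expect_true(all(deg$bh_p >= deg$p_comb))
  scr <- screen_degs(deg, 0.05, 0.5)
  called <- c(scr$up, scr$down)
  recall <- length(intersect(called, ex$truth$gene)) / nrow(ex$truth)
  expect_gte(recall, 0.9)
  expect_lte(length(setdiff(called, ex$truth$gene)), 5)
  # recovered direction labels all correct
  hit <- ex$truth[ex$truth$gene %in% called, ]
  expect_true(all(hit$gene[hit$direction == "up"] %in% scr$up))
  expect_true(all(hit$gene[hit$direction == "down"] %in% scr$down))
  # no randomness in this stage: identical rerun
  expect_identical(deg, meta_deg(ex$studies))
})

test_that("genes absent from one study are reported separately, never screened", {
  spec <- synthetic_spec(n_genes = 30, n_de_up = 3, n_de_down = 3,
                         n_case = 3, n_control = 3, seed = 4)
  st <- simulate_expression(spec)$studies
  st$study2$values <- st$study2$values[-(1:5), ]
  st$study2$group <- st$study2$group
  deg <- meta_deg(st)
  expect_equal(nrow(deg), 25)
  expect_setequal(attr(deg, "unshared_genes"), sprintf("G%04d", 1:5))
})
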