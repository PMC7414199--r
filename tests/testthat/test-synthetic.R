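test_that("spec validation enforces counts, fractions and noise", {
  expect_error(synthetic_spec(n_de_up = 300, n_de_down = 300, n_genes = 500),
               "exceed n_genes")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(decoy_edge_frac = 1.5), "decoy_edge_frac")
  expect_error(synthetic_spec(n_planted_ffl = 1e6), "possible triples")
})

test_that("planted effects appear exactly in the near-noiseless limit", {
  spec <- synthetic_spec(n_genes = 50, n_de_up = 5, n_de_down = 5,
                         effect_lfc = 1, noise_sd = 1e-9,
                         n_case = 4, n_control = 4, seed = 1)
  ex <- simulate_expression(spec)
  st <- ex$studies$study1
  up <- ex$truth$gene[ex$truth$direction == "up"]
  diffs <- rowMeans(st$values[up, st$group == "case"]) -
    rowMeans(st$values[up, st$group == "control"])
  expect_equal(unname(diffs), rep(1, 5), tolerance = 1e-6)
})

test_that("no planted genes means an empty ground-truth table", {
  spec <- synthetic_spec(n_genes = 20, n_de_up = 0, n_de_down = 0,
                         n_case = 2, n_control = 2, seed = 2)
  expect_equal(nrow(simulate_expression(spec)$truth), 0L)
})

test_that("studies share gene lists, have disjoint samples, and reproduce by seed", {
  spec <- synthetic_spec(seed = 7)
  ex <- simulate_expression(spec)
  expect_length(ex$studies, 2)
  expect_identical(rownames(ex$studies$study1$values),
                   rownames(ex$studies$study2$values))
  expect_length(intersect(colnames(ex$studies$study1$values),
                          colnames(ex$studies$study2$values)), 0)
  ex2 <- simulate_expression(synthetic_spec(seed = 7))
  expect_identical(ex$studies$study1$values, ex2$studies$study1$values)
  ex3 <- simulate_expression(synthetic_spec(seed = 8))
  expect_false(identical(ex$studies$study1$values, ex3$studies$study1$values))
})

test_that("too-small groups are rejected before downstream variance breaks", {
  expect_error(simulate_expression(synthetic_spec(n_case = 1, n_control = 5)),
               "variance undefined")
})

test_that("PPI generator covers every seed and honors the degenerate mean", {
  spec <- synthetic_spec(seed = 7)
  seeds <- paste0("S", 1:6)
  sim <- simulate_ppi(seeds, spec)
  partnered <- unique(c(sim$biogrid$partner_a, sim$hippie$partner_a))
  expect_true(all(seeds %in% partnered))
  expect_true(any(sim$hippie$score < 0.63))   # filter-exercising edges exist
  # zero extra partners: only the seed spine remains
  spec0 <- synthetic_spec(ppi_extra_partners = 0, seed = 7)
  sim0 <- simulate_ppi(seeds, spec0)
  both <- dplyr::bind_rows(sim0$biogrid[1:2], sim0$hippie[1:2])
  expect_true(all(c(both$partner_a, both$partner_b) %in% seeds))
})

test_that("forcing passing scores keeps every generated edge through the filters", {
  spec <- synthetic_spec(seed = 7)
  sim <- simulate_ppi(paste0("S", 1:4), spec)
  sim$hippie$score <- 0.9
  sim$biogrid$evidence_count <- 1L
  net <- build_ppi(paste0("S", 1:4), sim$biogrid, sim$hippie)
  n_pairs <- dplyr::bind_rows(sim$biogrid[1:2], sim$hippie[1:2]) |>
    dplyr::mutate(a = pmin(partner_a, partner_b), b = pmax(partner_a, partner_b)) |>
    dplyr::distinct(a, b) |> nrow()
  expect_equal(nrow(net$edges), n_pairs)
})

test_that("a single planted motif with no decoys yields exactly its three edges", {
  spec <- synthetic_spec(n_planted_ffl = 1, decoy_edge_frac = 0, seed = 3)
  reg <- simulate_regulatory(spec)
  expect_equal(nrow(reg$human), 3L)
  ffls <- enumerate_ffls(filter_reg_edges(reg$human))
  expect_equal(ffls, reg$truth_ffls)
})

test_that("decoy edges never create unplanted motifs unless allowed", {
  spec <- synthetic_spec(n_planted_ffl = 6, decoy_edge_frac = 1, seed = 5)
  reg <- simulate_regulatory(spec)
  found <- enumerate_ffls(filter_reg_edges(reg$human))
  expect_equal(found, reg$truth_ffls)
  expect_gt(nrow(reg$human), nrow(dplyr::bind_rows(
    dplyr::distinct(reg$truth_ffls, mirna, tf),
    dplyr::distinct(reg$truth_ffls, mirna, gene),
    dplyr::distinct(reg$truth_ffls, tf, gene))))
})

test_that("zero conservation empties the final miRNA set downstream", {
  spec <- synthetic_spec(conserved_frac = 0, seed = 5)
  reg <- simulate_regulatory(spec)
  expect_equal(nrow(reg$mouse), 0L)
  cons <- conservation_filter(filter_reg_edges(reg$human),
                              reg$mouse)
  expect_equal(nrow(cons$final_mirnas), 0L)
  expect_equal(nrow(enumerate_ffls(cons$edges)), 0L)
})

test_that("regulatory generation is reproducible and species-tagged", {
  spec <- synthetic_spec(seed = 6)
  r1 <- simulate_regulatory(spec)
  r2 <- simulate_regulatory(spec)
  expect_identical(r1, r2)
  expect_true(all(grepl("^mmu-", r1$mouse$source)))
  expect_true(all(r1$mouse$species == "mouse"))
})

test_that("the input bundle writer is byte-reproducible", {
  spec <- synthetic_spec(n_genes = 40, n_de_up = 4, n_de_down = 4,
                         n_case = 3, n_control = 3, n_planted_ffl = 3, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_inputs(spec, d1)
  write_synthetic_inputs(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
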