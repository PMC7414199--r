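reg_row <- function(source, target, type, species = "human", dialect = "mirwalk",
                    ...) {
  defaults <- list(score = 0.99, region = "3UTR", binding_gap = 1L,
                   high_conf = NA, upstream_bp = NA_integer_,
                   evidence_p = NA_real_)
  if (dialect == "chipbase") defaults$upstream_bp <- 500L
  if (dialect == "enrichr_tf") defaults$evidence_p <- 0.01
  if (dialect == "mirsearch") defaults$high_conf <- TRUE
  over <- list(...)
  defaults[names(over)] <- over
  tibble::tibble(source = source, target = target, edge_type = type,
                 species = species, dialect = dialect, !!!defaults)
}

test_that("source-specific thresholds are applied at their exact boundaries", {
  edges <- dplyr::bind_rows(
    reg_row("hsa-miR-1", "G1", "mirna_gene", score = 0.94),
    reg_row("hsa-miR-2", "G1", "mirna_gene", score = 0.95),
    reg_row("hsa-miR-3", "G1", "mirna_gene", score = 0.99, region = "CDS"),
    reg_row("hsa-miR-4", "G1", "mirna_gene", score = 0.99, binding_gap = 2L),
    reg_row("TF1", "G1", "tf_gene", dialect = "chipbase", upstream_bp = 1000L),
    reg_row("TF2", "G1", "tf_gene", dialect = "chipbase", upstream_bp = 1001L),
    reg_row("TF3", "G1", "tf_gene", dialect = "enrichr_tf", evidence_p = 0.05),
    reg_row("TF4", "G1", "tf_gene", dialect = "enrichr_tf", evidence_p = 0.049),
    reg_row("TF5", "G1", "tf_gene", dialect = "itfp"),
    reg_row("hsa-miR-5", "G1", "mirna_gene", dialect = "mirsearch", high_conf = FALSE),
    reg_row("hsa-miR-6", "G1", "mirna_gene", dialect = "mirsearch", high_conf = TRUE),
    reg_row("hsa-miR-7", "G1", "mirna_gene", dialect = "starbase", score = 0.96)
  )
  kept <- filter_reg_edges(edges)
  expect_setequal(kept$source,
                  c("hsa-miR-2", "TF1", "TF4", "TF5", "hsa-miR-6", "hsa-miR-7"))
})

test_that("the same pair from two dialects collapses to one edge with merged provenance", {
  edges <- dplyr::bind_rows(
    reg_row("hsa-miR-1", "G1", "mirna_gene", dialect = "mirwalk"),
    reg_row("hsa-miR-1", "G1", "mirna_gene", dialect = "starbase")
  )
  kept <- filter_reg_edges(edges)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$dialects, "mirwalk;starbase")
})

test_that("conservation keeps miRNAs present in both species and prunes the rest", {
  human <- dplyr::bind_rows(
    reg_row("hsa-miR-34b-5p", "SERPINB2", "mirna_gene"),
    reg_row("hsa-miR-34b-5p", "SMAD4", "mirna_tf"),
    reg_row("hsa-miR-999-3p", "SERPINB2", "mirna_gene"),
    reg_row("SMAD4", "SERPINB2", "tf_gene", dialect = "chipbase")
  ) |> filter_reg_edges()
  mouse <- reg_row("mmu-miR-34b-5p", "Serpinb2", "mirna_gene", species = "mouse") |>
    filter_reg_edges()
  cons <- conservation_filter(human, mouse)
  expect_equal(cons$final_mirnas$mirna, "hsa-miR-34b-5p")
  expect_false("hsa-miR-999-3p" %in% cons$edges$source)
  expect_true("SMAD4" %in% cons$edges$source)   # TF-gene edges untouched
  # idempotent
  again <- conservation_filter(cons$edges, mouse)
  expect_equal(again$edges, cons$edges)
  # empty mouse set removes every miRNA edge
  none <- conservation_filter(human, mouse[0, ])
  expect_equal(nrow(none$final_mirnas), 0L)
  expect_true(all(none$edges$edge_type == "tf_gene"))
})

test_that("arm-aware base names distinguish arms unless relaxed", {
  expect_equal(mirna_base_name("hsa-miR-449c-5p"), "mir-449c-5p")
  expect_equal(mirna_base_name("MMU-miR-449c-5p", keep_arm = FALSE), "mir-449c")
  human <- reg_row("hsa-miR-1-5p", "G1", "mirna_gene") |> filter_reg_edges()
  mouse <- reg_row("mmu-miR-1-3p", "G1", "mirna_gene", species = "mouse") |>
    filter_reg_edges()
  expect_equal(nrow(conservation_filter(human, mouse)$final_mirnas), 0L)
  expect_equal(nrow(conservation_filter(human, mouse, keep_arm = FALSE)$final_mirnas), 1L)
})

test_that("motif enumeration finds exactly the closed triples", {
  edges <- dplyr::bind_rows(
    reg_row("m1", "T1", "mirna_tf"),
    reg_row("m1", "g1", "mirna_gene"),
    reg_row("T1", "g1", "tf_gene", dialect = "chipbase")
  )
  ffls <- enumerate_ffls(edges)
  expect_equal(ffls, tibble::tibble(mirna = "m1", tf = "T1", gene = "g1"))
  # removing any one edge destroys the motif
  for (i in 1:3) expect_equal(nrow(enumerate_ffls(edges[-i, ])), 0L)
  # duplicate edges and shuffled order do not change the result
  shuffled <- dplyr::bind_rows(edges[3:1, ], edges[1, ])
  expect_equal(enumerate_ffls(shuffled), ffls)
})

test_that("motif enumeration equals a brute-force triple scan on random tripartite graphs", {
  withr::local_seed(13)
  for (i in 1:200) {
    edges <- random_tripartite_edges(sample(2:6, 1), sample(2:6, 1),
                                     sample(2:6, 1), p = stats::runif(1, 0.1, 0.5))
    expect_equal(enumerate_ffls(edges), bf_ffls(edges))
  }
})

test_that("merged network composition follows the motif union", {
  one <- dplyr::bind_rows(
    reg_row("m1", "T1", "mirna_tf"), reg_row("m1", "g1", "mirna_gene"),
    reg_row("T1", "g1", "tf_gene", dialect = "chipbase")
  )
  net1 <- build_ffl_network(enumerate_ffls(one), one)
  g1 <- glance(net1)
  expect_equal(g1$n_nodes, 3L); expect_equal(g1$n_edges, 3L)
  expect_equal(c(g1$n_mirna_gene, g1$n_tf_gene, g1$n_mirna_tf), c(1L, 1L, 1L))

  # two motifs sharing the TF and gene: 4 nodes, 5 edges
  two <- dplyr::bind_rows(one,
                          reg_row("m2", "T1", "mirna_tf"),
                          reg_row("m2", "g1", "mirna_gene"))
  net2 <- build_ffl_network(enumerate_ffls(two), two)
  expect_equal(glance(net2)$n_nodes, 4L)
  expect_equal(glance(net2)$n_edges, 5L)

  # an edge in no motif is dropped unless include_all_edges = TRUE
  extra <- dplyr::bind_rows(two, reg_row("m3", "g1", "mirna_gene"))
  net3 <- build_ffl_network(enumerate_ffls(extra), extra)
  expect_false("m3" %in% net3$nodes$node)
  net4 <- build_ffl_network(enumerate_ffls(extra), extra, include_all_edges = TRUE)
  expect_true("m3" %in% net4$nodes$node)

  # count identities: per-type sums equal totals
  gl <- glance(net4)
  expect_equal(gl$n_mirna_gene + gl$n_tf_gene + gl$n_mirna_tf, gl$n_edges)
  expect_equal(gl$n_mirnas + gl$n_tfs + gl$n_genes, gl$n_nodes)
})

test_that("the exact-composition generator hits its requested counts and is all-motif", {
  reg <- simulate_regulatory_exact()
  human <- filter_reg_edges(reg$human)
  expect_equal(nrow(human), nrow(reg$human))   # all generated edges pass filters
  cons <- conservation_filter(human, filter_reg_edges(reg$mouse))
  expect_equal(nrow(cons$edges), nrow(human))  # fully conserved
  ffls <- enumerate_ffls(cons$edges)
  net <- build_ffl_network(ffls, cons$edges)
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(human))        # every edge participates in a motif
  expect_equal(c(gl$n_mirnas, gl$n_tfs, gl$n_genes), c(26L, 20L, 5L))
})

test_that("infeasible exact-count requests raise explanatory errors", {
  expect_error(simulate_regulatory_exact(n_tf = 3, n_gene = 5), "n_tf >= n_gene")
  expect_error(simulate_regulatory_exact(n_tf_gene = 10), "without a gene edge")
  expect_error(simulate_regulatory_exact(n_mirna_gene = 10),
               "n_mirna_gene >= n_mirna")
  expect_error(simulate_regulatory_exact(n_mirna_tf = 10), "too small to cover")
  expect_error(simulate_regulatory_exact(n_mirna_tf = 1000), "grid capacity")
})
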