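test_that("brain-biased background is the strict union of the two datasets", {
  fc_a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     log2fc = c(0.6, 0.5, 0.0, NA))
  fc_b <- data.frame(gene = c("g1", "g2", "g3", "g5"),
                     log2fc = c(0.1, 0.5, 0.0, 2.0))
  bg <- brain_biased_background(fc_a, fc_b)
  expect_true("g1" %in% bg)    # above threshold in A only
  expect_false("g2" %in% bg)   # exactly 0.5 in both: strict inequality
  expect_false("g3" %in% bg)
  expect_false("g4" %in% bg)
  expect_true("g5" %in% bg)    # present in one table only
})

test_that("high-expression sets use a strict quantile cutoff", {
  m <- matrix(1:10, ncol = 1, dimnames = list(paste0("g", 1:10), "striatum|adult"))
  expect_setequal(high_expression_set(m, "striatum", "adult", 0.5),
                  paste0("g", 6:10))
  expect_setequal(high_expression_set(m, "striatum", "adult", 0.9), "g10")
  const <- matrix(5, nrow = 10, ncol = 1,
                  dimnames = list(paste0("g", 1:10), "striatum|adult"))
  expect_length(high_expression_set(const, "striatum", "adult", 0.5), 0)
  expect_error(high_expression_set(m, "striatum", "adult", 1.2), "quantile")
  expect_error(high_expression_set(m, "amygdala", "adult", 0.5), "no expression cell")
})

test_that("region-stage enrichment attains its minimum p in the loaded cell", {
  genes <- sprintf("g%04d", 1:500)
  sim <- simulate_expression(genes, target_genes = genes[1:40], effect = 5,
                             enriched_region_stage = c("striatum", "adolescent"),
                             seed = 31)
  res <- region_stage_enrichment(genes[1:40], sim$matrix, genes,
                                 quantiles = 0.5)
  best <- res[which.min(res$p), ]
  expect_equal(best$region, "striatum")
  expect_equal(best$stage, "adolescent")
  # +5 SD at the median cutoff puts every target gene in the high set
  expect_equal(best$k, 40)
  expect_equal(nrow(res), 16 * 5)
  expect_error(region_stage_enrichment(character(), sim$matrix, genes),
               "no target genes")
  expect_warning(region_stage_enrichment(c(genes[1:5], "nope"), sim$matrix,
                                         genes, quantiles = 0.5),
                 "outside the background")
})

test_that("permutation FWER honours its estimator bounds and determinism", {
  genes <- sprintf("g%04d", 1:300)
  sim <- simulate_expression(genes, seed = 12)
  target <- genes[1:25]
  obs <- region_stage_enrichment(target, sim$matrix, genes, quantiles = c(0.5, 0.7))
  fw <- permutation_fwer(obs, sim$matrix, genes, R = 99, seed = 7)
  expect_true(all(fw$fwer >= 1 / 100 & fw$fwer <= 1))
  # a cell with p = 1 gets FWER 1
  expect_true(all(fw$fwer[fw$p == 1] == 1))
  # monotone within a quantile family
  for (q in unique(fw$quantile)) {
    d <- fw[fw$quantile == q, ]
    d <- d[order(d$p), ]
    expect_true(all(diff(d$fwer) >= 0))
  }
  fw2 <- permutation_fwer(obs, sim$matrix, genes, R = 99, seed = 7)
  expect_identical(fw$fwer, fw2$fwer)
  expect_error(permutation_fwer(obs, sim$matrix, genes, target_size = 1000,
                                R = 9, seed = 1), "background")
})

test_that("fwer_table reshapes to one row per cell with per-quantile columns", {
  genes <- sprintf("g%04d", 1:200)
  sim <- simulate_expression(genes, seed = 2)
  obs <- region_stage_enrichment(genes[1:20], sim$matrix, genes,
                                 quantiles = c(0.5, 0.9))
  fw <- permutation_fwer(obs, sim$matrix, genes, R = 19, seed = 3)
  wide <- fwer_table(fw)
  expect_equal(nrow(wide), 16 * 5)
  expect_true(all(c("fwer_q0.5", "fwer_q0.9", "n_signif") %in% names(wide)))
  expect_equal(wide$n_signif,
               as.integer(rowSums(wide[, c("fwer_q0.5", "fwer_q0.9")] < 0.05)))
})

test_that("expression matrix TSV round trip preserves values", {
  genes <- sprintf("g%04d", 1:50)
  sim <- simulate_expression(genes, n_regions = 3, n_stages = 2, seed = 6)
  tsv <- tempfile(fileext = ".tsv")
  write_expression_matrix(sim$matrix, tsv)
  back <- read_expression_matrix(tsv)
  expect_equal(back, sim$matrix, tolerance = 1e-12)
})
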