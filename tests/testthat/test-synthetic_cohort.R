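test_that("truth simulation is seed-reproducible and respects case-specificity", {
  man <- default_manifest()
  t1 <- simulate_truth(man, n_shared = 50, n_case_specific = 10, seed = 42)
  t2 <- simulate_truth(man, n_shared = 50, n_case_specific = 10, seed = 42)
  expect_identical(t1$svs, t2$svs)
  expect_identical(t1$carriers, t2$carriers)

  relatives <- man$sample_id[man$role == "unaffected_relative"]
  case_ids <- t1$svs$sv_id[t1$svs$case_specific]
  case_carriers <- t1$carriers[t1$carriers$sv_id %in% case_ids, ]
  expect_false(any(case_carriers$sample_id %in% relatives))
  expect_true(all(t1$svs$acmg_class[t1$svs$case_specific] == 4L))
  # every shared SV reaches at least one relative
  shared_ids <- t1$svs$sv_id[!t1$svs$case_specific]
  for (id in shared_ids)
    expect_true(any(t1$carriers$sample_id[t1$carriers$sv_id == id] %in% relatives))

  no_proband <- data.frame(sample_id = "X", role = "unaffected_relative")
  expect_error(simulate_truth(structure(no_proband, class = c("cohort_manifest", "data.frame")),
                              n_case_specific = 5, seed = 1),
               "proband")
})

test_that("sampled lengths reproduce the bimodal retrotransposon signature", {
  set.seed(11)
  lens <- sample_sv_lengths(10000)
  expect_true(all(lens >= 30))
  d <- stats::density(log10(lens), bw = 0.05)
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  peaks <- peaks[d$y[match(peaks, d$x)] > 0.05 * max(d$y)]
  expect_true(any(abs(peaks - 2.5) <= 0.15))   # Alu mode ~300 bp
  expect_true(any(abs(peaks - 3.8) <= 0.15))   # L1 mode ~6 kb
  # small-event tail dominates the median
  expect_lt(stats::median(lens[lens <= 200]), 80)
})

test_that("caller emulation hits the binomial support expectation", {
  man <- default_manifest()
  profiles <- default_caller_profiles()  # 4 callers at sensitivity 0.9
  truth <- simulate_truth(man, n_shared = 1000, n_case_specific = 0, seed = 3)
  calls <- emulate_callers(truth, profiles, seed = 4)
  true_calls <- calls[!is.na(calls$truth_id), ]
  support <- table(paste(true_calls$truth_id, true_calls$sample_id))
  expect_equal(mean(support), 3.6, tolerance = 0.1 / 3.6)

  # degenerate profiles
  perfect <- caller_profile("p", sensitivity = 1, breakpoint_jitter = 0,
                            length_jitter = 0, false_rate = 0)
  small <- simulate_truth(man, n_shared = 20, n_case_specific = 5, seed = 6)
  exact <- emulate_callers(small, perfect, seed = 7)
  events <- merge(small$carriers, small$svs, by = "sv_id")
  expect_equal(nrow(exact), nrow(events))
  m <- merge(exact, small$svs, by.x = "truth_id", by.y = "sv_id")
  expect_true(all(m$start.x == m$start.y & m$length.x == m$length.y))
  blind <- caller_profile("b", sensitivity = 0, false_rate = 0)
  expect_equal(nrow(emulate_callers(small, blind, seed = 8)), 0)

  expect_identical(emulate_callers(small, perfect, seed = 7),
                   emulate_callers(small, perfect, seed = 7))
  expect_error(emulate_callers(small, perfect[0, ], seed = 1), "profile")
})

test_that("expression simulation plants the shift only in the chosen cell", {
  genes <- sprintf("g%03d", 1:100)
  null_sim <- simulate_expression(genes, seed = 5)
  expect_identical(null_sim$matrix, simulate_expression(genes, seed = 5)$matrix)
  expect_equal(dim(null_sim$matrix), c(100L, 80L))

  target <- genes[1:10]
  shifted <- simulate_expression(genes, target_genes = target, effect = 5,
                                 enriched_region_stage = c("striatum", "adolescent"),
                                 seed = 5)
  delta <- shifted$matrix - null_sim$matrix
  expect_equal(sum(delta != 0), 10)
  expect_equal(unname(delta[target, "striatum|adolescent"]), rep(5, 10),
               tolerance = 1e-12)
  # target genes are always brain-biased in the fold-change tables
  expect_true(all(shifted$fc_a$log2fc[shifted$fc_a$gene %in% target] > 0.5))
})

test_that("simulate_cohort_files writes a self-consistent input bundle", {
  dir <- file.path(tempdir(), "cohort_files_test")
  bundle <- simulate_cohort_files(dir, manifest = default_manifest(3, 2),
                                  n_shared = 15, n_case_specific = 3, seed = 5)
  sheet <- read.delim(bundle$paths$sample_sheet)
  expect_equal(nrow(sheet), 5 * 4)  # samples x callers
  expect_true(all(file.exists(sheet$vcf)))
  one <- read_sv_vcf(sheet$vcf[1], sheet$sample_id[1], sheet$caller_id[1])
  in_mem <- bundle$calls[bundle$calls$sample_id == sheet$sample_id[1] &
                         bundle$calls$caller_id == sheet$caller_id[1] &
                         bundle$calls$length >= 30, ]
  expect_equal(nrow(one), nrow(in_mem))
  models <- read_gene_models_bed(bundle$paths$genes_bed)
  expect_gt(nrow(models), 0)
  expect_true(file.exists(bundle$paths$pathways_gmt))
  unlink(dir, recursive = TRUE)
})
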