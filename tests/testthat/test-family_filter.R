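mk_case <- function(...) {
  df <- sv_calls(...)
  df$members <- lapply(seq_len(nrow(df)), function(i) df[i, 1:7])
  df
}

test_that("class filter retains class >= min_class and reconciles counters", {
  svs <- sv_calls(chrom = "chr1", start = c(1L, 2L, 3L) * 1000L, length = 100L,
                  svtype = "DEL", sample_id = "S", caller_id = "c",
                  acmg_class = c(3L, 4L, 5L))
  fs <- filter_by_class(svs)
  expect_equal(fs$retained$acmg_class, c(4L, 5L))
  expect_equal(unname(fs$counters["input"]),
               unname(fs$counters["class_filtered"] + fs$counters["retained"]))
  expect_equal(nrow(filter_by_class(svs, min_class = 1)$retained), 3)
  all_benign <- svs; all_benign$acmg_class <- 1L
  expect_equal(nrow(filter_by_class(all_benign)$retained), 0)
  svs$acmg_class[1] <- NA
  expect_warning(fs2 <- filter_by_class(svs), "without ACMG class")
  expect_equal(fs2$removed$removed_reason[1], "missing_class")
})

test_that("subtract_presence removes case SVs matched by any control call", {
  case <- mk_case(chrom = "chr1", start = 1000L, length = 100L, svtype = "DEL",
                  sample_id = "AP1", caller_id = "consensus", acmg_class = 4L)
  ctrl_hit <- sv_calls(chrom = "chr1", start = 1010L, length = 100L,
                       svtype = "DEL", sample_id = "AC1", caller_id = "c2")
  fs <- subtract_presence(case, ctrl_hit)      # RO ~ 0.82
  expect_equal(nrow(fs$retained), 0)
  expect_equal(fs$removed$control_sample, "AC1")

  # no control calls at all: identity
  fs2 <- subtract_presence(case, ctrl_hit[0, ])
  expect_equal(nrow(fs2$retained), 1)

  # INS length ratio below threshold: retained
  case_ins <- mk_case(chrom = "chr1", start = 5000L, length = 300L,
                      svtype = "INS", sample_id = "AP1", caller_id = "cons",
                      acmg_class = 4L)
  ctrl_ins <- sv_calls(chrom = "chr1", start = 5000L, length = 40L,
                       svtype = "INS", sample_id = "AC1", caller_id = "c1")
  expect_equal(nrow(subtract_presence(case_ins, ctrl_ins)$retained), 1)

  # type mismatch never matches
  ctrl_dup <- ctrl_hit; ctrl_dup$svtype <- "DUP"
  expect_equal(nrow(subtract_presence(case, ctrl_dup)$retained), 1)

  # small span rescued by proximity + size despite failing RO
  case_small <- mk_case(chrom = "chr1", start = 19415917L, length = 32L,
                        svtype = "DEL", sample_id = "AP1", caller_id = "cons",
                        acmg_class = 4L)
  ctrl_small <- sv_calls(chrom = "chr1", start = 19415871L, length = 32L,
                         svtype = "DEL", sample_id = "AC1", caller_id = "c1")
  expect_lt(reciprocal_overlap(case_small, ctrl_small), 0.7)
  expect_equal(nrow(subtract_presence(case_small, ctrl_small)$retained), 0)
})

test_that("retained SVs never match control calls (post-hoc audit)", {
  set.seed(77)
  for (rep in 1:10) {
    case <- random_call_instance(30)
    case <- merge_sample_calls(case, min_support = 1)
    ctrl <- random_call_instance(30)
    ctrl$sample_id <- "AC1"
    fs <- subtract_presence(case, ctrl)
    if (!nrow(fs$retained)) next
    for (i in seq_len(nrow(fs$retained))) {
      sv <- fs$retained[i, ]
      same <- ctrl[ctrl$svtype == sv$svtype, , drop = FALSE]
      if (!nrow(same)) next
      if (sv$svtype == "INS") {
        expect_false(any(insertions_match(sv, same)))
      } else {
        ro <- reciprocal_overlap(sv, same)
        near <- abs(sv$start - same$start) <= 500 &
          pmin(sv$length, same$length) / pmax(sv$length, same$length) >= 0.7
        expect_false(any(ro >= 0.7 | near))
      }
    }
    # conservation
    expect_equal(unname(fs$counters["input"]),
                 nrow(fs$retained) + nrow(fs$removed))
  }
})

test_that("run_direction recovers planted exclusivity with perfect callers", {
  man <- default_manifest(4, 2)
  perfect <- do.call(rbind, lapply(paste0("c", 1:4), caller_profile,
                                   sensitivity = 1, breakpoint_jitter = 0,
                                   length_jitter = 0, false_rate = 0))
  truth <- simulate_truth(man, n_shared = 40, n_case_specific = 10, seed = 9)
  calls <- emulate_callers(truth, perfect, seed = 10)

  fs <- run_direction(calls, man, "proband_exclusive")
  a <- audit_retained(fs$retained, truth)
  expect_equal(a$n_recovered, 10)
  expect_equal(a$n_shared_retained, 0)
  expect_equal(nrow(fs$retained), 10)
  expect_equal(unname(fs$counters["consensus"]),
               unname(fs$counters["class_filtered"] +
                      fs$counters["control_matched"] + fs$counters["retained"]))

  # symmetric direction: every shared class-4 SV is also in a proband,
  # so nothing is relative-exclusive in this truth set
  fs_rel <- run_direction(calls, man, "relative_exclusive")
  shared_ids <- truth$svs$sv_id[!truth$svs$case_specific]
  carried_by_proband <- vapply(shared_ids, function(id) {
    s <- truth$carriers$sample_id[truth$carriers$sv_id == id]
    any(s %in% man$sample_id[man$role == "proband"])
  }, logical(1))
  rel_only <- shared_ids[!carried_by_proband]
  cls4 <- truth$svs$sv_id[truth$svs$acmg_class >= 4]
  attributed <- vapply(fs_rel$retained$members, function(m)
    names(sort(table(m$truth_id), decreasing = TRUE))[1], character(1))
  # retained rows are per relative carrier; distinct variants must be exactly
  # the class-4 truth SVs carried by no proband
  expect_setequal(unique(attributed), intersect(rel_only, cls4))
})
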