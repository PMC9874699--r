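new_filtered_set <- function(retained, removed, counters) {
  structure(list(retained = retained, removed = removed, counters = counters),
            class = "filtered_set")
}

#' @export
print.filtered_set <- function(x, ...) {
  cat("<filtered_set>\n")
  for (nm in names(x$counters))
    cat(sprintf("  %-16s %d\n", nm, x$counters[[nm]]))
  invisible(x)
}

#' Retain SVs at or above a pathogenicity class
#'
#' Applies the ACMG class filter: only SVs classified as likely pathogenic
#' (class 4) or pathogenic (class 5) are kept under the default. SVs with a
#' missing class are dropped with a warning.
#'
#' @param svs SV table carrying an `acmg_class` column.
#' @param min_class minimum retained class (default 4).
#' @return a `filtered_set`: `$retained`, `$removed` (with a `removed_reason`
#'   column), and provenance `$counters`.
#' @export
filter_by_class <- function(svs, min_class = 4) {
  if (!"acmg_class" %in% names(svs))
    stop("SV table has no acmg_class column")
  missing_cls <- is.na(svs$acmg_class)
  if (any(missing_cls))
    warning(sum(missing_cls), " SV(s) without ACMG class dropped")
  keep <- !missing_cls & svs$acmg_class >= min_class
  removed <- svs[!keep, , drop = FALSE]
  removed$removed_reason <- ifelse(is.na(removed$acmg_class),
                                   "missing_class", "below_min_class")
  new_filtered_set(
    retained = svs[keep, , drop = FALSE],
    removed = removed,
    counters = c(input = nrow(svs), class_filtered = sum(!keep),
                 retained = sum(keep))
  )
}

#' Remove case SVs that are present in control samples
#'
#' The family-based exclusivity filter: a case (consensus) SV is removed if
#' ANY raw control call of the same SV type matches it. Span types match by
#' reciprocal overlap at or above `ro_threshold`, OR by breakpoint
#' proximity with closely matching size (start distance within `ins_window`
#' and length ratio at least `ins_ratio`); insertions match by
#' [insertions_match()]. The proximity alternative matters for events
#' smaller than the callers' breakpoint noise, where strict reciprocal
#' overlap is blind to control calls that plainly describe the same
#' variant. The asymmetry is deliberate: controls are matched with
#' un-merged single-caller calls ("seen by at least one analytical tool"),
#' which is the conservative direction - one caller's evidence in a relative
#' suffices to disqualify a candidate. Control calls are matched regardless
#' of their own pathogenicity class.
#'
#' When a case SV carries its supporting member calls (the `members`
#' list-column produced by [merge_sample_calls()]), a control call matching
#' *any* member also removes the SV: the representative breakpoints are
#' medians whose error is shared across every control comparison, so for
#' short events a single unlucky representative would otherwise escape all
#' control evidence at once. Matching the raw supporting calls restores the
#' intended "seen by at least one tool" semantics under breakpoint noise.
#'
#' @param case_svs consensus SVs from the case group.
#' @param control_calls raw per-caller calls from the control group.
#' @param ro_threshold,ins_window,ins_ratio match-predicate parameters,
#'   identical to the within-sample merge defaults.
#' @return a `filtered_set`; removed rows carry the first matching control
#'   call as `control_sample`, `control_caller`, `control_start`,
#'   `control_length`.
#' @export
subtract_presence <- function(case_svs, control_calls, ro_threshold = 0.7,
                              ins_window = 500, ins_ratio = 0.7) {
  n <- nrow(case_svs)
  # expand each case SV to its comparable intervals: representative + members
  if ("members" %in% names(case_svs) && n) {
    reps <- lapply(seq_len(n), function(i) {
      mem <- case_svs$members[[i]]
      out <- data.frame(chrom = c(case_svs$chrom[i], mem$chrom),
                        start = c(case_svs$start[i], mem$start),
                        length = c(case_svs$length[i], mem$length),
                        svtype = case_svs$svtype[i],
                        stringsAsFactors = FALSE)
      out$case_idx <- i
      out
    })
    probe <- do.call(rbind, reps)
  } else if (n) {
    probe <- data.frame(chrom = case_svs$chrom, start = case_svs$start,
                        length = case_svs$length, svtype = case_svs$svtype,
                        case_idx = seq_len(n), stringsAsFactors = FALSE)
  }
  match_idx <- rep(NA_integer_, n)
  if (n && nrow(control_calls)) {
    for (type in intersect(SV_TYPES, unique(probe$svtype))) {
      ci <- which(probe$svtype == type)
      ki <- which(control_calls$svtype == type)
      if (!length(ki)) next
      cs <- probe[ci, , drop = FALSE]
      ks <- control_calls[ki, , drop = FALSE]
      if (type == "INS") {
        gr_c <- GenomicRanges::GRanges(cs$chrom,
                  IRanges::IRanges(cs$start - ins_window, cs$start + ins_window))
        gr_k <- GenomicRanges::GRanges(ks$chrom, IRanges::IRanges(ks$start, width = 1L))
        hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_c, gr_k))
        i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
        ok <- insertions_match(cs[i, , drop = FALSE], ks[j, , drop = FALSE],
                               window = ins_window, length_ratio = ins_ratio)
      } else {
        # candidate pairs within the proximity window (supersets of RO hits)
        gr_c <- GenomicRanges::GRanges(cs$chrom,
                  IRanges::IRanges(cs$start - ins_window,
                                   cs$start + cs$length + ins_window))
        gr_k <- sv_granges(ks)
        hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_c, gr_k))
        i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
        ro_ok <- reciprocal_overlap(cs[i, , drop = FALSE],
                                    ks[j, , drop = FALSE]) >= ro_threshold
        # SURVIVOR-style rescue for events smaller than the breakpoint noise:
        # nearby control call of closely matching size
        near <- abs(cs$start[i] - ks$start[j]) <= ins_window
        ratio <- pmin(cs$length[i], ks$length[j]) /
                 pmax(cs$length[i], ks$length[j])
        ok <- ro_ok | (near & ratio >= ins_ratio)
      }
      if (any(ok)) {
        case_of <- cs$case_idx[i[ok]]
        ctrl <- ki[j[ok]]
        best <- tapply(ctrl, case_of, min)
        for (b in seq_along(best)) {
          ix <- as.integer(names(best)[b])
          match_idx[ix] <- min(match_idx[ix], best[b], na.rm = TRUE)
        }
      }
    }
  }
  removed <- case_svs[!is.na(match_idx), , drop = FALSE]
  ev <- control_calls[match_idx[!is.na(match_idx)], , drop = FALSE]
  if (nrow(removed)) {
    removed$removed_reason <- "control_matched"
    removed$control_sample <- ev$sample_id
    removed$control_caller <- ev$caller_id
    removed$control_start <- ev$start
    removed$control_length <- ev$length
  }
  new_filtered_set(
    retained = case_svs[is.na(match_idx), , drop = FALSE],
    removed = removed,
    counters = c(input = n, control_matched = nrow(removed),
                 retained = n - nrow(removed))
  )
}

#' Run the full family-exclusivity workflow in either direction
#'
#' Composes the three stages on raw per-caller calls for a whole cohort:
#' per-sample multi-caller consensus in the case group, ACMG class
#' filtering, then subtraction of everything matched by any raw call in the
#' control group. `direction = "proband_exclusive"` treats probands as cases
#' and unaffected relatives as controls; `"relative_exclusive"` swaps the
#' roles (the symmetric contrast used as a sanity check of the design).
#'
#' @param calls raw per-caller SV calls for all samples.
#' @param manifest a [cohort_manifest()].
#' @param direction `"proband_exclusive"` or `"relative_exclusive"`.
#' @param min_class minimum ACMG class retained (default 4).
#' @inheritParams merge_sample_calls
#' @return a `filtered_set` whose counters reconcile:
#'   `consensus = class_filtered + control_matched + retained`.
#' @export
run_direction <- function(calls, manifest,
                          direction = c("proband_exclusive", "relative_exclusive"),
                          ro_threshold = 0.7, ins_window = 500, ins_ratio = 0.7,
                          min_support = 2, min_class = 4) {
  direction <- match.arg(direction)
  case_role <- if (direction == "proband_exclusive") "proband" else "unaffected_relative"
  case_ids <- manifest$sample_id[manifest$role == case_role]
  control_ids <- manifest$sample_id[manifest$role != case_role]
  case_calls <- calls[calls$sample_id %in% case_ids, , drop = FALSE]
  control_calls <- calls[calls$sample_id %in% control_ids, , drop = FALSE]

  consensus <- merge_cohort_calls(case_calls, ro_threshold = ro_threshold,
                                  ins_window = ins_window, ins_ratio = ins_ratio,
                                  min_support = min_support)
  by_class <- filter_by_class(consensus, min_class = min_class)
  final <- subtract_presence(by_class$retained, control_calls,
                             ro_threshold = ro_threshold,
                             ins_window = ins_window, ins_ratio = ins_ratio)
  removed <- rbind_fill(by_class$removed, final$removed)
  new_filtered_set(
    retained = final$retained,
    removed = removed,
    counters = c(case_calls = nrow(case_calls),
                 consensus = nrow(consensus),
                 class_filtered = unname(by_class$counters["class_filtered"]),
                 control_matched = unname(final$counters["control_matched"]),
                 retained = nrow(final$retained))
  )
}

# rbind two data.frames, padding missing columns with NA
rbind_fill <- function(a, b) {
  if (!nrow(a)) return(b)
  if (!nrow(b)) return(a)
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[, names(a), drop = FALSE])
}

#' Write the audit trail of a filtered set
#'
#' One row per removed case SV with the reason and, where applicable, the
#' matching control evidence.
#'
#' @param fs a `filtered_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(fs, path) {
  write_sv_table(fs$removed, path)
}
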