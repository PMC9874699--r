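#' Reciprocal overlap between two genomic intervals
#'
#' The symmetric similarity used to decide that two span-type SV calls
#' describe the same event: the length of the intersection divided by the
#' longer of the two spans (equivalently, the minimum of the two mutual
#' overlap fractions). Intervals on different contigs, or disjoint
#' intervals, score 0.
#'
#' @param a,b interval tables with columns `chrom`, `start`, `length`
#'   (rows are recycled to a common length).
#' @return numeric vector of overlap fractions in `[0, 1]`.
#' @export
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, length = 100)
#' b <- data.frame(chrom = "chr1", start = 150, length = 100)
#' reciprocal_overlap(a, b)  # 0.5
reciprocal_overlap <- function(a, b) {
  if (any(a$length < 1) || any(b$length < 1))
    stop("reciprocal overlap is undefined for zero-length intervals")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  sa <- a$start[ai]; la <- a$length[ai]
  sb <- b$start[bi]; lb <- b$length[bi]
  ov <- pmax(0, pmin(sa + la, sb + lb) - pmax(sa, sb))
  out <- ov / pmax(la, lb)
  out[as.character(a$chrom[ai]) != as.character(b$chrom[bi])] <- 0
  out
}

#' Do two insertion calls describe the same event?
#'
#' Reciprocal overlap is undefined for point insertions, so insertions are
#' matched by breakpoint proximity and inserted-length agreement: anchors
#' within `window` bp on the same contig, and the shorter inserted length at
#' least `length_ratio` of the longer.
#'
#' @param a,b INS call tables (columns `chrom`, `start`, `length`; recycled).
#' @param window maximum anchor distance in bp (default 500).
#' @param length_ratio minimum min/max inserted-length ratio (default 0.7,
#'   mirroring the reciprocal-overlap rule).
#' @return logical vector.
#' @export
insertions_match <- function(a, b, window = 500, length_ratio = 0.7) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  same_chrom <- as.character(a$chrom[ai]) == as.character(b$chrom[bi])
  near <- abs(a$start[ai] - b$start[bi]) <= window
  la <- a$length[ai]; lb <- b$length[bi]
  ratio <- pmin(la, lb) / pmax(la, lb)
  same_chrom & near & ratio >= length_ratio
}

# candidate matching pairs among calls of ONE svtype, as a two-column index
# matrix; pairs are pre-screened with findOverlaps then confirmed with the
# exact predicate
match_pairs <- function(calls, ro_threshold, ins_window, ins_ratio) {
  if (nrow(calls) < 2) return(matrix(integer(), ncol = 2))
  type <- calls$svtype[1]
  if (type == "INS") {
    gr <- GenomicRanges::GRanges(calls$chrom,
            IRanges::IRanges(calls$start - ins_window, calls$start + ins_window))
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
    keep <- insertions_match(calls[i, , drop = FALSE], calls[j, , drop = FALSE],
                             window = ins_window, length_ratio = ins_ratio)
  } else {
    gr <- sv_granges(calls)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
    keep <- reciprocal_overlap(calls[i, , drop = FALSE],
                               calls[j, , drop = FALSE]) >= ro_threshold
  }
  cbind(i[keep], j[keep])
}

# single-linkage component membership over the match predicate
match_components <- function(calls, ro_threshold, ins_window, ins_ratio) {
  pairs <- match_pairs(calls, ro_threshold, ins_window, ins_ratio)
  g <- igraph::make_empty_graph(n = nrow(calls), directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  igraph::components(g)$membership
}

#' Merge one sample's multi-caller calls into consensus SVs
#'
#' Calls are grouped per SV type by single-linkage connected components over
#' the match predicate: reciprocal overlap at least `ro_threshold` for
#' DEL/DUP/INV, [insertions_match()] for INS. Groups supported by at least
#' `min_support` distinct callers emit one consensus SV. Within a group each
#' caller contributes at most one call - the one whose start is closest to
#' the group's provisional median start (ties to the smaller start) - and
#' the representative start and length are the medians over the contributed
#' calls, rounded half-up. The consensus ACMG class is the maximum over
#' member classes (NA if none is classified).
#'
#' @param calls SV call table for a single sample (several callers).
#' @param ro_threshold reciprocal-overlap threshold (default 0.7).
#' @param ins_window,ins_ratio insertion-matching parameters.
#' @param min_support minimum number of distinct supporting callers
#'   (default 2, the weakest reading of "found by multiple tools").
#' @return a data.frame of consensus SVs with columns `chrom`, `start`,
#'   `length`, `svtype`, `sample_id`, `acmg_class`, `n_callers`, `callers`
#'   (comma-separated, sorted) and a list-column `members` holding the
#'   contributing rows of `calls`.
#' @export
merge_sample_calls <- function(calls, ro_threshold = 0.7, ins_window = 500,
                               ins_ratio = 0.7, min_support = 2) {
  if (min_support < 1) stop("min_support must be >= 1")
  validate_sv_calls(calls)
  sid <- unique(calls$sample_id)
  if (length(sid) > 1)
    stop("merge_sample_calls expects calls from a single sample")
  empty <- data.frame(chrom = character(), start = integer(), length = integer(),
                      svtype = character(), sample_id = character(),
                      acmg_class = integer(), n_callers = integer(),
                      callers = character(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (!nrow(calls)) return(empty)

  res <- list()
  for (type in intersect(SV_TYPES, unique(calls$svtype))) {
    sub <- calls[calls$svtype == type, , drop = FALSE]
    rownames(sub) <- NULL
    memb <- match_components(sub, ro_threshold, ins_window, ins_ratio)
    for (comp in split(seq_len(nrow(sub)), memb)) {
      grp <- sub[comp, , drop = FALSE]
      callers <- unique(grp$caller_id)
      if (length(callers) < min_support) next
      med0 <- stats::median(grp$start)
      pick <- vapply(callers, function(cl) {
        rows <- which(grp$caller_id == cl)
        d <- abs(grp$start[rows] - med0)
        rows[order(d, grp$start[rows], grp$length[rows])[1]]
      }, integer(1))
      sel <- grp[pick, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        chrom = grp$chrom[1],
        start = as.integer(round_half_up(stats::median(sel$start))),
        length = as.integer(round_half_up(stats::median(sel$length))),
        svtype = type,
        sample_id = sid,
        acmg_class = if (all(is.na(grp$acmg_class))) NA_integer_
                     else max(grp$acmg_class, na.rm = TRUE),
        n_callers = length(callers),
        callers = paste(sort(callers), collapse = ","),
        stringsAsFactors = FALSE
      )
      res[[length(res)]]$members <- list(grp)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$svtype, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge calls for every sample in a cohort
#'
#' @param calls SV call table covering several samples.
#' @inheritParams merge_sample_calls
#' @return row-bound consensus tables for all samples.
#' @export
merge_cohort_calls <- function(calls, ro_threshold = 0.7, ins_window = 500,
                               ins_ratio = 0.7, min_support = 2) {
  parts <- lapply(split(calls, calls$sample_id), merge_sample_calls,
                  ro_threshold = ro_threshold, ins_window = ins_window,
                  ins_ratio = ins_ratio, min_support = min_support)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
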