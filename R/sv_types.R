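#' @keywords internal
"_PACKAGE"

SV_TYPES <- c("DEL", "INS", "DUP", "INV")
SPAN_TYPES <- c("DEL", "DUP", "INV")

#' Construct a table of structural-variant calls
#'
#' The central container of the package: one row per call made by one caller
#' for one sample. Coordinates are 1-based; a span-type SV (DEL/DUP/INV) of
#' length L starting at `start` occupies positions `start .. start + L - 1`;
#' an insertion (INS) is anchored at `start` and `length` is the inserted
#' sequence length.
#'
#' @param chrom contig names (character).
#' @param start 1-based leftmost positions (integer, >= 1).
#' @param length event sizes in bp (integer, >= 1).
#' @param svtype SV types, each one of `DEL`, `INS`, `DUP`, `INV`.
#' @param sample_id,caller_id sample and caller identifiers (character).
#' @param acmg_class optional ACMG pathogenicity class, integer 1 (benign)
#'   to 5 (pathogenic); `NA` when unclassified.
#' @param ... further columns recycled to the common length (e.g. `gene`,
#'   `location`, truth bookkeeping columns).
#' @return a `data.frame` of calls, validated by [validate_sv_calls()].
#' @export
sv_calls <- function(chrom = character(), start = integer(), length = integer(),
                     svtype = character(), sample_id = NA_character_,
                     caller_id = NA_character_, acmg_class = NA_integer_, ...) {
  n <- max(length(chrom), length(start), length(length), length(svtype))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    length = rep_len(as.integer(length), n),
    svtype = rep_len(as.character(svtype), n),
    sample_id = rep_len(as.character(sample_id), n),
    caller_id = rep_len(as.character(caller_id), n),
    acmg_class = rep_len(as.integer(acmg_class), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_sv_calls(df)
}

#' Validate a table of SV calls
#'
#' Checks the container invariants: required columns present, `start >= 1`,
#' `length >= 1`, `svtype` within the supported set, `acmg_class` in 1..5
#' or `NA`.
#'
#' @param svs a data.frame as produced by [sv_calls()].
#' @return `svs`, invisibly unchanged, or an error.
#' @export
validate_sv_calls <- function(svs) {
  req <- c("chrom", "start", "length", "svtype")
  miss <- setdiff(req, names(svs))
  if (length(miss))
    stop("SV call table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(svs)) {
    if (any(svs$start < 1L, na.rm = TRUE)) stop("SV starts must be >= 1")
    if (any(svs$length < 1L, na.rm = TRUE)) stop("SV lengths must be >= 1")
    bad <- setdiff(unique(svs$svtype), SV_TYPES)
    if (length(bad))
      stop("unsupported svtype(s): ", paste(bad, collapse = ", "))
    if ("acmg_class" %in% names(svs)) {
      cls <- svs$acmg_class[!is.na(svs$acmg_class)]
      if (length(cls) && (any(cls < 1L) || any(cls > 5L)))
        stop("acmg_class must be in 1..5")
    }
  }
  svs
}

#' Construct a cohort manifest
#'
#' Maps each sequenced sample to its role in the family-based contrast.
#' Pedigree topology is deliberately not modelled: the analysis only needs
#' to know which samples are affected probands and which are unaffected
#' relatives serving as within-family controls.
#'
#' @param sample_id sample identifiers (unique).
#' @param role one of `"proband"` or `"unaffected_relative"` per sample.
#' @param family_id optional family labels.
#' @return a `data.frame` with class `cohort_manifest`.
#' @export
cohort_manifest <- function(sample_id, role, family_id = NA_character_) {
  if (anyDuplicated(sample_id)) stop("duplicated sample_id in manifest")
  ok <- c("proband", "unaffected_relative")
  if (!all(role %in% ok))
    stop("roles must be 'proband' or 'unaffected_relative'")
  if (!any(role == "proband")) stop("manifest needs at least one proband")
  out <- data.frame(sample_id = as.character(sample_id),
                    role = as.character(role),
                    family_id = as.character(family_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' Default study-design manifest: 10 probands, 5 unaffected relatives
#'
#' @param n_probands,n_relatives cohort sizes.
#' @return a [cohort_manifest()].
#' @export
default_manifest <- function(n_probands = 10, n_relatives = 5) {
  cohort_manifest(
    sample_id = c(paste0("AP", seq_len(n_probands)),
                  paste0("AC", seq_len(n_relatives))),
    role = c(rep("proband", n_probands),
             rep("unaffected_relative", n_relatives))
  )
}

# round half away from zero (R's round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# GRanges view of span-type calls; INS become width-1 anchors
sv_granges <- function(svs) {
  width <- ifelse(svs$svtype == "INS", 1L, svs$length)
  GenomicRanges::GRanges(
    seqnames = svs$chrom,
    ranges = IRanges::IRanges(start = svs$start, width = width)
  )
}
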