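#' SV length mixture model
#'
#' Three-component model of the medium-sized SV length distribution seen in
#' long-read call sets: a small-event tail (shifted, truncated geometric on
#' `[min_length, tail_max]` with median near 60 bp), an Alu-like mode and an
#' L1-like mode (normals on the log10-length scale centred at 2.5 and 3.8,
#' i.e. ~300 bp and ~6,000 bp - the two retrotransposon peaks of the
#' insertion/deletion length density).
#'
#' @param weights mixture weights (tail, Alu, L1); must sum to 1.
#' @param tail_max upper bound of the small-event tail (bp).
#' @param tail_p geometric success probability of the tail component.
#' @param alu_mode,l1_mode component locations on the log10 scale.
#' @param log10_sd component scale on the log10 scale.
#' @param min_length minimum SV length (bp).
#' @return a `sv_length_model` list.
#' @export
sv_length_model <- function(weights = c(tail = 0.55, alu = 0.35, l1 = 0.10),
                            tail_max = 200, tail_p = 0.023,
                            alu_mode = 2.5, l1_mode = 3.8, log10_sd = 0.08,
                            min_length = 30) {
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(weights = weights, tail_max = tail_max, tail_p = tail_p,
                 alu_mode = alu_mode, l1_mode = l1_mode, log10_sd = log10_sd,
                 min_length = min_length), class = "sv_length_model")
}

#' Sample SV lengths from a length model
#'
#' Draws from the current RNG state; seed control belongs to the calling
#' simulation operation.
#'
#' @param n number of lengths.
#' @param model an [sv_length_model()].
#' @return integer lengths, all `>= model$min_length`.
#' @export
sample_sv_lengths <- function(n, model = sv_length_model()) {
  comp <- sample.int(3, n, replace = TRUE, prob = model$weights)
  len <- integer(n)
  n_tail <- sum(comp == 1)
  if (n_tail) {
    # truncated geometric via inverse CDF on the admissible range
    span <- model$tail_max - model$min_length
    u <- stats::runif(n_tail)
    cdf_max <- 1 - (1 - model$tail_p)^(span + 1)
    g <- floor(log1p(-u * cdf_max) / log1p(-model$tail_p))
    len[comp == 1] <- model$min_length + pmin(g, span)
  }
  for (ci in 2:3) {
    m <- sum(comp == ci)
    if (!m) next
    mu <- if (ci == 2) model$alu_mode else model$l1_mode
    len[comp == ci] <- as.integer(round(10^stats::rnorm(m, mu, model$log10_sd)))
  }
  pmax(len, model$min_length)
}

#' Caller error profile
#'
#' @param caller_id caller name.
#' @param sensitivity probability that a true SV carried by a sample is
#'   reported by this caller.
#' @param breakpoint_jitter SD (bp) of the Gaussian start-position error.
#' @param length_jitter SD (bp) of the Gaussian length error.
#' @param false_rate expected number of spurious calls per sample.
#' @return a one-row data.frame.
#' @export
caller_profile <- function(caller_id, sensitivity = 0.9, breakpoint_jitter = 20,
                           length_jitter = 0, false_rate = 0) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  if (breakpoint_jitter < 0 || length_jitter < 0) stop("jitters must be >= 0")
  data.frame(caller_id = caller_id, sensitivity = sensitivity,
             breakpoint_jitter = breakpoint_jitter,
             length_jitter = length_jitter, false_rate = false_rate,
             stringsAsFactors = FALSE)
}

#' Default caller profiles
#'
#' Four long-read profiles (high sensitivity, small breakpoint error) and,
#' optionally, four short-read profiles (lower sensitivity for
#' medium-sized events, larger breakpoint error) mirroring the
#' four-plus-four caller design of a long-read discovery / short-read
#' confirmation study.
#'
#' @param platform `"long_read"`, `"short_read"`, or both.
#' @return row-bound [caller_profile()] table.
#' @export
default_caller_profiles <- function(platform = "long_read") {
  platform <- match.arg(platform, c("long_read", "short_read"), several.ok = TRUE)
  long <- do.call(rbind, lapply(c("sniffles_like", "svim_like", "pbsv_like",
                                  "cutesv_like"), caller_profile,
                                sensitivity = 0.9, breakpoint_jitter = 20,
                                length_jitter = 5, false_rate = 5))
  short <- do.call(rbind, lapply(c("readdepth_like", "splitread_like",
                                   "pairedend_like", "softclip_like"),
                                 caller_profile,
                                 sensitivity = 0.55, breakpoint_jitter = 60,
                                 length_jitter = 20, false_rate = 10))
  out <- rbind(if ("long_read" %in% platform) long,
               if ("short_read" %in% platform) short)
  rownames(out) <- NULL
  out
}

#' Toy genome contig table
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (bp).
#' @return data.frame with `chrom` and `length`.
#' @export
toy_genome <- function(n_contigs = 2, contig_length = 5e7) {
  data.frame(chrom = paste0("chr", seq_len(n_contigs)),
             length = as.integer(contig_length), stringsAsFactors = FALSE)
}

DEFAULT_TYPE_MIX <- c(DEL = 0.45, INS = 0.45, DUP = 0.06, INV = 0.04)

#' Simulate a cohort truth set
#'
#' Plants two kinds of true SVs on a toy genome: *shared* SVs carried by a
#' random subset of samples - each sample independently with probability
#' 1/2, forced to include at least one carrier and at least one unaffected
#' relative, so that "shared" always means present on both sides of the
#' affection contrast - and *case-specific* SVs, each planted in one
#' randomly chosen proband and never in any relative. Case-specific SVs are
#' always ACMG class 4 (the signal the family filter is meant to recover);
#' shared SVs are class 4 with probability `prop_pathogenic`, otherwise
#' class 1-3. SV positions are spaced at least `min_separation` bp apart so
#' distinct true events can never merge.
#'
#' @param manifest a [cohort_manifest()].
#' @param length_model an [sv_length_model()].
#' @param n_shared,n_case_specific SV counts.
#' @param genome contig table ([toy_genome()]).
#' @param type_mix named probabilities over DEL/INS/DUP/INV.
#' @param prop_pathogenic fraction of shared SVs that are class >= 4.
#' @param min_separation minimum distance between planted SVs (bp).
#' @param models optional [gene_models()]; when given, a fraction
#'   `frac_genic` of the SVs is relocated into gene bodies (at most one SV
#'   per gene), mimicking the predominantly intragenic composition of
#'   published likely-pathogenic SV sets.
#' @param frac_genic fraction of SVs placed inside genes when `models` is
#'   supplied.
#' @param seed integer seed; the truth set is reproducible given it.
#' @return a `truth_set`: `$svs` (with `sv_id`, `case_specific`,
#'   `acmg_class`), `$carriers` (long `sv_id`/`sample_id` table),
#'   `$manifest`, `$genome`, `$length_model`, `$type_mix`.
#' @export
simulate_truth <- function(manifest, length_model = sv_length_model(),
                           n_shared = 200, n_case_specific = 30,
                           genome = toy_genome(),
                           type_mix = DEFAULT_TYPE_MIX,
                           prop_pathogenic = 0.5, min_separation = 1e4,
                           models = NULL, frac_genic = 0.6, seed = 1) {
  probands <- manifest$sample_id[manifest$role == "proband"]
  relatives <- manifest$sample_id[manifest$role == "unaffected_relative"]
  if (n_case_specific > 0 && !length(probands))
    stop("case-specific SVs require at least one proband")
  n <- n_shared + n_case_specific
  withr::with_seed(seed, {
    lens <- sample_sv_lengths(n, length_model)
    if (any(lens >= min(genome$length))) stop("contigs shorter than sampled SV length")
    # lay SVs on a genome-wide grid of well-separated slots
    slots_per_contig <- floor(genome$length / min_separation) - 1L
    slot <- sample.int(sum(slots_per_contig), n)
    contig_idx <- findInterval(slot - 1L, cumsum(c(0L, slots_per_contig)),
                               rightmost.closed = FALSE)
    within <- slot - c(0L, cumsum(slots_per_contig))[contig_idx]
    start <- as.integer(within * min_separation -
                          sample.int(min_separation %/% 2L, n, replace = TRUE))
    svs <- data.frame(
      sv_id = sprintf("sv%04d", seq_len(n)),
      chrom = genome$chrom[contig_idx],
      start = pmax(start, 1L),
      length = lens,
      svtype = sample(names(type_mix), n, replace = TRUE, prob = type_mix),
      case_specific = rep(c(FALSE, TRUE), c(n_shared, n_case_specific)),
      stringsAsFactors = FALSE
    )
    if (!is.null(models)) {
      bodies <- do.call(rbind, lapply(unique(models$gene), function(g) {
        ex <- models[models$gene == g, ]
        data.frame(gene = g, chrom = ex$chrom[1], start = min(ex$start),
                   end = max(ex$end), stringsAsFactors = FALSE)
      }))
      genic <- which(stats::runif(n) < frac_genic)
      if (length(genic) > nrow(bodies))
        genic <- sort(sample(genic, nrow(bodies)))
      picks <- sample.int(nrow(bodies), length(genic))
      room <- pmax(1L, bodies$end[picks] - bodies$start[picks] -
                     svs$length[genic])
      svs$chrom[genic] <- bodies$chrom[picks]
      svs$start[genic] <- bodies$start[picks] +
        vapply(room, function(r) sample.int(r, 1), integer(1))
    }
    svs$acmg_class <- ifelse(svs$case_specific, 4L,
                             ifelse(stats::runif(n) < prop_pathogenic, 4L,
                                    sample(1:3, n, replace = TRUE)))
    carriers <- lapply(seq_len(n), function(i) {
      if (svs$case_specific[i]) sample(probands, 1)
      else {
        carry <- manifest$sample_id[stats::runif(nrow(manifest)) < 0.5]
        if (!length(carry)) carry <- sample(manifest$sample_id, 1)
        if (length(relatives) && !any(carry %in% relatives))
          carry <- c(carry, sample(relatives, 1))
        carry
      }
    })
    carriers <- data.frame(sv_id = rep(svs$sv_id, lengths(carriers)),
                           sample_id = unlist(carriers),
                           stringsAsFactors = FALSE)
    structure(list(svs = svs, carriers = carriers, manifest = manifest,
                   genome = genome, length_model = length_model,
                   type_mix = type_mix), class = "truth_set")
  })
}

#' Emulate imperfect SV callers on a truth set
#'
#' Each true SV carried by a sample is detected by each caller
#' independently with the caller's sensitivity; detected calls get Gaussian
#' start and length perturbations (rounded, lengths floored at 1 bp).
#' Spurious calls (Poisson with the caller's `false_rate` per sample) are
#' drawn from the truth set's length model at uniform positions, with types
#' from the truth type mix and classes 1-3.
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param profiles [caller_profile()] table (at least one row).
#' @param seed integer seed.
#' @return an SV call table with bookkeeping columns `truth_id`
#'   (`NA` for false calls).
#' @export
emulate_callers <- function(truth, profiles, seed = 1) {
  if (!nrow(profiles)) stop("at least one caller profile is required")
  events <- merge(truth$carriers, truth$svs, by = "sv_id")
  withr::with_seed(seed, {
    parts <- list()
    for (ci in seq_len(nrow(profiles))) {
      pr <- profiles[ci, ]
      det <- stats::runif(nrow(events)) < pr$sensitivity
      if (any(det)) {
        e <- events[det, , drop = FALSE]
        start <- pmax(1L, as.integer(round(e$start +
                  stats::rnorm(nrow(e), 0, pr$breakpoint_jitter))))
        len <- pmax(1L, as.integer(round(e$length +
                  stats::rnorm(nrow(e), 0, pr$length_jitter))))
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = e$chrom, start = start, length = len, svtype = e$svtype,
          sample_id = e$sample_id, caller_id = pr$caller_id,
          acmg_class = e$acmg_class, truth_id = e$sv_id,
          stringsAsFactors = FALSE)
      }
      if (pr$false_rate > 0) {
        for (sid in truth$manifest$sample_id) {
          nf <- stats::rpois(1, pr$false_rate)
          if (!nf) next
          contig <- sample.int(nrow(truth$genome), nf, replace = TRUE)
          lens <- sample_sv_lengths(nf, truth$length_model)
          parts[[length(parts) + 1L]] <- data.frame(
            chrom = truth$genome$chrom[contig],
            start = as.integer(ceiling(stats::runif(nf) *
                     (truth$genome$length[contig] - lens))),
            length = lens,
            svtype = sample(names(truth$type_mix), nf, replace = TRUE,
                            prob = truth$type_mix),
            sample_id = sid, caller_id = pr$caller_id,
            acmg_class = sample(1:3, nf, replace = TRUE),
            truth_id = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, parts)
    if (is.null(out))
      return(sv_calls(sample_id = character(), caller_id = character(),
                      truth_id = character()))
    out <- out[order(out$sample_id, out$caller_id, out$chrom, out$start), ,
               drop = FALSE]
    rownames(out) <- NULL
    validate_sv_calls(out)
  })
}

#' Match SV calls back to planted truth
#'
#' Audit helper: each call (or consensus SV) is matched to a truth SV of
#' the same sample-agnostic locus using the same predicate as the pipeline
#' (reciprocal overlap for span types, [insertions_match()] for INS).
#'
#' @param svs SV table to audit.
#' @param truth a `truth_set`.
#' @param ro_threshold,ins_window,ins_ratio match-predicate parameters.
#' @return character vector of matched `sv_id` (NA where unmatched).
#' @export
match_to_truth <- function(svs, truth, ro_threshold = 0.7, ins_window = 500,
                           ins_ratio = 0.7) {
  out <- rep(NA_character_, nrow(svs))
  tr <- truth$svs
  for (i in seq_len(nrow(svs))) {
    cand <- which(tr$svtype == svs$svtype[i] & tr$chrom == svs$chrom[i])
    if (!length(cand)) next
    if (svs$svtype[i] == "INS") {
      ok <- insertions_match(svs[i, , drop = FALSE], tr[cand, , drop = FALSE],
                             window = ins_window, length_ratio = ins_ratio)
    } else {
      ok <- reciprocal_overlap(svs[i, , drop = FALSE],
                               tr[cand, , drop = FALSE]) >= ro_threshold
    }
    if (any(ok)) out[i] <- tr$sv_id[cand[ok][1]]
  }
  out
}

#' Audit a retained consensus set against planted truth labels
#'
#' Uses the `truth_id` bookkeeping carried by the emulated calls (via the
#' consensus `members` list-column) rather than interval matching, so the
#' audit is exact: each retained SV is attributed to the planted SV its
#' member calls came from (`NA` for groups of purely spurious calls).
#'
#' @param retained consensus SV table with a `members` list-column whose
#'   member calls carry `truth_id`.
#' @param truth a `truth_set`.
#' @return list with `n_planted`, `n_recovered` (distinct case-specific
#'   truth SVs among the retained members), `recovery` (their ratio),
#'   `n_shared_retained` (retained SVs attributed to a non-case-specific
#'   truth SV) and `n_unattributed` (retained SVs with no truth label).
#' @export
audit_retained <- function(retained, truth) {
  stopifnot("members" %in% names(retained))
  attributed <- vapply(retained$members, function(m) {
    ids <- m$truth_id[!is.na(m$truth_id)]
    if (!length(ids)) NA_character_
    else names(sort(table(ids), decreasing = TRUE))[1]
  }, character(1))
  planted <- truth$svs$sv_id[truth$svs$case_specific]
  shared <- truth$svs$sv_id[!truth$svs$case_specific]
  list(
    n_planted = length(planted),
    n_recovered = length(intersect(attributed, planted)),
    recovery = length(intersect(attributed, planted)) / max(1L, length(planted)),
    n_shared_retained = sum(attributed %in% shared),
    n_unattributed = sum(is.na(attributed))
  )
}

#' Simulate toy gene models covering a genome
#'
#' Places non-overlapping multi-exon genes along each contig; half on each
#' strand. Used to exercise annotation and to provide gene names for the
#' enrichment stages.
#'
#' @param genome contig table.
#' @param n_genes number of genes.
#' @param exons_per_gene exon count per gene.
#' @param exon_length,intron_length feature sizes (bp).
#' @param seed integer seed.
#' @return a [gene_models()] object.
#' @export
simulate_gene_models <- function(genome, n_genes = 100, exons_per_gene = 8,
                                 exon_length = 200, intron_length = 8000,
                                 seed = 1) {
  gene_span <- exons_per_gene * exon_length +
    (exons_per_gene - 1) * intron_length
  per_contig <- ceiling(n_genes / nrow(genome))
  withr::with_seed(seed, {
    parts <- list()
    g <- 0L
    for (ci in seq_len(nrow(genome))) {
      pitch <- floor(genome$length[ci] / per_contig)
      if (pitch <= gene_span) stop("genome too small for requested gene models")
      for (j in seq_len(per_contig)) {
        if (g >= n_genes) break
        g <- g + 1L
        gstart <- (j - 1L) * pitch + sample.int(pitch - gene_span, 1)
        ex_start <- gstart + (seq_len(exons_per_gene) - 1L) *
          (exon_length + intron_length)
        parts[[g]] <- data.frame(
          gene = sprintf("G%03d", g), chrom = genome$chrom[ci],
          strand = if (g %% 2L) "+" else "-",
          start = as.integer(ex_start),
          end = as.integer(ex_start + exon_length - 1L),
          stringsAsFactors = FALSE)
      }
    }
    gene_models(do.call(rbind, parts))
  })
}

#' Simulate pathway gene sets
#'
#' Random gene sets over a gene universe, optionally with one planted term
#' containing a given gene list (to verify that enrichment recovers it).
#'
#' @param genes gene universe (character).
#' @param n_terms number of random terms.
#' @param size_range term size range (uniform draw).
#' @param planted optional character vector: genes of one extra term
#'   (`"PLANTED"`) appended after the random ones.
#' @param seed integer seed.
#' @return gene-set table in the [read_gmt()] layout.
#' @export
simulate_pathways <- function(genes, n_terms = 50, size_range = c(30, 300),
                              planted = NULL, seed = 1) {
  withr::with_seed(seed, {
    sizes <- sample(size_range[1]:min(size_range[2], length(genes)),
                    n_terms, replace = TRUE)
    out <- data.frame(term_id = sprintf("T%04d", seq_len(n_terms)),
                      term_name = sprintf("random term %d", seq_len(n_terms)),
                      stringsAsFactors = FALSE)
    out$genes <- lapply(sizes, function(s) sample(genes, s))
    if (!is.null(planted)) {
      row <- data.frame(term_id = "PLANTED", term_name = "planted term",
                        stringsAsFactors = FALSE)
      row$genes <- list(unique(planted))
      out <- rbind(out, row)
    }
    out
  })
}

#' Simulate a region-by-stage expression matrix with optional planted signal
#'
#' Baseline expression is i.i.d. normal per gene and cell. When an
#' `enriched_region_stage` is given, the target genes are shifted upward by
#' `effect` (in baseline SD units) in that cell only. Two brain-versus-body
#' log2 fold-change tables are generated with a configurable fraction of
#' brain-biased genes (all target genes are brain-biased, mirroring the use
#' of a brain-expressed background).
#'
#' @param genes gene universe.
#' @param n_regions,n_stages grid size (defaults 16 x 5).
#' @param enriched_region_stage optional `c(region, stage)` pair.
#' @param target_genes genes receiving the shift (subset of `genes`).
#' @param effect expression shift in SD units (0 = null).
#' @param baseline_mean,baseline_sd baseline distribution parameters.
#' @param frac_brain_biased fraction of non-target genes marked
#'   brain-biased in each fold-change table.
#' @param seed integer seed.
#' @return list with `$matrix` (genes x `"region|stage"`), `$fc_a`, `$fc_b`
#'   (gene/log2fc tables), `$regions`, `$stages`.
#' @export
simulate_expression <- function(genes, n_regions = 16, n_stages = 5,
                                enriched_region_stage = NULL,
                                target_genes = character(), effect = 0,
                                baseline_mean = 5, baseline_sd = 1,
                                frac_brain_biased = 0.8, seed = 1) {
  stopifnot(all(target_genes %in% genes))
  regions <- DEFAULT_REGIONS[seq_len(n_regions)]
  stages <- DEFAULT_STAGES[seq_len(n_stages)]
  cells <- as.vector(outer(regions, stages, cell_name))
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(genes) * length(cells), baseline_mean,
                             baseline_sd),
                nrow = length(genes), dimnames = list(genes, cells))
    if (!is.null(enriched_region_stage) && length(target_genes) && effect != 0) {
      col <- cell_name(enriched_region_stage[1], enriched_region_stage[2])
      if (!col %in% cells) stop("unknown enriched cell ", col)
      m[target_genes, col] <- m[target_genes, col] + effect * baseline_sd
    }
    fc <- function() {
      biased <- genes %in% target_genes |
        stats::runif(length(genes)) < frac_brain_biased
      data.frame(gene = genes,
                 log2fc = ifelse(biased,
                                 stats::runif(length(genes), 0.6, 3),
                                 stats::runif(length(genes), -1, 0.4)),
                 stringsAsFactors = FALSE)
    }
    list(matrix = m, fc_a = fc(), fc_b = fc(), regions = regions,
         stages = stages)
  })
}

#' Write a complete synthetic cohort to disk
#'
#' Materializes everything the pipeline reads: per-sample per-caller VCFs,
#' a sample sheet, gene models (BED12), pathway GMT, expression matrix and
#' fold-change TSVs, and the truth tables for auditing.
#'
#' @param dir output directory (created if needed).
#' @param manifest,length_model,profiles,genome see [simulate_truth()] and
#'   [emulate_callers()].
#' @param n_shared,n_case_specific planted SV counts.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return (invisibly) a list with the truth set and all written paths.
#' @export
simulate_cohort_files <- function(dir, manifest = default_manifest(),
                                  length_model = sv_length_model(),
                                  profiles = default_caller_profiles(),
                                  genome = toy_genome(),
                                  n_shared = 200, n_case_specific = 30,
                                  seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- simulate_gene_models(genome, seed = seed + 2L)
  truth <- simulate_truth(manifest, length_model, n_shared = n_shared,
                          n_case_specific = n_case_specific, genome = genome,
                          models = models, seed = seed)
  calls <- emulate_callers(truth, profiles, seed = seed + 1L)
  sheet <- list()
  for (sid in manifest$sample_id) {
    for (cid in profiles$caller_id) {
      sub <- calls[calls$sample_id == sid & calls$caller_id == cid, , drop = FALSE]
      vcf <- file.path(dir, paste0(sid, ".", cid, ".vcf"))
      write_sv_vcf(sub, vcf)
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample_id = sid, caller_id = cid,
        role = manifest$role[manifest$sample_id == sid], vcf = vcf,
        stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, sheet)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)

  bed_path <- file.path(dir, "genes.bed")
  write_gene_models_bed(models, bed_path)

  genes <- unique(models$gene)
  universe <- c(genes, sprintf("BG%04d", seq_len(2000)))
  pathways <- simulate_pathways(universe, planted = genes, seed = seed + 3L)
  gmt_path <- file.path(dir, "pathways.gmt")
  write_gmt(pathways, gmt_path)

  expr <- simulate_expression(universe, target_genes = genes, effect = 3,
                              enriched_region_stage = c("striatum", "adolescent"),
                              seed = seed + 4L)
  expr_path <- file.path(dir, "expression.tsv")
  write_expression_matrix(expr$matrix, expr_path)
  fc_a_path <- file.path(dir, "brain_fc_a.tsv")
  fc_b_path <- file.path(dir, "brain_fc_b.tsv")
  utils::write.table(expr$fc_a, fc_a_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$fc_b, fc_b_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_path <- file.path(dir, "truth_svs.tsv")
  utils::write.table(truth$svs, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  carriers_path <- file.path(dir, "truth_carriers.tsv")
  utils::write.table(truth$carriers, carriers_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(truth = truth, calls = calls,
                 paths = list(sample_sheet = sheet_path, genes_bed = bed_path,
                              pathways_gmt = gmt_path, expression = expr_path,
                              fc_a = fc_a_path, fc_b = fc_b_path,
                              truth = truth_path, carriers = carriers_path)))
}

#' Write gene models as BED12
#'
#' @param models a [gene_models()] object.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(models, path) {
  rows <- vapply(unique(models$gene), function(g) {
    ex <- models[models$gene == g, , drop = FALSE]
    ex <- ex[order(ex$start), ]
    chrom_start <- ex$start[1] - 1L            # BED is 0-based half-open
    paste(ex$chrom[1], chrom_start, max(ex$end), g, 0, ex$strand[1],
          chrom_start, max(ex$end), "0,0,0", nrow(ex),
          paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
          paste0(paste(ex$start - 1L - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
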