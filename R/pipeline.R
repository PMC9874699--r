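#' Assemble and validate a pipeline configuration
#'
#' A declarative description of one end-to-end run: input paths, every
#' stage threshold, and the master seed. Validation is strict and happens
#' before any work: a malformed threshold aborts immediately.
#'
#' @param sample_sheet TSV with columns `sample_id`, `caller_id`, `role`,
#'   `vcf` (one row per sample-caller VCF).
#' @param genes_bed BED12 gene models (or `genes_gff3` instead).
#' @param genes_gff3 GFF3 gene models (alternative to `genes_bed`).
#' @param pathways_gmt GMT gene sets.
#' @param expression expression matrix TSV (genes x `"region|stage"`).
#' @param fc_a,fc_b brain-versus-body log2 fold-change TSVs.
#' @param outdir output directory.
#' @param ro_threshold reciprocal-overlap threshold in (0, 1].
#' @param min_length minimum SV length (bp).
#' @param min_support minimum supporting callers.
#' @param ins_window,ins_ratio insertion-matching parameters.
#' @param min_class minimum ACMG class (1-5).
#' @param min_bg,max_bg pathway background-count window.
#' @param fdr_cut,strength_cut pathway retention thresholds.
#' @param quantiles expression quantile cutoffs, each in (0, 1).
#' @param permutations FWER permutation count.
#' @param k_pathways,k_genes bi-cluster cut sizes.
#' @param seed master seed (mandatory; all stochastic stages derive from it).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, genes_bed = NULL, genes_gff3 = NULL,
                            pathways_gmt = NULL, expression = NULL,
                            fc_a = NULL, fc_b = NULL, outdir,
                            ro_threshold = 0.7, min_length = 30,
                            min_support = 2, ins_window = 500, ins_ratio = 0.7,
                            min_class = 4, min_bg = 30, max_bg = 1000,
                            fdr_cut = 0.05, strength_cut = 0.5,
                            quantiles = seq(0.5, 0.9, by = 0.1),
                            permutations = 1000, k_pathways = 9, k_genes = 8,
                            seed = 1) {
  cfg <- as.list(environment())
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$ro_threshold > 0 && cfg$ro_threshold <= 1,
      "ro_threshold must be in (0, 1]")
  chk(cfg$ins_ratio > 0 && cfg$ins_ratio <= 1, "ins_ratio must be in (0, 1]")
  chk(cfg$min_length >= 1, "min_length must be >= 1")
  chk(cfg$min_support >= 1, "min_support must be >= 1")
  chk(cfg$min_class >= 1 && cfg$min_class <= 5, "min_class must be in 1..5")
  chk(cfg$min_bg >= 1 && cfg$max_bg >= cfg$min_bg,
      "background window must satisfy 1 <= min_bg <= max_bg")
  chk(cfg$fdr_cut > 0 && cfg$fdr_cut < 1, "fdr_cut must be in (0, 1)")
  chk(all(cfg$quantiles > 0 & cfg$quantiles < 1), "quantiles must be in (0, 1)")
  chk(cfg$permutations >= 1, "permutations must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed),
      "seed is mandatory")
  chk(!is.null(cfg$genes_bed) || !is.null(cfg$genes_gff3),
      "gene models (BED12 or GFF3) are required")
  structure(cfg, class = "pipeline_config")
}

#' Run the full family-based SV pipeline
#'
#' Executes, in order: per-caller VCF loading, per-sample multi-caller
#' consensus, ACMG class filtering, family subtraction (proband-exclusive),
#' gene/feature annotation, summary statistics, pathway
#' over-representation, membership bi-clustering, and brain region-stage
#' enrichment with permutation FWER. Every stage writes a TSV into
#' `cfg$outdir` and contributes record counts to `manifest.json`; re-running
#' the same config reproduces every output bit for bit.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(parameters = cfg[!(names(cfg) %in%
    c("sample_sheet", "genes_bed", "genes_gff3", "pathways_gmt", "expression",
      "fc_a", "fc_b", "outdir"))])
  class(manifest$parameters) <- NULL

  sheet <- stage("load", {
    s <- utils::read.delim(cfg$sample_sheet, stringsAsFactors = FALSE)
    req <- c("sample_id", "caller_id", "role", "vcf")
    if (!all(req %in% names(s))) stop("sample sheet needs columns ",
                                      paste(req, collapse = ", "))
    s
  })
  calls <- stage("load", do.call(rbind, lapply(seq_len(nrow(sheet)), function(i)
    read_sv_vcf(sheet$vcf[i], sheet$sample_id[i], sheet$caller_id[i],
                min_length = cfg$min_length))))
  manifest$counts <- list(input_calls = nrow(calls))
  man <- cohort_manifest(unique(sheet$sample_id),
                         sheet$role[!duplicated(sheet$sample_id)])

  filtered <- stage("family_filter", run_direction(
    calls, man, "proband_exclusive", ro_threshold = cfg$ro_threshold,
    ins_window = cfg$ins_window, ins_ratio = cfg$ins_ratio,
    min_support = cfg$min_support, min_class = cfg$min_class))
  manifest$counts <- c(manifest$counts, as.list(filtered$counters))
  stage("family_filter", {
    write_sv_table(filtered$retained, out("proband_exclusive.tsv"))
    write_filter_audit(filtered, out("filter_audit.tsv"))
  })

  models <- stage("annotation", {
    if (!is.null(cfg$genes_bed)) read_gene_models_bed(cfg$genes_bed)
    else read_gene_models_gff3(cfg$genes_gff3)
  })
  annotated <- stage("annotation", annotate_svs(filtered$retained, models))
  stage("annotation", write_sv_table(annotated, out("annotated.tsv")))
  summary <- summarize_svs(annotated)
  write_sv_summary(summary, out("summary.tsv"))
  manifest$counts$annotated_genes <- summary$n_distinct_genes

  results <- list(calls = calls, filtered = filtered, annotated = annotated,
                  summary = summary)

  query <- unique(annotated$gene[!is.na(annotated$gene)])
  if (!is.null(cfg$pathways_gmt) && length(query)) {
    pathways <- stage("enrichment", read_gmt(cfg$pathways_gmt))
    er <- stage("enrichment", {
      bg <- unique(unlist(pathways$genes))
      enrich(intersect(query, bg), pathways, background_genes = bg,
             min_bg = cfg$min_bg, max_bg = cfg$max_bg,
             fdr_cut = cfg$fdr_cut, strength_cut = cfg$strength_cut)
    })
    utils::write.table(er, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$counts$enriched_pathways <- nrow(er)
    results$enrichment <- er
    if (nrow(er) >= 2) {
      bc <- stage("bicluster", {
        retained <- pathways[pathways$term_id %in% er$term_id, , drop = FALSE]
        m <- membership_matrix(query, retained)
        bicluster(m, k_pathways = min(cfg$k_pathways, ncol(m)),
                  k_genes = min(cfg$k_genes, nrow(m)))
      })
      write_bicluster_labels(bc, out("bicluster_labels.tsv"))
      results$bicluster <- bc
    }
  }

  if (!is.null(cfg$expression) && length(query)) {
    brain <- stage("brain_enrichment", {
      mat <- read_expression_matrix(cfg$expression)
      fca <- utils::read.delim(cfg$fc_a, stringsAsFactors = FALSE)
      fcb <- utils::read.delim(cfg$fc_b, stringsAsFactors = FALSE)
      bg <- brain_biased_background(fca, fcb)
      obs <- region_stage_enrichment(query, mat, bg, quantiles = cfg$quantiles)
      permutation_fwer(obs, mat, bg, R = cfg$permutations, seed = cfg$seed)
    })
    utils::write.table(brain, out("brain_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fwer_table(brain), out("brain_enrichment_wide.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$brain_cells_significant <-
      sum(fwer_table(brain)$n_signif > 0)
    results$brain <- brain
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Summary report for the packaged published SV fixture
#'
#' Loads the packaged 88-SV proband-exclusive set and computes its summary
#' statistics (overall and for the 51 short-read-confirmed SVs).
#'
#' @param path optional TSV path for the overall summary.
#' @return list with `$all` and `$confirmed` [summarize_svs()] objects.
#' @export
run_fixture_report <- function(path = NULL) {
  fx <- load_paper_fixture()
  all <- summarize_svs(fx)
  confirmed <- summarize_svs(fx[fx$confirmed_by_illumina, , drop = FALSE])
  if (!is.null(path)) write_sv_summary(all, path)
  list(all = all, confirmed = confirmed)
}
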