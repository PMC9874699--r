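#' Build gene models from an exon table
#'
#' A gene model is a set of non-overlapping exons on one strand of one
#' contig; introns are derived as the gaps between consecutive exons.
#' Feature numbering follows transcription order (strand-aware), matching
#' the RefSeq convention used by variant annotators: on the minus strand the
#' genomically last exon is exon 1.
#'
#' @param exons data.frame with columns `gene`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based, closed).
#' @return a `gene_models` object (the exon table, sorted and rank-annotated).
#' @export
gene_models <- function(exons) {
  req <- c("gene", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("exon table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$gene, exons$start), req, drop = FALSE]
  exons$exon_rank <- NA_integer_
  for (ix in split(seq_len(nrow(exons)), exons$gene)) {
    n <- length(ix)
    if (n > 1 && any(exons$end[ix][-n] >= exons$start[ix][-1]))
      stop("overlapping exons in gene ", exons$gene[ix[1]])
    exons$exon_rank[ix] <- if (exons$strand[ix[1]] == "+") seq_len(n) else rev(seq_len(n))
  }
  rownames(exons) <- NULL
  structure(exons, class = c("gene_models", "data.frame"))
}

#' Read gene models from a BED12 file
#'
#' Each BED12 record is one transcript; blocks become exons and the `name`
#' field the gene name. When several records share a name the longest
#' transcript (largest summed exon width) is kept.
#'
#' @param path BED12 file path.
#' @return a [gene_models()] object.
#' @export
read_gene_models_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  blocks <- rtracklayer::blocks(gr)
  pick_longest_transcripts(blocks, names(blocks),
                           as.character(GenomicRanges::strand(gr)))
}

#' Read gene models from a GFF3 file
#'
#' Uses `type == "exon"` records; transcripts are grouped by `Parent` (or
#' `transcript_id`) and genes by `gene_id` (falling back to `gene_name` or
#' `Name`). One transcript per gene is kept: the one with the largest summed
#' exon width.
#'
#' @param path GFF3 file path.
#' @return a [gene_models()] object.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  meta <- S4Vectors::mcols(ex)
  tx <- if ("Parent" %in% names(meta)) as.character(unlist(meta$Parent))
        else as.character(meta$transcript_id)
  gene <- NULL
  for (key in c("gene_id", "gene_name", "Name")) {
    if (key %in% names(meta) && !all(is.na(meta[[key]]))) {
      gene <- as.character(meta[[key]]); break
    }
  }
  if (is.null(gene)) gene <- tx
  exl <- S4Vectors::split(ex, tx)
  gene_of_tx <- vapply(S4Vectors::split(gene, tx), function(g) g[1], character(1))
  strand_of_tx <- vapply(exl, function(e) as.character(GenomicRanges::strand(e))[1],
                         character(1))
  pick_longest_transcripts(exl, gene_of_tx[names(exl)], strand_of_tx)
}

# choose the longest transcript per gene and flatten to an exon table
pick_longest_transcripts <- function(exons_by_tx, gene_of_tx, strand_of_tx) {
  widths <- vapply(exons_by_tx, function(e) sum(GenomicRanges::width(e)), numeric(1))
  keep <- unlist(lapply(split(seq_along(widths), gene_of_tx),
                        function(ix) ix[which.max(widths[ix])]))
  parts <- lapply(keep, function(i) {
    e <- exons_by_tx[[i]]
    data.frame(gene = unname(gene_of_tx[i]),
               chrom = as.character(GenomicRanges::seqnames(e)),
               strand = unname(strand_of_tx[i]),
               start = GenomicRanges::start(e),
               end = GenomicRanges::end(e),
               stringsAsFactors = FALSE)
  })
  gene_models(do.call(rbind, parts))
}

# features (exons + derived introns) of one gene in genomic order, with
# transcription-order labels
gene_features <- function(models, gene) {
  ex <- models[models$gene == gene, , drop = FALSE]
  n <- nrow(ex)
  feats <- data.frame(start = ex$start, end = ex$end,
                      label = paste0("exon", ex$exon_rank),
                      stringsAsFactors = FALSE)
  if (n > 1) {
    intron_rank <- if (ex$strand[1] == "+") seq_len(n - 1) else rev(seq_len(n - 1))
    feats <- rbind(feats, data.frame(
      start = ex$end[-n] + 1L, end = ex$start[-1] - 1L,
      label = paste0("intron", intron_rank), stringsAsFactors = FALSE))
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$txorder <- if (ex$strand[1] == "+") seq_len(nrow(feats)) else rev(seq_len(nrow(feats)))
  feats
}

#' Annotate SVs with genes and intron/exon location labels
#'
#' Each SV is assigned to the gene whose body (first to last exon) it
#' overlaps; with several candidates the gene with the largest overlap wins.
#' Span-type SVs are labelled by the first and last feature they touch in
#' transcription order (`"intron5"`, or `"exon30-intron30"` when spanning a
#' boundary); insertions by the feature containing their anchor. SVs outside
#' every gene body get `gene = NA`.
#'
#' @param svs SV call table.
#' @param models a [gene_models()] object.
#' @return `svs` with `gene` and `location` columns.
#' @export
annotate_svs <- function(svs, models) {
  validate_sv_calls(svs)
  genes <- unique(models$gene)
  body <- do.call(rbind, lapply(genes, function(g) {
    ex <- models[models$gene == g, ]
    data.frame(gene = g, chrom = ex$chrom[1],
               start = min(ex$start), end = max(ex$end),
               stringsAsFactors = FALSE)
  }))
  gr_body <- GenomicRanges::GRanges(body$chrom, IRanges::IRanges(body$start, body$end))
  sv_end <- ifelse(svs$svtype == "INS", svs$start, svs$start + svs$length - 1L)
  gr_sv <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$start, sv_end))
  hits <- GenomicRanges::findOverlaps(gr_sv, gr_body)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_sv[qh], gr_body[sh]))

  svs$gene <- rep(NA_character_, nrow(svs))
  svs$location <- rep(NA_character_, nrow(svs))
  if (length(qh)) {
    best <- tapply(seq_along(qh), qh, function(ix) ix[which.max(ov[ix])])
    for (b in best) {
      i <- qh[b]; g <- body$gene[sh[b]]
      svs$gene[i] <- g
      svs$location[i] <- label_within_gene(svs$start[i], sv_end[i],
                                           gene_features(models, g))
    }
  }
  svs
}

# label one SV interval [s, e] against a gene's feature table
label_within_gene <- function(s, e, feats) {
  touched <- feats$end >= s & feats$start <= e
  if (!any(touched)) return(NA_character_)  # anchors in a flank gap
  lab <- feats$label[touched]
  txo <- feats$txorder[touched]
  first <- lab[which.min(txo)]; last <- lab[which.max(txo)]
  if (first == last) first else paste0(first, "-", last)
}

#' Summary statistics of an annotated SV set
#'
#' The descriptive statistics reported for a proband-exclusive SV set:
#' counts of SVs and distinct genes, genes hit at two or more distinct loci,
#' the length distribution (mean and median reported rounded half-up to
#' whole bp), and per-sample / per-type breakdowns.
#'
#' @param svs annotated SV table (a `gene` column is optional but needed for
#'   the gene counts).
#' @return an object of class `sv_summary` (a list of scalars and tables).
#' @export
summarize_svs <- function(svs) {
  n <- nrow(svs)
  genes <- if ("gene" %in% names(svs)) svs$gene[!is.na(svs$gene)] else character()
  tab <- table(genes)
  out <- list(
    n_svs = n,
    n_distinct_genes = length(tab),
    n_genes_multi_locus = sum(tab >= 2),
    length_min = if (n) min(svs$length) else 0L,
    length_max = if (n) max(svs$length) else 0L,
    length_mean = if (n) as.integer(round_half_up(mean(svs$length))) else 0L,
    length_median = if (n) as.integer(round_half_up(stats::median(svs$length))) else 0L,
    per_sample = if (n) c(table(svs$sample_id)) else integer(),
    per_type = if (n) c(table(svs$svtype)) else integer()
  )
  structure(out, class = "sv_summary")
}

#' @export
print.sv_summary <- function(x, ...) {
  cat("<sv_summary>\n")
  cat(sprintf("  SVs: %d   distinct genes: %d   genes with >=2 loci: %d\n",
              x$n_svs, x$n_distinct_genes, x$n_genes_multi_locus))
  cat(sprintf("  length (bp): min %d, max %d, mean %d, median %d\n",
              x$length_min, x$length_max, x$length_mean, x$length_median))
  cat("  per type: ", paste(names(x$per_type), as.integer(x$per_type),
                            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write an `sv_summary` as a two-column TSV
#'
#' @param s an `sv_summary`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sv_summary <- function(s, path) {
  scalars <- c(n_svs = s$n_svs, n_distinct_genes = s$n_distinct_genes,
               n_genes_multi_locus = s$n_genes_multi_locus,
               length_min = s$length_min, length_max = s$length_max,
               length_mean = s$length_mean, length_median = s$length_median)
  rows <- data.frame(statistic = names(scalars), value = unname(scalars))
  rows <- rbind(rows,
    data.frame(statistic = paste0("n_", names(s$per_type)),
               value = as.integer(s$per_type)),
    data.frame(statistic = paste0("n_sample_", names(s$per_sample)),
               value = as.integer(s$per_sample)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
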