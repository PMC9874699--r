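toy_models <- function(strand = "+") {
  gene_models(data.frame(
    gene = "G1", chrom = "chr1", strand = strand,
    start = c(100L, 300L, 500L), end = c(199L, 399L, 599L)))
}

ann1 <- function(start, length, svtype = "DEL", models = toy_models()) {
  sv <- sv_calls(chrom = "chr1", start = start, length = length,
                 svtype = svtype, sample_id = "S", caller_id = "c")
  annotate_svs(sv, models)
}

test_that("feature labels are strand-aware and numbered in transcription order", {
  expect_equal(ann1(250, 10)$location, "intron1")   # between exon 1 and 2
  expect_equal(ann1(150, 10)$location, "exon1")
  expect_equal(ann1(250, 10, models = toy_models("-"))$location, "intron2")
  expect_equal(ann1(150, 10, models = toy_models("-"))$location, "exon3")
})

test_that("spanning SVs are labelled first-to-last feature in transcription order", {
  expect_equal(ann1(150, 100)$location, "exon1-intron1")
  expect_equal(ann1(150, 250)$location, "exon1-exon2")
  expect_equal(ann1(150, 300)$location, "exon1-intron2")
  # minus strand: genomically-later feature comes first in transcription
  expect_equal(ann1(150, 100, models = toy_models("-"))$location,
               "intron2-exon3")
  # INS labelled by the feature containing the anchor
  expect_equal(ann1(320, 300, "INS")$location, "exon2")
  # outside the gene body
  out <- ann1(10000, 50)
  expect_true(is.na(out$gene) && is.na(out$location))
})

test_that("BED12 and GFF3 gene-model readers agree on a toy annotation", {
  models <- simulate_gene_models(toy_genome(1, 2e6), n_genes = 4,
                                 exons_per_gene = 3, seed = 5)
  bed <- tempfile(fileext = ".bed")
  write_gene_models_bed(models, bed)
  from_bed <- read_gene_models_bed(bed)
  expect_equal(as.data.frame(from_bed), as.data.frame(models))

  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3")
  for (g in unique(models$gene)) {
    ex <- models[models$gene == g, ]
    # two transcripts: the full one and a shorter decoy missing one exon
    lines <- c(lines,
      sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
              min(ex$start), max(ex$end), ex$strand[1], g, g),
      sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s;gene_id=%s",
              min(ex$start), max(ex$end), ex$strand[1], g, g, g),
      sprintf("chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1;gene_id=%s",
              ex$start, ex$end, ex$strand[1], g, g),
      sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t2;Parent=%s;gene_id=%s",
              min(ex$start), max(ex$end[-nrow(ex)]), ex$strand[1], g, g, g),
      sprintf("chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t2;gene_id=%s",
              ex$start[-nrow(ex)], ex$end[-nrow(ex)], ex$strand[1], g, g))
  }
  writeLines(lines, gff)
  from_gff <- read_gene_models_gff3(gff)
  expect_equal(as.data.frame(from_gff), as.data.frame(models))
})

test_that("summarize_svs computes exact counts and rounded length statistics", {
  one <- summarize_svs(sv_calls(chrom = "chr1", start = 1L, length = 77L,
                                svtype = "DEL", sample_id = "S",
                                caller_id = "c"))
  expect_equal(one$length_min, 77L)
  expect_equal(one$length_max, 77L)
  expect_equal(one$length_mean, 77L)
  expect_equal(one$length_median, 77L)

  empty <- summarize_svs(sv_calls())
  expect_equal(empty$n_svs, 0)
  expect_equal(empty$length_mean, 0L)

  svs <- sv_calls(chrom = "chr1", start = c(1:4) * 1000L,
                  length = c(30L, 40L, 41L, 100L), svtype = "DEL",
                  sample_id = c("A", "A", "B", "B"), caller_id = "c")
  svs$gene <- c("g1", "g1", "g2", NA)
  s <- summarize_svs(svs)
  expect_equal(s$n_distinct_genes, 2)
  expect_equal(s$n_genes_multi_locus, 1)
  expect_equal(s$length_median, 41L)  # 40.5 rounds half-up
  expect_equal(s$per_sample[c("A", "B")], c(A = 2L, B = 2L))
})
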