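# famsv — family-based structural variant consensus, filtering and enrichment

`famsv` implements a family-based discovery workflow for medium-sized
structural variants (SVs, ~50–2,000 bp) — the size class that short-read
indel callers and SNP arrays both miss, and that long-read sequencing of
multiplex families can recover. It is aimed at statistical geneticists
analysing small affected/unaffected family cohorts with multi-caller SV
call sets.

## The method

Given per-sample call sets from several SV callers (VCF with
`SVTYPE`/`SVLEN`/`END`), the pipeline:

1. **Merges calls into consensus SVs.** Two span-type calls (DEL/DUP/INV)
   describe the same event when their reciprocal overlap
   RO(a,b) = |a ∩ b| / max(|a|, |b|) ≥ 0.7; insertions match by anchor
   distance (≤ 500 bp) and inserted-length ratio (≥ 0.7). Per sample and
   type, calls are grouped by single-linkage over this predicate; groups
   supported by ≥ 2 distinct callers emit one consensus SV with median
   breakpoints.
2. **Builds the proband-exclusive set.** Consensus SVs from probands are
   kept only if ACMG class ≥ 4 (likely pathogenic) and no raw call from any
   unaffected relative matches them — one caller's evidence in a relative
   suffices to remove a candidate. Every removal is logged with its control
   evidence and the counters reconcile exactly.
3. **Annotates genes and features.** SVs are labelled with strand-aware
   transcription-order features (`intron5`, `exon30-intron30`) from BED12 or
   GFF3 gene models, and summarized (counts, length distribution, per-sample
   and per-type breakdowns).
4. **Tests pathway over-representation.** Upper-tail hypergeometric
   P(X ≥ k) per gene set, background size filter 30–1,000 applied before
   testing, Benjamini–Hochberg FDR < 0.05, and STRING-style strength
   log10((k/n)/(K/N)) > 0.5.
5. **Bi-clusters genes × pathways.** Average-linkage clustering over Jaccard
   distance on both axes of the binary membership matrix.
6. **Tests brain region–stage enrichment.** Hypergeometric enrichment of the
   candidate genes among highly expressed genes (quantile cutoffs 0.5–0.9)
   in 16 brain regions × 5 developmental stages against a brain-biased
   background (log2 FC > 0.5 in either of two reference datasets), with a
   competitive min-p permutation FWER = (1 + r) / (R + 1).

A synthetic-cohort generator (truth sets, caller error profiles, a
retrotransposon-driven bimodal length mixture with modes at ~300 bp and
~6 kb, expression matrices with plantable signal) makes every stage testable
offline, and a packaged fixture transcribes a published 88-SV
proband-exclusive result set for exact checks.

## Worked example

The packaged fixture report needs no inputs:

```r
library(famsv)
rep <- run_fixture_report()
rep$all
#> <sv_summary>
#>   SVs: 88   distinct genes: 79   genes with >=2 loci: 9
#>   length (bp): min 32, max 12345, mean 465, median 60
#>   per type:  DEL=59  INS=29
rep$confirmed
#> <sv_summary>
#>   SVs: 51   distinct genes: 47   genes with >=2 loci: 4
#>   length (bp): min 32, max 12345, mean 685, median 57
#>   per type:  DEL=51
```

88 likely-pathogenic SVs in 79 genes were private to the 10 probands; 51 of
them (all deletions, in 47 genes) were additionally confirmed by short-read
sequencing. Nine genes harbour SVs at two distinct loci.

An end-to-end run on a synthetic cohort:

```r
dir <- tempfile("cohort")
simulate_cohort_files(dir, seed = 1)           # VCFs, sample sheet, BED12, GMT, expression
cfg <- pipeline_config(
  sample_sheet = file.path(dir, "sample_sheet.tsv"),
  genes_bed    = file.path(dir, "genes.bed"),
  pathways_gmt = file.path(dir, "pathways.gmt"),
  expression   = file.path(dir, "expression.tsv"),
  fc_a         = file.path(dir, "brain_fc_a.tsv"),
  fc_b         = file.path(dir, "brain_fc_b.tsv"),
  outdir       = file.path(dir, "out"),
  permutations = 200, seed = 1)
res <- run_pipeline(cfg)
```

`outdir` then contains one TSV per stage (`proband_exclusive.tsv`,
`filter_audit.tsv`, `annotated.tsv`, `summary.tsv`, `enrichment.tsv`,
`brain_enrichment.tsv`, …) and a `manifest.json` with all parameters and
per-stage record counts; re-running the same config is bit-identical.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/famsv` (`simulate`, `report` and `all` subcommands).

## Vignette

`vignettes/family-sv-pipeline.Rmd` documents the models, parameter choices,
numerical conventions and known limitations in detail.
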