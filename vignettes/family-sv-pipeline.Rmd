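---
title: "Family-based discovery of medium-sized structural variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based discovery of medium-sized structural variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsv)
```

## The problem

Medium-sized structural variants (SVs, roughly 50–2,000 bp) fall into a
detection gap: too large for short-read indel calling, too small for SNP-array
CNV detection. Long-read sequencing of multiplex families closes that gap, but
individual SV callers disagree substantially, and a family design needs a
principled way to isolate variants private to affected probands. `famsv`
implements that workflow as composable, testable stages:

1. **Consensus calling** — merge one sample's calls from several callers;
   keep events supported by multiple tools.
2. **Family filtering** — subtract anything seen in unaffected relatives;
   keep only likely-pathogenic candidates (ACMG class ≥ 4).
3. **Annotation** — assign SVs to genes and intron/exon features; summarize.
4. **Pathway over-representation** — hypergeometric tests with
   Benjamini–Hochberg FDR and a STRING-style strength (log10 observed/expected).
5. **Bi-clustering** — group genes and enriched pathways by shared membership.
6. **Brain region–stage enrichment** — test whether candidate genes are
   over-represented among genes highly expressed in each of 16 brain regions ×
   5 developmental stages, with a permutation family-wise error rate.

A synthetic-cohort generator produces caller-level call sets, gene models,
pathway memberships and expression matrices with the statistical structure the
analysis assumes, so every stage — and the pipeline end to end — is testable
without any external download. The packaged fixture transcribes a published
88-SV proband-exclusive result set, used for exact summary-statistic checks.

## Consensus model

Two span-type calls (DEL/DUP/INV) describe the same event when their
**reciprocal overlap** — intersection length divided by the longer span — is at
least 0.7. Reciprocal overlap is undefined for point insertions, so two INS
calls match when their anchors lie within 500 bp and the shorter inserted
length is at least 0.7 of the longer; the ratio deliberately mirrors the
overlap rule, and the window is a free parameter (real insertion breakpoints
in repeats wobble by tens to hundreds of bp).

Per sample and per SV type, calls are grouped by **single-linkage connected
components** over the match predicate. Single linkage is order-independent and
matches common SV-merging practice; it can in principle chain distant calls,
but with a 0.7 overlap requirement a chain's ends still share most of their
span. A group becomes a consensus SV when it contains calls from at least
`min_support` distinct callers. "Found by multiple tools" is read as
`min_support = 2` of 4 — the weakest reading consistent with "multiple" —
and is configurable from 2 to 4.

Each caller contributes at most one call per group: the one whose start is
closest to the group's provisional median start, with ties broken toward the
smaller start and then the smaller length, so the result is invariant to input
order. Representative start and length are the medians over the contributed
calls, rounded half away from zero — robust to one outlying caller. The test
suite checks equivalence of the whole procedure against a brute-force
all-pairs/union-find oracle on a thousand random instances, plus order
invariance and monotonicity in `min_support`.

## Family filtering

The proband-exclusive set is built asymmetrically: case SVs must be *consensus*
calls, but a case SV is disqualified if it is seen in any unaffected relative
**by even a single caller**. Control calls are matched regardless of their own
pathogenicity class. This is conservative in the right direction — weak
evidence suffices to remove a candidate, strong evidence is required to keep
one.

Two design points deserve explanation:

* **Member-level matching.** A control call matches a case SV if it matches
  the representative interval *or any of its supporting member calls*. The
  representative breakpoint is a median whose error is shared across every
  control comparison; for an event whose size is comparable to the callers'
  breakpoint noise, one unlucky representative would otherwise escape all
  control evidence simultaneously. Raw member calls have independent errors.
* **Proximity rescue for small spans.** For span types the control match is
  reciprocal overlap ≥ 0.7 *or* breakpoint distance ≤ 500 bp with length
  ratio ≥ 0.7. Strict reciprocal overlap on a 32 bp deletion demands breakpoint
  agreement within ~10 bp, which no caller achieves on repetitive sequence; a
  relative's call of identical length 50 bp away plainly describes the same
  variant. The distance-plus-size predicate is the standard cross-sample match
  in SV-merging tools. Within-sample consensus keeps the pure
  reciprocal-overlap rule.

Every removal is recorded with the matching control evidence, and the
provenance counters reconcile exactly:
`consensus = class_filtered + control_matched + retained`.

The class filter consumes ACMG classes as input (annotation is an upstream
concern); the packaged VCF dialect carries them in an `ACMG_CLASS` INFO key.

## Coordinates

All coordinates are 1-based with explicit lengths, the Bioconductor
convention; a span SV of length L at start s occupies s … s+L−1 and an
insertion is a point anchor carrying an inserted length. Interval arithmetic
is delegated to IRanges/GenomicRanges, and VCF/BED conversions happen only at
the I/O boundary (BED block coordinates are 0-based half-open).

## Gene and feature annotation

Gene models come from BED12 or GFF3; when a gene has several transcripts the
longest (largest summed exon width) is used, since published per-SV labels
carry a single intron number. Features are numbered in transcription order —
on the minus strand the genomically last exon is exon 1 — matching the RefSeq
convention used by SV annotators. A span SV is labelled by the first and last
feature it touches in transcription order (`intron5`, `exon30-intron30`); an
insertion by the feature containing its anchor. Summary statistics report mean
and median lengths rounded half-up to whole base pairs, which is how the
fixture's published statistics (median 60 bp over 88 events with an even-count
median of 59.5) are reproduced.

## Pathway over-representation

For a query of n genes against a background universe of N genes, a term with K
background members and k query members gets the upper-tail hypergeometric
p-value P(X ≥ k). Terms with K outside [30, 1000] are excluded *before*
testing, so the BH correction spans only tested terms (the per-analysis FDR
convention of STRING-style tools; the ordering is a design choice the
reference workflow leaves unstated). A term is retained when FDR < 0.05 and
strength = log10((k/n)/(K/N)) > 0.5; at k = 0 the p-value is 1, strength is
undefined, and the term can never be retained. The default background is the
union of the supplied pathway universe; for genome-wide work pass the
organism's full gene complement.

Null calibration is checked by simulation: random 47-gene queries against
random 200-term GMTs leave essentially no terms below q = 0.05.

## Bi-clustering

The binary gene × pathway membership matrix is clustered independently on each
axis with average-linkage agglomeration over the Jaccard distance
(`stats::dist(method = "binary")`) — the standard choice for binary membership
data; the reference analysis names neither metric nor linkage. All-zero rows
and columns are pruned (the distance is undefined for them). Dendrograms are
cut into 9 pathway and 8 gene clusters by default, following the published
analysis of a 20-pathway result set; the published "suggested by the
dendrogram" choice of k is not algorithmic, so k is an explicit parameter.
Merges at exactly equal heights follow `hclust`'s deterministic order; a
permuted input can in principle resolve such ties differently, which is why
the permutation-invariance test uses planted block structure rather than
arbitrary tie-heavy matrices.

## Brain region–stage enrichment

The background universe is the set of *brain-biased* genes: log2 fold-change
(brain versus all other tissues) strictly greater than 0.5 in **either** of two
reference expression datasets. For each of the 16 × 5 region–stage cells and
each quantile cutoff q ∈ {0.5, 0.6, 0.7, 0.8, 0.9}, the "highly expressed"
set contains background genes whose expression in that cell strictly exceeds
the cell's q-th quantile over background genes (R's default inclusive
linear-interpolation quantile; the convention must be fixed for
reproducibility). Enrichment of the target list in each high set is the same
upper-tail hypergeometric test.

The permutation FWER is competitive and family-wide: R random gene sets of the
target size are drawn uniformly from the background; for each permutation the
minimum p over all 80 cells *at one quantile* is recorded, and a cell's FWER is
`(1 + #{permutation minima ≤ observed p}) / (R + 1)` — the add-one estimator,
whose floor 1/(R+1) avoids zero estimates. The family is defined per quantile
because results are reported with one FWER column per cutoff; whether the
reference implementation pools quantiles into one family is not documented,
and this choice is the one consistent with that report layout. Target genes
missing from the expression matrix or background are dropped with a warning,
mirroring real annotation gaps.

## The synthetic cohort

The generator emulates the study design the analysis assumes: 10 probands and
5 unaffected relatives, four long-read caller profiles (optionally four
noisier short-read profiles), and a three-component SV length mixture —
weights 0.55/0.35/0.10 over a small-event tail (shifted truncated geometric on
30–200 bp, median ≈ 60 bp) and two log10-normal modes at 2.5 (~300 bp,
Alu-like) and 3.8 (~6 kb, L1-like) with scale 0.08. These defaults reproduce
the characteristic bimodal log-length density of long-read call sets and a
small-event median near 60 bp. SV types default to DEL 0.45 / INS 0.45 /
DUP 0.06 / INV 0.04, reflecting the near-equal insertion/deletion balance of
retrotransposon-driven variation. Truth SVs are laid on a well-separated
genomic grid (≥ 5 kb apart) so distinct events can never merge; when gene
models are supplied, 60% of SVs are relocated into gene bodies (at most one
per gene), mimicking the predominantly intragenic composition of published
likely-pathogenic sets.

Each caller detects a carried SV independently with its sensitivity, perturbs
start and length with Gaussian noise, and adds Poisson spurious calls drawn
from the length model. *Case-specific* SVs (always class 4) are planted in one
proband each and never in relatives. *Shared* SVs carry each sample
independently with probability 1/2, forced to include at least one carrier and
at least one unaffected relative — in this generator "shared" means present on
both sides of the affection contrast, which is what makes the proband-exclusive
filter's false-positive behaviour testable. All randomness flows from explicit
seed arguments (`withr::with_seed`); nothing depends on global RNG state.

What the generator does **not** emulate: sequence context (no reads, no
repeats, so caller errors are independent across callers rather than
correlated at hard loci), pedigree transmission, linkage disequilibrium, and
genuinely caller-specific biases. Passing tests therefore demonstrate the
pipeline's logic and calibration, not performance on real data.

## Problem sizes used by the checks

The packaged checks run the consensus-versus-oracle comparison on 1,000 random
instances of up to 200 calls; hypergeometric enumeration over all universes
N ≤ 12; planted-SV recovery on the full 10+5 cohort with 30 planted and 200
shared SVs at sensitivity 0.95 and 20 bp jitter; pathway null calibration
over 500 replicates of 47-gene queries against 200-term GMTs on a
10,000-gene universe; and brain-enrichment calibration/power with a
2,000-gene universe at R = 200 (null) and R = 1000 (power) permutations.
These sizes were chosen to make Monte-Carlo conclusions stable while keeping a
full run in the minutes range on one core.

## Known limitations

* Breakpoints are not sequence-resolved; left-normalization of caller VCFs is
  not attempted (real callers differ here, and the consensus rule absorbs
  moderate disagreement).
* BND/translocation records are skipped; multi-allelic SV records and
  genotype/FORMAT fields beyond presence are out of scope.
* The pathway stage takes term memberships as given — no GO DAG propagation.
* Reproducing the specific published pathway lists and FWER values would
  require the exact external database snapshots (STRING 11.5, Brainspan,
  Descartes, GTEx); the property-based checks above stand in for them.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile("cohort")
bundle <- simulate_cohort_files(dir, seed = 1)
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
res$manifest$counts
```

The published-fixture report needs no inputs at all:

```{r fixture}
rep <- run_fixture_report()
rep$all
rep$confirmed
```
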