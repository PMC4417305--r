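---
title: "Methods: CpG-island methylation and substitution-rate turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-island methylation and substitution-rate turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgiturnover)
```

## The question and the analysis

CpG dinucleotides carrying a methylated cytosine deaminate to TpG (CpA on
the complementary strand) much faster than unmethylated ones. CpG islands
(CGIs) that are methylated in germline cells should therefore lose CpGs
over evolutionary time — yet many persist. The analysis implemented here
quantifies, per CGI, the forces in play: germline hypomethylation
(measured as sperm methylation state), deamination pressure (the
CpG→TpG/CpA substitution rate since the human–chimpanzee ancestor), CpG
selection (a depressed CpG→anything rate), CpG fixation (TpG/CpA→CpG), and
biased gene conversion (elevated A/T→G/C). The pipeline classifies CGIs by
their position in genes, attaches methylation levels from bisulfite call
counts, estimates six context-dependent substitution rates from three-way
alignments, learns the deamination-rate threshold separating sperm-HM from
sperm-LM CGIs with a decision stump, and emits grouped summary tables.

## Positional classification

Each CGI is tested, in priority order, for ≥ 1 bp of overlap with any
transcript's

1. **5′ window** — 3 kb upstream of the first exon through the end of the
   first exon ("first" in transcription orientation: the
   highest-coordinate exon on minus-strand transcripts);
2. **3′ window** — the final exon through 3 kb downstream;
3. **intragenic window** — the 3′ end of the first exon to the 5′ end of
   the final exon (first intron through final intron; in genomic
   coordinates the same interval for either strand);

falling through to **intergenic**. Coordinates are 0-based half-open
throughout (the convention of the UCSC tables this input format follows),
windows are clamped at position 0 and, when chromosome lengths are
supplied, at the chromosome end. A transcript is non-coding when
`cdsStart == cdsEnd`, the knownGene convention.

Three points were genuinely open and resolved as package design choices:

* *Does the 3′ window include the final exon body, or only the region
  strictly downstream?* It includes the body, mirroring the 5′ window
  definition, which explicitly includes the first exon.
* *Overlap* means at least one shared base; no minimum fraction.
* *Coding tie rule.* When several transcripts trigger the same (winning)
  category, the CGI is coding if **any** of them is protein-coding; the
  coding flag is taken from the triggering transcripts only, not from
  other transcripts that overlap via lower-priority windows.

## Methylation levels

Per CGI and sample, from per-site methylated/unmethylated call counts, in
percent:

* `pooled_strand_averaged` — level `100·S/(S+C)` pooled within each
  strand, then the unweighted mean of the two strand levels. A strand
  with zero calls is ignored rather than treated as 0%. This is the
  whole-genome bisulfite variant.
* `pooled` — one ratio over all calls (the RRBS variant).
* `site_mean` — unweighted mean of per-site ratios over sites with at
  least `min_reads_per_site` calls (4 for coverage-filtered RRBS-style
  exports, 0 otherwise; zero-call sites are always dropped since their
  ratio is undefined).

A CGI with fewer than **5 total calls** is excluded. The source
description of this filter ("fewer than five methylated or hypomethylated
cytosines") admits several readings — S+C < 5, S < 5 and C < 5, or
either < 5; this package reads it as *total calls* S+C < 5, applied once
per CGI per sample, which excludes exactly the CGIs whose level estimate
rests on fewer than five informative read-bases. Labels are inclusive at
both bounds: LM ⇔ level ≤ 20, HM ⇔ level ≥ 80; everything between is
`intermediate` and filtered CGIs are `excluded`. Sites belong to a CGI
when the cytosine position lies in `[start, end)`.

Hydroxymethylation uses the same pooled arithmetic on a separate 5hmC
call stream, and `has_hydroxymethylation()` flags CGIs with ≥ 1
hydroxymethylated call for optional removal (bisulfite chemistry cannot
separate 5mC from 5hmC, and 5hmC deaminates less readily, so keeping such
CGIs dilutes the methylation–deamination contrast).

## Substitution rates

Inputs are blocks of three gapped rows — human, chimpanzee, their
inferred common ancestor — anchored on human coordinates. MAF was chosen
as the container (the information content of ancestral-alignment EMF
dumps, with far wider tooling support); species labels are configurable.

Counting semantics, applied per alignment column whose human position
falls inside the CGI:

* An **ancestral dinucleotide** is two consecutive alignment columns in
  which the ancestor has two non-gap, non-N bases. A dinucleotide belongs
  to the CGI by its **first** base (the second may lie one base past the
  CGI end). Each lineage contributes at most one event per ancestral
  dinucleotide, and only when it is non-gap/non-N in both columns — an
  insertion between the two columns voids that lineage's event.
* Dinucleotide classes and targets: ancestral CpG → derived TpG/CpA
  (deamination) or GpG/ApG/CpC/CpT; ancestral TpG/CpA → derived CpG;
  ancestral GpG/ApG/CpC/CpT → derived CpG. Derived states outside the
  listed targets (e.g. CpG→TpA, double substitutions) count toward no
  numerator but stay in the denominator: the rates divide by ancestral
  counts only.
* Single-base classes: ancestral A/T with a derived G/C **in a non-CpG
  context of the derived sequence**; ancestral G/C **in a non-CpG context
  of the ancestral sequence** with a derived A/T. The asymmetry follows
  the two formulas' wording literally: the first conditions on the
  derived state ("derived G/Cs in a non-CpG context"), the second on the
  ancestral state. CpG context is evaluated on the ungapped sequence of
  the relevant species (nearest non-gap neighbour base); an unknown
  neighbour (block edge, N) counts as non-CpG, since a CpG cannot be
  confirmed. The A/T denominator does not exclude sites whose
  substitution would create a CpG — the printed denominator is all
  ancestral A/Ts.

Each rate is `events / (2 × opportunities)` (two lineages), `NA` when the
opportunity count is zero; `NA` rates are dropped from group means rather
than imputed as 0. CGIs whose human-anchored coverage (fraction of CGI
bases present as non-gap human columns in any block) is **strictly
below 50%** are excluded; exactly 50% is retained, because the removal
rule targets coverage *less than* half. Rates are computed on the forward
strand only — the CpA target class already encodes
complementary-strand deamination.

## The decision stump

The threshold separating sperm-HM from sperm-LM CGIs on the CpG→TpG/CpA
rate is learned by an exhaustive single Gini split: candidates are the
midpoints between consecutive distinct sorted rates; the candidate
minimising size-weighted Gini impurity wins; ties break toward the
smallest threshold. Leaves are reported as (≥ t) = left, (< t) = right.
The original analysis used a CART package with default parameters and
reported a single split; implementing the stump directly makes the split
criterion explicit and exhaustively optimal, which the test suite
verifies against both a brute-force search and an independent CART
implementation (rpart at depth 1). A `min_leaf` option (default 1)
supports parity experiments with minimum-leaf-size defaults of CART
packages. Degenerate inputs — a single class, or fewer than two distinct
rates — return a flagged fit with an undefined threshold rather than an
error. Published thresholds (0.03825 for the whole-genome analysis,
0.03984 for the RRBS replication) can be replayed as fixed configuration
constants in the pipeline; they arise from the full-scale data and are
not reproducible from desk-scale simulations.

## Summary tables

Counts of LM/HM per (category × coding) cell with totals; cross-sample
cross-tabs stratified on one sample's label with the other sample's LM/HM
counts (intermediate/excluded fall in neither column, so rows need not
sum to the stratum size); grouped mean ± SEM per substitution-rate type
(SEM = sample SD/√n with the n−1 denominator, undefined below n = 2); and
below-threshold partition reports per (category × coding × H1-label)
stratum. Emitted tables round fractions to 4 decimals; in-memory results
keep full precision.

## The synthetic-data generator

The generator emulates the statistical structure the estimators assume,
not human genome realism:

* **Sequence.** Chromosomes are built from two-base slots; a slot is a
  planted CpG with probability 0.12 inside islands and 0.01 outside
  (island CpG density at the scale of annotated CGIs against a depleted
  background; both from the study conditions this package is tested
  under), otherwise a non-CpG dinucleotide drawn from background base
  frequencies (A/T 0.3, G/C 0.2). Accidental cross-slot CpGs are patched
  away, so the planted slots are *exactly* the CpGs of the sequence and
  island CpG counts are exact binomials — which the density-recovery test
  exploits.
* **Layout.** Each CGI sits in its own 12-kb cassette with (for
  non-intergenic classes) one 3-exon transcript of either strand, placed
  so the planted class is the true class by construction and cassettes
  are too far apart for windows to interact. CGI lengths are drawn
  uniformly from 500–1500 bp (the scale of annotated human CGIs;
  intragenic placements cap at 1400 bp to fit between first and final
  introns). Seven (category × coding) combinations are populated;
  intergenic CGIs are non-coding by definition.
* **Methylation.** Each CGI is sperm-HM or sperm-LM (balanced by default,
  giving equal precision per group in two-group comparisons), with an
  H1 label drawn conditionally (P(H1-HM) = 0.7 given sperm-HM, 0.1 given
  sperm-LM, echoing the strong but imperfect germline/embryonic
  concordance). True levels are 0.9 (HM) and 0.05 (LM). Per CpG site and
  strand, coverage is Poisson (mean 30) and methylated calls binomial at
  the true level; zero-coverage sites are dropped as in real call tables.
* **Evolution.** Human and chimpanzee are mutated independently from the
  ancestor. Per-branch event probabilities are applied per region — each
  CGI uses its sperm-group's set, everything else the background set.
  Defaults plant the contrast the analysis is designed to detect:
  deamination 0.04 (sperm-HM) vs 0.005 (sperm-LM) per ancestral CpG per
  branch, CpG fixation 0.012 vs 0.008, and identical values across groups
  for the four remaining classes (0.004, 0.004, 0.003, 0.006), so that
  only the deamination and fixation panels should separate the groups.
  Background CpGs deaminate at 0.08, reflecting unprotected methylated
  CpGs outside islands.
* **Exact truth bookkeeping.** At most one event touches a base; a
  dinucleotide event locks both its bases; an event whose single-base
  write would make an *overlapping* classified ancestral dinucleotide
  display a target-class derived state is skipped, as is an A/T→G/C event
  that could only create a new derived CpG. These commit rules guarantee
  that the recorded truth counts equal an exact recount of the emitted
  gapless alignment by the column scanner — the recount-oracle test
  asserts equality, not approximation. The realised event fraction
  therefore sits slightly below the nominal probability in dense CpG
  contexts; recovery tests compare estimates to the recorded truth, and
  group means remain centred on the planted values (e.g. 0.040 vs 0.04 at
  200 islands per group).
* **Indels** (off by default) punch short deletions into the chimp and
  ancestor rows as a stressor for the gap rules; the human row stays
  ungapped because it anchors the coordinate system. Truth counts are not
  maintained under indels — they are a robustness stressor, not a
  recovery condition.

What the generator does **not** emulate: real CGI length and density
distributions, isochore/GC structure, selection, substitution-rate
heterogeneity along the genome, overlapping transcripts sharing windows,
lineage-specific insertion alignment ambiguity, and bisulfite conversion
failure. Passing recovery tests therefore demonstrates estimator
correctness under the stated generative model, not robustness to every
artefact of real WGBS or EPO alignments.

## Numerical choices and problem sizes

Determinism: every simulation entry point takes a seed; a fixed seed
yields byte-identical emitted files, and the pipeline writes a manifest
with seed and per-stage counts. Test problem sizes were chosen to give
stable statistics at interactive runtimes: classification oracles run on
≤ 10 kb toy genomes with ≤ 5 transcripts; the counting oracle compares
1,000 random ≤ 100 bp triples exactly; recovery runs use 200 islands per
methylation group, with threshold-location checks across 100 seeded
replicates; methylation recovery uses 30× coverage and 56 CGIs. The
fitted-threshold check asks that the stump threshold fall strictly
between the two planted branch probabilities (0.005, 0.04): per-island
rate distributions overlap at finite CpG counts (an island of ~60 CpGs
yields rate increments of ~0.008), so disjoint empirical supports cannot
be expected, but the optimal Gini split reliably lands between the group
centres.
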