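---
title: "Methods: race-stratified multi-omics comparison of tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-stratified multi-omics comparison of tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomics)
```

## The problem

Tumor-genomic resources are dominated by European-ancestry cohorts, so
population-specific molecular comparisons typically pit a very small study
cohort (here called cohort A, e.g. 17 samples) against a large public
comparator (cohort B, hundreds of samples), with the two cohorts profiled
on different platforms. stratomics implements the analysis layers such a
comparison needs — somatic mutation frequencies, copy-number variation,
gene expression, mutational signatures, and pathway-level integration —
together with a synthetic study generator that makes every analysis
testable against planted ground truth.

Three design constraints run through the whole package:

* **Severe cohort imbalance.** Every test must behave sensibly at 17 vs
  several hundred samples; exact tests (Fisher, hypergeometric) and
  rank-based tests (Mann-Whitney/Wilcoxon) are used throughout rather than
  asymptotic parametric models.
* **Platform heterogeneity.** The cohorts are harmonized by restricting
  DNA analyses to a shared gene panel and by a within-sample rank transform
  for expression, not by cross-platform normalization models.
* **Multiplicity.** Every per-gene/per-arm/per-pathway family is adjusted
  with the Benjamini-Hochberg step-up procedure.

## Statistical primitives

The primitives are implemented in the package itself (`fisher_exact_two_sided()`,
`bh_adjust()`, `mann_whitney_u()`, `hypergeom_upper_tail()`, `nnls()`,
`cosine_similarity()`), so each can be validated against an independent
oracle — exhaustive enumeration, brute-force tail summation, or the base-R
reference implementation — and so every convention is explicit:

* The two-sided Fisher p-value uses the *probability-mass* rule (sum of
  the probabilities of all tables, at the observed margins, no more
  probable than the observed one), with a relative tolerance of `1e-7` on
  the comparison to absorb floating-point noise. This matches the
  convention of the mainstream implementations used in this field.
* Odds ratios are unconditional cross-product ratios; a zero denominator
  yields `Inf` (or `NA` when both products vanish) rather than silent
  smoothing. Smoothing (+0.5 Haldane-Anscombe on all four cells) is
  applied only inside the bootstrap, and only to resampled tables that
  contain a zero cell, so point estimates on well-populated tables are
  untouched.
* The Mann-Whitney test defaults to an automatic mode: exact enumeration
  for tiny tie-free inputs (n ≤ 12 combined), otherwise the normal
  approximation with tie correction and continuity correction. At the
  cohort sizes this package targets, the normal branch is always the one
  used in production; the exact branch exists so tests can compare both
  against full enumeration.
* `nnls()` is a plain Lawson-Hanson active-set solver; the problems here
  are 96 rows by a handful of columns, where the active-set method is
  exact and fast.

## Mutation layer

Variants pass a three-stage cascade in the order population-AF filter
(drop `popmax_af > 5e-4`; the threshold is strict, so a variant at exactly
5e-4 is kept; variants with no AF annotation are kept, since absence of
annotation is not evidence of commonness), protein-altering filter
(missense, nonsense, frameshift and in-frame indels, splice site,
translation start site), and panel restriction. The three filters commute;
only the per-stage attrition counts depend on the order.

Retained variants collapse to a binary gene-by-sample indicator; each
panel gene is tested with Fisher's exact test on the 2x2 table of mutated
vs non-mutated by cohort, with BH adjustment at FDR 0.1. The BH family is
the set of panel genes with at least one mutated sample: all-zero genes
carry p = 1 by construction and only dilute the ranks (a `universe =
"all"` mode is available since the choice is a judgment call).

Discoveries are stress-tested by a within-cohort bootstrap
(`bootstrap_log_or()`, default 5000 resamples): samples are resampled with
replacement independently inside each cohort and the log odds ratio is
recomputed; directional consistency is the fraction of resamples whose
log-OR sign agrees with the point estimate. When the point estimate is
exactly zero there is no direction to agree with, and the positive-sign
fraction (≈ 0.5 under a null) is reported instead.

## CNV layer

The two cohorts may enter at different granularity — segment calls for one
and pre-called gene-level statuses for the other, mirroring a panel
platform vs an array platform — and both are normalized to a gene-by-sample
status table in `{gain, loss, neutral, invalid, missing}` before any test.
Segment-to-gene assignment intersects 0-based half-open intervals (one
overlapping base suffices). When a gene overlaps segments with both a gain
and a loss in one sample, its status is `invalid` and the sample is
excluded from that gene's denominator. The default mode invalidates only
gain+loss conflicts, so an alteration overlapping a neutral segment
resolves to the alteration; a `strict` mode invalidates any two distinct
overlapping states, because "conflicting" could defensibly be read either
way.

Frequencies are events over *valid* samples; Fisher + BH at 0.05 is run
separately for gains, losses, and the combined "change" (gain or loss)
event. For presentation, infinite/zero odds ratios are truncated at the
plot limits only — the tables keep exact counts.

Arm-level analysis assigns each gene to the chromosome arm containing its
midpoint (deterministic and order-free; genes spanning a centromere go to
the midpoint's arm). An arm is flagged in a sample when at least one panel
gene on it carries the event; arm burden is the per-sample count of
flagged arms, compared between cohorts with the Wilcoxon rank-sum test.
Arm frequencies get Fisher + BH at 0.05 within each event type.

## Expression layer

Genes whose mean normalized expression is below 10 in *both* cohorts are
removed (the retain-if-adequate-in-either reading; a pooled-mean mode is
provided). Each sample's surviving values are replaced by within-sample
average ranks. The point of the transform is the invariance property the
test suite asserts exactly: applying any strictly monotone,
sample-specific distortion to the input leaves every Mann-Whitney p-value
unchanged (to 1e-12), which is what makes the cross-platform comparison
defensible. The log2 fold change is *not* invariant — it is computed on
the original normalized values (with a pseudocount of 1 on both cohort
means, configurable) precisely because ranks are not scale-interpretable.
A gene is a DEG when BH-adjusted p < 0.01 and |log2FC| ≥ 2; cohort means
are arithmetic means of the normalized values.

## Mutational signatures

Single-base substitutions are classified into the 96 pyrimidine-centered
trinucleotide classes (purine-reference calls are reverse-complemented);
contexts come from a MAF context column or a reference FASTA, and the
middle context base must equal the reference allele. Catalogs pool both
cohorts, as panel catalogs are sparse and the factorization needs every
sample.

`extract_signatures()` is a compact implementation of the
resampling-stability scheme used by the established signature extractors:
for each candidate k it fits NMF with the Kullback-Leibler objective
(multiplicative updates, relative-change tolerance 1e-8 or 10,000
iterations; implemented in C++ since the updates dominate runtime) to
Poisson-resampled catalogs from independent random starts, pools the
replicate signatures, clusters them into k groups by cosine distance with
k-medoids (`cluster::pam`), and scores the candidate by mean silhouette
(stability; for k = 1, where the silhouette is undefined, the mean cosine
similarity of replicates to the medoid) and by the mean per-sample cosine
distance between the catalog and its reconstruction. Consensus signatures
are the cluster medoids; exposures are refit per sample by NNLS. The
selected k is the largest candidate with stability ≥ 0.8 (ties broken
toward lower reconstruction error); the KL/Poisson pairing reflects the
fact that catalogs are counts. No trinucleotide-frequency renormalization
between panel and genome background is applied — panel catalogs are used
as observed, and a renormalization hook would be the natural extension.

De novo signatures are decomposed onto a reference spectra matrix by NNLS;
coefficients are renormalized to percentage contributions and each
signature is named after its top contributor (with the best
single-reference cosine reported alongside). Exposures are compared
between cohorts per signature with the Mann-Whitney test on absolute
attributed counts (a proportion mode exists); raw p-values at 0.05 are
reported, as is conventional for a small fixed set of signatures.

## Enrichment and integration

Over-representation uses the hypergeometric upper tail with BH across the
pathways that intersect the universe. Universes are layer-specific: panel
genes for mutation and CNV layers, expression-filter survivors for DEG
layers — each layer is conditioned on what it could have measured. The
integrative matrix combines the per-layer results (typically seven layers:
differentially mutated genes, up-DEGs per cohort, CNV gains and losses per
cohort) into a pathway-by-layer grid of −log10(q); cells with zero overlap
are empty rather than zero, stars mark q < 0.05, and rows are ranked by
the number of significantly enriched layers, ties alphabetical.

## The synthetic study generator

`simulate_study()` writes a complete two-cohort study to disk — MAFs with
decoy variants violating each filter rule, segment-level CNV for cohort A
and gene-level CNV for cohort B (exercising both ingestion paths), a
distorted expression matrix, panel BED, cytoBand arms, a GMT with planted
pathways, true spectra, a context-consistent chromosome-1 FASTA — plus a
truth ledger recording every planted effect. Its defaults are the emulated
study conditions:

* cohorts of 17 vs 689 (tests and the acceptance script use 17 vs 60 to
  keep runtimes in minutes while preserving the imbalance);
* a 648-gene panel laid out on 22 small synthetic autosomes with p/q arms;
* 11 planted differentially mutated genes at per-sample rates 0.24 vs 0.02
  over a 0.02 background;
* broad arm gains concentrated in cohort B (per-arm probabilities 6.24/44
  vs 20.73/44, so the expected gain burdens are ~6 vs ~21 arms);
* focal losses concentrated in cohort A: 12 planted genes on distinct arms
  at 0.35 vs 0.05, over a diffuse per-gene loss background of 0.008 shared
  by both cohorts, which keeps cohort B's loss burden near 5 arms and
  cohort A's near 7-8 while leaving loss arms mostly non-significant —
  gains broad, losses focal and heterogeneous;
* asymmetric planted DEGs (40 up in A, 12 up in B, fold 8), log-normal
  gene means (meanlog log 100, sdlog 1), multiplicative log-normal noise
  (sdlog 0.5), and a cohort-specific monotone platform distortion
  (power/scale 1.0/1.0 vs 0.92/1.2);
* three signature spectra with pairwise cosine ≤ 0.6 and gamma-distributed
  (shape 2, non-negative and skewed) exposure means of (5, 5, 20) in A vs
  (20, 20, 20) in B. Two signatures are therefore shifted toward B and one
  is flat, which requires cohort B to carry the higher total burden —
  with equal totals, two mixture components cannot rise while the third
  stays flat in absolute counts — so cohort B draws 3-7 SNVs per mutated
  gene against 1-3 in cohort A.

`evaluate_recovery()` scores a pipeline run against the ledger
(sensitivity, observed FDR and direction correctness per layer, greedy
cosine matching of signatures, exposure-shift pattern agreement, planted
pathway ranks) against floors set from design-stage power calculations at
the 17-vs-60 scale: e.g. the focal-loss floor is one of twelve planted
genes, because the per-gene detection probability at that scale is ≈ 0.25
and the probability of recovering none is ≈ 3%.

### What the generator does and does not emulate

It reproduces the study's *structure* — cohort imbalance, mixed CNV
granularity, platform-distorted expression, signature mixtures, decoy
variants — with independent genes, independent samples, and clean
vocabularies. It does not model linkage between layers (mutations and
expression are independent), subclonality, purity, FFPE artifacts, or
germline contamination. Passing recovery tests therefore demonstrates that
the pipeline detects what it claims to detect under its stated model, not
that real data meet that model.

## Numerical and design choices

* All internal intervals are 0-based half-open; MAF point positions stay
  1-based as in the format. Chromosome names are stored without a `chr`
  prefix; mitochondrial and alt contigs are dropped with a counted
  message.
* The variant-classification mapping is a packaged text table, so new MAF
  dialects are configuration rather than code.
* `popmax_af` maximizes over all configured population-AF columns ("common
  in any subpopulation").
* Bootstrapping a binary indicator within a cohort is implemented as a
  binomial draw on the empirical rate — exactly the distribution of a
  column resample — which keeps 5000 resamples effectively free.
* Run manifests contain the config hash, seed, thresholds, and input
  digests; wall-clock timings go to a separate log so manifests are
  byte-identical across reruns.
* Test-scale choices: signature recovery runs at 120 samples × 150
  mutations with 20 replicates over k = 1..5 and lighter NMF convergence
  (1500 iterations, tolerance 1e-6) — sufficient for cosines ≥ 0.95 —
  while the function defaults keep k = 1..10 and the tighter 1e-8/10,000
  contract; the end-to-end study runs at 17 vs 60 with k ≤ 4 and 8
  replicates.

## Known limitations

* Panel-derived catalogs are sparse; signature extraction on such
  catalogs is exploratory, and the package deliberately does not assume
  row sums far above 96.
* Gene-level CNV tests are not independent when alterations are broad;
  that is exactly why the arm-level collapse and burden comparison exist,
  and conclusions should lean on the concordance of the two levels.
* The recovery floors quantify power under the generator's model only.
* At a 17-sample cohort, single-gene mutation tests have limited power by
  nature; a median sensitivity much above one half at FDR 0.1 is not
  achievable for a 0.24-vs-0.02 effect inside a 648-gene family, and the
  package reports this honestly rather than tuning around it.
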