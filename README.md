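# stratomics

Race-stratified multi-omics comparison of two tumor cohorts of very
unequal size — the situation that arises whenever a small,
underrepresented study cohort (say 17 tumors on a targeted panel) is
compared against a large public comparator (hundreds of TCGA-style
samples on different platforms). The package implements the full analysis
stack for that design and a synthetic two-cohort study generator with a
ground-truth ledger, so every layer is testable against planted effects.

## What it computes

For cohorts 1 and 2 with gene panel *G*:

* **Somatic mutations.** After a filtering cascade (population allele
  frequency `popmax_af > 5e-4` excluded, protein-altering consequences
  only, panel restriction), each gene *g* is tested with a two-sided
  Fisher's exact test on the 2×2 table (mutated vs not × cohort), using
  the probability-mass convention; p-values get Benjamini–Hochberg
  adjustment with discoveries at FDR < 0.1, and each discovery's log odds
  ratio is stress-tested by a within-cohort bootstrap (5000 resamples,
  directional consistency).
* **Copy number.** Segment calls (cohort 1) and pre-called gene-level
  statuses (cohort 2) are normalized to gene × sample statuses in
  {gain, loss, neutral, invalid, missing}; a gene overlapped by both a
  gain and a loss segment in one sample is *invalid* and leaves that
  sample's denominator. Fisher + BH at 0.05 per event type
  (gain/loss/change), aggregation to chromosome arms ("at least one panel
  gene on the arm"), and per-sample arm-burden comparison by Wilcoxon
  rank-sum.
* **Expression.** Genes with mean normalized expression < 10 in both
  cohorts are dropped; values are rank-transformed within each sample
  (average ranks for ties); per-gene Mann–Whitney U tests with BH; DEGs at
  adjusted p < 0.01 **and** |log₂FC| ≥ 2, the fold change computed on the
  original normalized scale. The rank transform makes every p-value
  exactly invariant to strictly monotone per-sample (platform)
  distortions.
* **Mutational signatures.** SBS96 catalogs (pyrimidine-centered
  trinucleotide classes); de novo extraction by KL-NMF over k = 1..10
  with Poisson resampling, replicate clustering by cosine k-medoids,
  silhouette stability and cosine reconstruction error for model
  selection; NNLS decomposition onto reference spectra with
  percent-contribution naming; per-signature exposure comparison by
  Mann–Whitney.
* **Enrichment.** Hypergeometric over-representation of any gene layer
  against any GMT collection, and an integrative pathway × layer matrix
  (−log₁₀ q, empty cells for zero overlap, rows ranked by number of
  significantly enriched layers, ties alphabetical).

## Worked example

Simulate a benchmark study (17 vs 60 samples, defaults documented in the
methods vignette), run every stage, and score recovery:

```r
library(stratomics)

sim <- simulate_study("demo", simulation_config(n_A = 17, n_B = 60, seed = 1))
res <- run_all(pipeline_config(sim$paths, k_max = 4, n_replicates = 8,
                               bootstrap_n = 1000, seed = 1))

head(res$mutation$tests[res$mutation$tests$significant, ], 5)
#> # A tibble: 2 × 8
#>   gene  n_mut_1 n_mut_2 freq_1 freq_2 odds_ratio         p      q
#> 1 G494        6       0  0.353 0           Inf   0.0000522 0.0265
#> 2 G277        7       2  0.412 0.0333       20.3 0.000223  0.0565
```

Two planted genes reach FDR < 0.1 at this scale: mutated in 35–41% of the
small cohort against 0–3% of the comparator (with 17 samples the power for
a 0.24-vs-0.02 effect is intrinsically modest; the other planted genes
rank high but miss the cutoff).

```r
res$cnv$burden
#> # A tibble: 2 × 4
#>   event mean_1 mean_2        p
#> 1 gain    6.29   20.4  3.30e-10
#> 2 loss    7.76    5.2  1.18e- 4
```

The planted asymmetry is recovered: broad gains give the large cohort ~20
gained arms per sample against ~6, while focal losses push the small
cohort's loss burden to ~7.8 against ~5.2.

```r
glance(res$mutsig$model)
#> # A tibble: 1 × 5
#>       k stability reconstruction_error n_samples total_exposure
#> 1     3     0.930                0.163        77          4109.

res$mutsig$exposure_tests
#> # A tibble: 3 × 6
#>   signature     median_1 median_2         p significant higher_cohort
#> 1 Signature96-A    20.5      15.9 0.576     FALSE       A
#> 2 Signature96-B     5.79     16.7 0.000395  TRUE        B
#> 3 Signature96-C     4.39     20.9 0.0000296 TRUE        B
```

Three signatures are selected at stability 0.93; the two planted
exposure-shifted signatures test significantly higher in cohort B and the
unshifted one does not — the planted pattern. `evaluate_recovery(sim$ledger,
res)` summarizes all layers against their floors (all pass at this seed:
DEG sensitivity 1.0, signature cosines 0.97, planted pathways ranked
first).

Each result type has an `autoplot()` (mutation/CNV volcanoes, signature
spectra, the integrative heatmap), and the signature model has
`tidy()`/`glance()` methods.

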