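---
title: "Methods: proteogenomic analysis of plasma-cell malignancies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic analysis of plasma-cell malignancies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelomics)
```

`myelomics` re-implements, as tested and reusable functions, the
computational procedures of a proteogenomic workflow for plasma-cell
disorders: TMT proteomics preprocessing, moderated differential
expression with cis/trans annotation, RNA–protein–copy-number
integration with a CNV buffering score, single-sample GSEA and NMF
subtype clustering, a bootstrap-stabilized prognostic protein score, and
therapeutic target nomination. This vignette explains each model, its
assumptions, the parameters that matter, and the design decisions taken
where the underlying procedure left room for interpretation. No number
quoted here is asserted beyond what the package's own tests and
acceptance script compute.

## TMT preprocessing

Quantification starts from log2 reporter intensities of protein groups.
Identification-quality filters remove decoy (reverse) hits, potential
contaminants, proteins only identified by a modification site, and
features with fewer than two peptides or without a unique/razor peptide
(`filter_protein_groups()`).

Each TMT plex carries one pooled internal-standard channel. Ratios are
formed by subtracting that channel from every member sample on the log2
scale (`tmt_ratio_normalize()`); a missing standard value makes the
ratio missing. Each sample is then median-centered and scaled by its
MAD. Two conventions had to be fixed:

* **MAD consistency constant.** We scale by 1.4826 × raw MAD so that the
  scale estimate is consistent with the SD under normality. Whether the
  original analysis used the constant is not determinable from its
  description; the constant only rescales all values of a sample jointly
  and does not affect ranks, correlations or t-statistics. The fixed
  point (per-sample median 0, scaled MAD 1) is asserted in the tests.
* **Direction.** "Median–MAD normalization" is read as center-then-scale
  per sample, the standard reading.

Features detected in **more than 49%** of cohort samples are retained
(`filter_min_valid()`); the boundary is strict, so 50 valid of 100
samples passes and 49 does not.

Missing label-free values are imputed from a downshifted normal
distribution (`impute_downshifted_normal()`): per sample with observed
mean m and SD s, draws from Normal(m − 1.8·s, (0.3·s)²). The imputation
is column-wise ("in the sample"), seeded, and never touches observed
entries. The defaults 1.8 and 0.3 are the method's published constants;
`scripts/acceptance.R` recomputes both from a 150,000-entry simulated
sample.

RNA TPM values are made comparable to TMT ratios by log2(TPM + 1)
transform (the pseudocount avoids log 0 at a negligible cost for
expressed genes), per-gene median centering, and per-sample median–MAD
scaling (`normalize_rna_tpm()`).

## Moderated differential expression

Subgroup-versus-rest comparisons use a two-sided moderated two-sample
t-test (`moderated_t_test()`). Per feature, the pooled two-sample
variance s² with df = n_A + n_B − 2 (valid counts per feature, so
matrices may retain missing values after the 49% filter) is shrunk
toward an empirical-Bayes prior:

* prior: s² ~ s₀²·F(df, d₀), fitted once per comparison by moment
  matching of log variances against digamma/trigamma moments
  (`fit_variance_prior()`); when the empirical spread of log s² does not
  exceed pure sampling noise, d₀ = ∞ and s₀² is the bias-corrected
  geometric mean;
* posterior variance: (d₀·s₀² + df·s²)/(d₀ + df);
* statistic: log2FC / sqrt(posterior·(1/n_A + 1/n_B)), referred to a t
  distribution with d₀ + df degrees of freedom (normal when d₀ = ∞).

We use the untrended prior (no mean–variance trend), the simplest model
consistent with the description; the prior fit is cross-checked against
an independent implementation in the test suite, and setting d₀ = 0
recovers the classical pooled t exactly. P-values are adjusted with
Benjamini–Hochberg over the tested features (`bh_adjust()`); untestable
features (fewer than two valid values in a group) are reported with
missing statistics rather than dropped, preserving the feature universe
for downstream joins.

Cis/trans annotation (`annotate_cis_trans()`) flags a feature as cis
when its cytogenetic band lies on the altered chromosome arm, and
reports the cis fraction among significant up- and downregulated sets.

## RNA–protein–copy-number integration

Feature matrices are collapsed to gene level by median
(`collapse_to_gene()`). Per-gene Pearson correlations between layers
require at least 10 complete pairs (`correlate_pairs()`). The CNV
buffering score per gene g is

> [cor(RNA_g, CN_g) − cor(protein_g, CN_g)] × |mean(CN_g) − 2|

with CN on the linear copy scale. All three quantities are computed on
**listwise-complete triples**: the two correlations are only comparable
by subtraction if they share one sample universe. (Pairwise deletion is
the plausible alternative; it would let each correlation see different
samples and can make the difference uninterpretable.)

Band-level copy-number calls (`bins_to_bands()`) assign each 1-Mb bin
(0-based half-open) to the band it overlaps most, round each bin with
`round_cn()`, and call the band as the most prevalent integer among at
least 3 valid bins. `round_cn()` implements the diploid-vicinity rule:
values within 0.35 of 2 are called 2; values between 1 and 3 beyond that
margin are called **away** from 2 (the threshold exists to call
subclonal gains/losses, so a 2.4 becomes a 3, not a 2); elsewhere plain
half-up rounding applies. Plain rounding is one flag away
(`plain = TRUE`). Ties between equally frequent band calls go to the
value nearer 2, then to the smaller value — conservative against false
aberration calls.

## Single-sample GSEA and NMF subtyping

`ssgsea_scores()` projects a gene-level matrix onto gene sets, one
sample at a time: values are replaced by ascending ranks scaled to
(0, 1], genes are ordered by decreasing normalized value, and a set's
raw enrichment is the area under the weighted running sum (weight
exponent 0.75 on the normalized values; out-of-set genes decrement by
1/(N − m)). The area telescopes to an O(m) expression per set, which
makes permutation nulls cheap. The normalized enrichment score is the
z-score of the raw area against `nperm = 1000` random same-size gene
sets. Because that null depends only on set size, it is computed once
per (sample, size) and shared — an exact identity, not an
approximation. Sets with fewer than `min_overlap = 10` genes present are
dropped. The reference implementation's internal scaling constants are
not published; our rank normalization and z-score NES are a documented
stand-in, and the tests pin the properties that matter (exact
invariance under monotone transforms, null mean ≈ 0 / SD ≈ 1,
directionality, overlap gating). `ssgsea_preranked()` applies the same
statistic to a single z-scored ranking vector (e.g. RNA–protein
correlations).

For subtype discovery, signed NES matrices are made nonnegative by
positive/negative row splitting (`split_signed()`), the standard
lossless encoding for signature matrices. `nmf_brunet()` implements the
KL-divergence multiplicative updates (divergence is non-increasing by
construction; the trace is recorded and asserted). `select_rank()` runs
`nrun = 50` restarts for each k in 2..7, forms the consensus
co-clustering matrix (cluster = dominant metagene per sample), and
scores stability by the cophenetic correlation between consensus
dissimilarities and their average-linkage dendrogram; the selected rank
maximizes the coefficient (ties to smaller k). `final_clusters()`
repeats the factorization with 500 random initializations at the chosen
rank and keeps the best-divergence run.

## The prognostic protein score

The risk-score construction (`cox_screen()` → `bootstrap_p_ci()` →
`select_candidates()` → `stepwise_aic()`) works on **fully quantified**
features only:

1. Per feature, a univariate continuous Cox model (Efron ties) for the
   endpoint, BH-adjusted across features.
2. 1,000 bootstrap cohorts of the same size, drawn with replacement;
   per replicate, each univariate p-value is recomputed. The "95%
   confidence interval of p-values" is the (2.5, 97.5) percentile
   interval of the bootstrap p-values — the standard bootstrap CI for a
   bounded statistic (a normal approximation could leave [0, 1]).
   Degenerate resamples (no events, constant feature) contribute p = 1,
   keeping the upper limit conservative.
3. Candidates: FDR < 0.1 **and** bootstrap upper CI < 0.1.
4. Forward stepwise Cox with AIC = −2·logPL + 2k, starting from the
   empty model and stopping when no addition lowers AIC. Forward-only,
   matching "step-wise addition"; ties break by screen p-value. The
   final model is restricted to proteins (the screen may include
   phosphopeptides when present in the matrix).

The fitted `risk_model` scores a sample as the coefficient-weighted sum
of its protein abundances (`risk_scores()`, also available as
`predict()`); model proteins missing from a matrix are omitted from the
sum, which is exactly how the score transfers to external cohorts that
lack a protein (`transfer_external()`, median-split grouping).
`stratify_quartiles()` uses k = round(n/4), so 100 patients split
25/50/25; `km_logrank()` and `multivariable_cox()` (score + R-ISS
indicator contrasts vs stage I) complete the evaluation.

## The synthetic cohort generator

`generate_cohort()` draws a cohort with the dependency structure the
pipeline assumes, plus ground truth for recovery tests. Defaults
emulate a newly-diagnosed myeloma cohort at desk scale: 120 MM samples
(plus small MGUS/PCL/healthy groups), subgroup frequencies near
reported NDMM incidences (t(11;14) 20%, t(4;14) 15%, t(14;16) 5%, HRD
45%; 1q gain in ~40% with 25%/15% one/two extra copies; 13q deletion
40%), and 2,000 proteins with 600 phosphopeptides.

The generative chain is deliberately minimal:

* **Copy number**: fixed band archetypes (HRD = trisomies of odd
  chromosomes; 1q gain; 13q/17p/1p deletions) on a simplified band map,
  each altered band retained per sample with probability 0.9
  (Bernoulli subclonal deviation) — testable cis/trans structure
  without genome simulation.
* **RNA** = 0.5 log2 units per copy (cis dosage) + subgroup trans
  effects (50 genes per translocation subgroup, effects N(0, 0.8); the
  magnitudes are free parameters — no published effect sizes exist for
  them) + N(0, 0.5) noise.
* **Protein** = 0.5 × RNA + N(0, 0.82). These three constants are the
  calibration anchor: for a diploid gene the implied RNA–protein
  Pearson correlation is a·σ_RNA/√(a²σ_RNA² + σ_prot²) = 0.29, the
  median reported for patient cohorts. The acceptance suite verifies
  the realized median across three seeds.
* **Phosphopeptides** inherit the parent protein value plus N(0, 0.5)
  site noise.
* **Missingness** is MNAR: the missingness probability is logistic in
  abundance (slope 1.5), with the threshold solved so the overall
  detection rate hits `frac_detected` (default 0.8). This mirrors the
  left-censored missingness that motivates downshifted-normal
  imputation, rather than MCAR.
* **Survival** is exponential with log-hazard Σ coefficients × centered
  true protein values of three planted prognostic proteins (0.8, −0.8,
  0.6), with independent exponential censoring calibrated to a 30%
  censoring fraction under the null and a baseline median of 30 months.
  Exponential + independent censoring is the simplest model satisfying
  proportional hazards, so Cox recovery is well-posed. Planted proteins
  are kept fully quantified so they remain screen-eligible.

What the generator does **not** emulate: batch/plex effects, peptide-
level rollup noise, correlated missingness between layers, subclonal
copy-number heterogeneity beyond the Bernoulli retention, non-
proportional hazards, and informative censoring. Passing recovery tests
therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to those violations.

## Problem sizes used in the tests

The test and acceptance suites run the procedures at reduced but
faithful scales, chosen as the smallest sizes at which the asserted
properties are stable: imputation moments at 150,000 entries; null
t-test calibration at 2,000 features; prior recovery at 20,000
variances; ssGSEA null calibration at 5,000 genes × 1,000 random sets
with 1,000 permutations; NMF consensus at 30 restarts per rank on
60 × 24 matrices; and the risk pipeline at 20 replicate cohorts of
n = 150 with 20 fully quantified proteins and B = 200 bootstrap
resamples (B = 1000 remains the analysis default).

## Known limitations

* The ssGSEA NES is z-scored against a gene-permutation null; absolute
  NES values are not interchangeable with implementations that use
  different internal scalings, though rankings and signs are.
* The variance prior is untrended; strongly intensity-dependent
  variance would call for a trended prior.
* `bins_to_bands()` assigns each bin to a single best-overlap band;
  bins straddling band boundaries contribute only to the larger side.
* The forward-only stepwise search can retain a protein that a
  backward step would remove; with the bootstrap-gated candidate list
  this is rare but not impossible.
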