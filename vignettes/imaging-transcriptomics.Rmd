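---
title: "Methods: imaging transcriptomics of sex-specific rsFC alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging transcriptomics of sex-specific rsFC alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions they rest on, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script does
not itself compute.

## 1. The scientific problem

Case-control resting-state fMRI studies of depression report connectivity
abnormalities whose anatomy differs between men and women. One way to ask
*why* is imaging transcriptomics: regress the spatial pattern of
depression-related connectivity change, seeded from a region of interest, on
the spatial patterns of regional gene expression measured in donor brains.
Genes whose normative expression topography tracks the connectivity-change
topography are candidates for mechanistic follow-up, which this pipeline
pursues three ways: gene-set enrichment of the resulting ranking, convergent
selection against postmortem differential expression and eQTL evidence, and
an additive risk-allele score tested against connectivity in genotyped
subjects.

All of the study-scale data such an analysis needs (patient fMRI, donor
microarrays, genotypes) are restricted or bulky, so this package treats the
*procedures* as the deliverable and ships a synthetic world rich enough to
exercise every stage with known ground truth.

## 2. Expression mapping

Donor microarray samples are mapped to a parcellation by the following fixed
rules, each implemented as a separate tested operation:

* probes of the same gene are averaged, unweighted (`collapse_probes`);
* a sample joins the parcel whose representative volume locus lies within
  2 mm (Euclidean, millimeter frame); nearest wins, exact ties go to the
  lexicographically smaller parcel id (`assign_samples_to_parcels`).
  The 2 mm radius mirrors common practice for assigning microarray sample
  sites to imaging space;
* per parcel, assigned samples are averaged; per gene, the donor's covered
  parcels are Z-scored, removing donor-specific affine distortions of scale
  and offset (`build_donor_matrix`);
* hemispheres are mirrored through the homolog map: one-sided coverage is
  copied, two-sided coverage is averaged into both sides
  (`mirror_hemispheres`, idempotent by construction);
* donors are averaged over covering donors only, and each gene column is
  Z-scored a second time over the union coverage (`aggregate_donors`).
  Uncovered parcels are excluded, never imputed.

**Order of operations.** The source procedure Z-scores per donor, mirrors,
averages, and Z-scores again, but does not pin down the relative order of the
first Z and the mirroring. This package fixes build → Z → mirror → aggregate
→ Z. Rationale: Z-scoring before mirroring means the mirror copies values
that are already free of donor scale, so a donor with one covered hemisphere
contributes on the same scale as one with two.

Zero-variance gene columns cannot be Z-scored; they are set to zero, flagged
(`flat_genes`), and excluded from PLS.

## 3. Connectivity statistics

rsFC features are Fisher-z transformed correlations (`atanh(r)`, with |r|
clipped at 1 − 1e−12). Site effects are removed by parametric empirical-Bayes
location/scale harmonization (ComBat): per feature, batch means and variances
of standardized residuals are shrunk toward cross-feature priors (normal for
means, moment-matched inverse-gamma for variances, the standard fixed-point
iteration), and the data are adjusted by subtracting the additive and
dividing by the multiplicative parameter. Sex, diagnosis and age sit in the
standardization design, so covariate-associated signal is preserved. No
external ComBat implementation is available in the build environment; the
algorithm is implemented in-package and validated by parameter recovery
(site shift removed, planted diagnosis effect retained).

Group contrasts use a 2×2 factorial ANOVA per feature with Type II sums of
squares — each main effect adjusted for the other, the interaction adjusted
for both, error from the full model — which coincides with the textbook
balanced decomposition whenever cells are balanced. Post-hoc sex-stratified
contrasts are pooled-variance two-sample t-tests (the classic post-hoc
choice; Welch is available as a switch since the source is silent). The sign
convention — positive t means increased connectivity in patients — is
enforced by test. Multiplicity is controlled by Benjamini–Hochberg FDR;
shared/sex-specific classification uses unadjusted p < 0.05 by design, and
the count of sex-specific effects is calibrated against sex-label
permutations (one-sided p with the +1 correction, 1000 permutations by
default).

The PLS response for a seed region is built by averaging the subject-level
Fisher-z values over the seed's features per target parcel *before* the
t-test, so each target parcel contributes exactly one response value.

## 4. PLS, bootstrap ranking

NIPALS PLS1 with deflation; for a single response the first-component weight
vector has the closed form `u ∝ Xᵀy`, which the implementation must match to
1e−10 (acceptance criterion). K defaults to 2 but every reported statistic
uses component 1. Component 1 is sign-aligned so that ρ = Corr(Xu, y) ≥ 0;
bootstrap replicates are sign-aligned to the empirical weight vector by the
sign of their dot product, without which bootstrap SDs are inflated by
arbitrary sign flips. Y is centered but not variance-scaled (the reported
statistic is a correlation, which is scale-free).

A regime note: the noiseless identity "y = Xw implies ρ₁ = 1" holds only as
G/P → ∞ (then XXᵀ ≈ G·I and the single component suffices); at desk scale
with G comparable to P, ρ₁ < 1 even without noise. Study-scale dimensions
(hundreds of parcels, tens of thousands of genes) are squarely in the
large-G regime.

Bootstrap: rows of X and Y are resampled jointly with replacement (10,000
replicates by default), the first component refit per replicate — implemented
as one matrix product per chunk using multinomial count weights, which is
algebraically identical to refitting on the resampled rows — and genes are
ranked by Z = empirical weight / bootstrap SD, descending. Replicates with
zero-variance resampled Y are redrawn and counted; genes with zero bootstrap
SD are excluded from the ranking with a non-finite Z. Both tails matter:
positive-tail genes track the response topography, negative-tail genes track
its inverse, and downstream consumers (enrichment, convergence selection)
treat the tails separately.

## 5. Null models

**Spin test.** The null for ρ must respect spatial autocorrelation: smooth
maps correlate with smooth maps by construction, so naive permutation nulls
are anti-conservative. The spin family handles this by rotating one map over
the (hemi)sphere and re-assigning parcels, preserving the map's correlation
structure while destroying its alignment with the predictor.

The synthetic parcellation places each hemisphere's centroids quasi-uniformly
on *half* of one unit sphere (Fibonacci lattice, seeded jitter, exact
x-mirror homologs). On that geometry a rotation drawn uniformly from all of
SO(3) — the natural choice on a full sphere — ejects the large majority of
centroids from their hemisphere; the bijective re-assignment then behaves
much like a random shuffle and the null loses exactly the property it exists
to preserve. Projecting the half-sphere onto a full sphere does not help:
any such projection must collapse the hemisphere rim to a point, which
scrambles rim neighborhoods. The package therefore draws the rotation from
the *isometry group of the hemisphere itself*: a uniform rotation about the
pole axis composed with a coin-flip reflection. These motions map the
half-sphere exactly onto itself, preserve all pairwise distances (hence the
map's autocorrelation, up to lattice discretization), and — because the
synthetic fields are isotropic — make the null exactly exchangeable. The
right hemisphere receives the x-mirrored motion. Re-assignment is greedy
nearest-neighbour without replacement, worst-off first, so every draw is a
true permutation and the value multiset is conserved exactly.

Loading weights are refit on every permuted response (`ρ_k = Corr(X u_k,
Y_k)` with `u_k` from the permuted fit), following the quoted convention; a
fixed-weights variant is exposed as an option. Parcels without expression
coverage take part in the rotation and are dropped afterwards, pairwise per
permutation. p-values are one-sided with the +1 correction; the spatially
naive `random_test` differs only in drawing uniform permutations, and the
two nulls agree in distribution on spatially white data (tested).

A caution documented for users: at coarse parcel resolution the spin
statistic is sensitive to the discretization of the re-assignment, because
the observed arrangement is the only one that is perfectly lattice-aligned.
Calibration is therefore verified on maps that carry a realistic sampling-
noise component on top of the smooth field (which is what t-maps and
microarray aggregates are); perfectly noise-free ultra-smooth maps at very
small P can push the test anti-conservative, a regime real data do not
occupy.

**Cross-validation.** Reproducibility uses ten-times ten-fold
diagnosis-stratified CV within the sex stratum. Per fold, the seed effect
map is recomputed from training subjects, the first component fit, and
`ρ_ho = Corr(X u_train, Y_test)` evaluated against the effect map recomputed
from the held-out subjects. A matched null arm permutes diagnosis labels
within the stratum (per fold evaluation) and repeats everything. Per repeat,
the fold differences feed the Nadeau–Bengio corrected resampled t-test,
whose variance multiplier `1/k + n_test/n_train` accounts for overlapping
training sets (the naive paired t is anti-conservative and the corrected t
is strictly smaller in magnitude — tested). The 10 per-repeat p-values are
Bonferroni-corrected and the omnibus rule rejects when any adjusted p falls
below 0.05. Fold partitions (and the null label permutation) are redrawn if
any test fold would hold fewer than two subjects of either group in either
arm.

## 6. Enrichment

Preranked GSEA on the bootstrap-Z ranking: weighted Kolmogorov–Smirnov
running sum over the descending list, hit increments ∝ |z|^exponent
(exponent 1 by default), uniform miss decrements, ES = signed extremum.
The null follows the preranked convention of the cited tooling — random
same-size gene draws, not phenotype permutation — with NES = ES normalized
by the mean |null ES| of matching sign, matching-sign tail p with the +1
rule, and BH across sets. Negative NES denotes enrichment among
negative-loading genes and is reported as such. Set-size eligibility
defaults to 15–500. The simple permutation estimator is implemented and
labeled as such; no multilevel refinement. The decile analysis counts set
members per rank decile (ties broken by gene id) against a simulated
2.5/97.5 percentile band from uniform random sets.

## 7. Genotype validation

QC excludes SNPs with missingness > 10%, minor allele frequency < 5%, or
Hardy–Weinberg deviation (1-df chi-square, α = 0.05). The MAF clause in the
source text reads inverted ("excluded if … minor allele frequency > 5%");
the conventional reading is implemented, the literal one kept behind
`literal_maf_rule`. Convergent genes must sit in the extreme loading-weight
decile with the tail sign, postmortem DEX direction and eQTL direction all
in agreement. Risk-allele scores are integer allele sums, complete-case by
default (mean imputation optional). The score→connectivity association is
ordinary least squares with age as covariate, fit separately per sex (the
source implies separate fits), with no multiplicity correction across the
two hypothesis-driven score tests, following the source's explicit choice.

## 8. Power and classifier simulations

The sex-composition bootstrap subsamples 140 patients and 70 controls
without replacement at each of the seven canonical fractions female (0, 20,
33, 50, 67, 80, 100%), applied to both groups, and records per-iteration
t-statistics of the subject-level mean over the within-network feature block
plus per-feature FDR rejections. The elastic-net classifiers use α = 0.5
(equal ridge and lasso), a log-spaced 80-point λ grid spanning four decades
below λ_max (the grid is the package's choice; the source states only the
count), 145 training and 72 strictly held-out test subjects per iteration,
100 iterations, with AUC traced along the path and indexed by both λ and the
active-feature count. ROI weight maps average coefficients over iterations
*first* and sum absolute values per ROI *second*, following the stated
order. Classifier comparisons across strata use identical train/test sizes
so AUC differences are attributable to composition, not sample size.
`glmnet` provides the penalized fits; everything around it (draws, AUC,
aggregation) is package code under test.

## 9. The synthetic world

The generator's defaults state the world the tests live in:

* geometry: Fibonacci half-sphere lattices, seeded tangential jitter (25% of
  lattice spacing), volume loci at 70 mm radius — reproducible quasi-uniform
  coverage with exact mirror homologs;
* expression: per-gene Gaussian-process fields with covariance
  `exp(−d/smoothness)` over great-circle distance, Cholesky-sampled at
  parcel resolution; smoothness defaults to 0.5 rad — the empirical spatial
  smoothness of donor atlases is not stated anywhere authoritative, so this
  is a free parameter, exposed in config, chosen once so that maps are
  smooth at parcel scale without being rank-deficient. Donors add per-gene
  affine distortions (log-normal scale, normal shift), sample/probe noise
  (SD 0.2 each), ≤ 2 probes per gene, and 2 mm-compatible coordinate jitter
  (SD 0.5 mm); a configurable donor fraction (default 2/6, deterministic
  count) lacks right-hemisphere samples;
* rsFC: features generated directly at Fisher-z scale from the factorial
  model `baseline + site + β_sex·sex + β_mdd·mdd + β_int·sex·mdd + ε` with
  sex and diagnosis coded 0/1 and the interaction as their product; an AR(1)
  time-series route exists solely to exercise `compute_rsfc`;
* planted associations: sparse gene weights, `Y = s·Xw + e` with the
  variance ratio fixed exactly at the requested SNR;
* genotypes: Hardy–Weinberg draws (heterozygote depletion when a violation
  is flagged), configurable missingness, and additive causal wiring into a
  named rsFC feature of one sex.

What a green test does and does not establish: the generators produce
exactly the statistical structure the analysis assumes — linear effects,
Gaussian noise, isotropic smooth fields, exact HWE. Real data violate all of
these (non-Gaussian motion artifacts, anisotropic cortical smoothness,
population stratification, probe chemistry). Green tests establish that the
procedures are implemented correctly and recover what they are designed to
recover; they say nothing about robustness to those violations.

## 10. Numerical choices and degenerate inputs

* NIPALS stops at weight change < 1e−10 or 500 iterations (PLS1 converges in
  one step; the safeguard matters only for deflation stages).
* Permutation p-values always use the +1 correction and can never be 0; the
  smallest attainable p is 1/(n_perm + 1).
* |r| = 1 is clipped to 1 − 1e−12 before `atanh`; constant time series give
  missing features with a warning.
* Zero-variance bootstrap responses are redrawn (counted); zero-SD genes are
  flagged out of Z-scoring and ranking.
* The corrected resampled t-test returns t = 0, p = 1 for all-zero
  differences and a signed infinity sentinel (with warning) for zero
  variance with nonzero mean.
* Sample-assignment ties break to the lexicographically smaller parcel id;
  GSEA decile ties break by gene id — determinism everywhere.
* Every stochastic routine takes an explicit seed; the pipeline derives
  independent per-stage substreams from one master seed, and reruns with the
  same config and seed are byte-identical in all numeric artifacts.

## 11. Known limitations

* The spin null is an interpretation: bijective greedy reassignment under
  hemisphere isometries. Tools in the wild differ (non-bijective nearest
  centroid, full-sphere per-hemisphere projections); the bijective contract
  conserves the value multiset exactly but is one member of that family, and
  at coarse resolution its discretization is visible (Section 5).
* Voxel-level volumetric processing is intentionally collapsed to
  sample→parcel assignment; probe re-annotation and differential-stability
  filtering are out of scope.
* The GSEA estimator is the simple permutation one; very small p-values are
  resolution-limited by n_perm.
* BOLD physics, head motion and scanner physics are not simulated; the
  time-series route exists only to exercise the correlation stage.
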