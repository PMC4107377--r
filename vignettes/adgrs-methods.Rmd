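---
title: "Methods: probability-scale genetic risk scores and race-stratified panel models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probability-scale genetic risk scores and race-stratified panel models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgrs)
library(dplyr)
```

This vignette is the package's own account of its statistical machinery: the
score construction, the panel models and their inference, the synthetic
cohort that makes the pipeline testable without restricted data, and the
numerical and design choices that were genuinely open.

## 1. The probability-scale risk score

The score family combines dosages of pre-specified risk alleles with
externally estimated per-allele log odds ratios. With dosages
$g_{ij} \in \{0,1,2\}$ and weights $\beta_j$,

$$ s_i = \sum_j g_{ij}\,\beta_j, \qquad
   \mathrm{odds}_i = \pi\, e^{s_i}, \qquad
   \mathrm{GRS}_i = \frac{\mathrm{odds}_i}{1 + \mathrm{odds}_i}, $$

where $\pi$ is an assumed population prevalence (default 0.1, the
conventional dementia figure for a 65+ panel; it is configuration, so the
family is reusable for other diseases). The anchor makes the score
directly interpretable as a probability: someone with no risk alleles sits
at $\pi/(1+\pi) \approx 0.0909$, and every risk allele moves the person
along the logistic curve by its log odds ratio. The transform is computed as
`plogis(log(prevalence) + s)`, which is monotone, exactly invertible over
the realistic range of allele sums ($|s| \lesssim 15$ recovers $s$ to
1e-9), and saturates gracefully in double precision far outside it.

Three score identities are enforced by tests rather than assumed: the full
weighted sum decomposes exactly into the APOE and non-APOE partial sums; a
locus with $\beta = 0$ never changes the score; and a zero-dosage genome
scores exactly $\pi/(1+\pi)$.

**Weights are an input, not an estimate.** The bundled table
(`inst/extdata/alzgene_weights_synthetic.tsv`) covers the ten loci
conventionally used for an Alzheimer's score — APOE via rs429358/rs7412 plus
nine GWAS loci — with odds ratios *representative of* meta-analysis values
circa 2013. It is a synthetic stand-in (the meta-analysed values themselves
are not redistributed) and is meant to be replaced via
`read_weight_table()` for substantive work.

**Missing dosages.** Mean imputation over non-missing persons at the locus
is the default, matching the common polygenic-score convention and keeping
panels balanced; a strict mode drops the person instead. A person with no
observed locus is always indeterminate.

**Genotype harmonization.** VCF input is matched to the weight table's
effect allele against REF, ALT and their reverse complements, so strand
flips are recovered; dosages are counted on whichever written allele
corresponds to the effect allele. Palindromic (A/T, C/G) sites cannot be
strand-resolved from a single file and are excluded with a warning by
default — the conservative convention — with `force_palindromic = TRUE` to
accept them on the written strand. The per-locus decision trail is attached
to the genotype table as a `harmonization` attribute.

**APOE $\varepsilon 4$.** Carrier status is counted from the rs429358 risk
allele alone by default, which is sufficient for "at least one
$\varepsilon 4$ allele" analyses. A strict haplotype mode flags the one
unphased configuration that is genuinely ambiguous — the rs429358/rs7412
double heterozygote, compatible with both $\varepsilon 2/\varepsilon 4$ and
$\varepsilon 1/\varepsilon 3$ — as indeterminate.

**Quintiles** are rank-based with ties sharing the lower bin: deterministic,
balanced to within one person apart from ties, and undefined (an error) for
all-equal input.

## 2. Panel models and cluster-robust inference

Outcomes are person-wave records over up to three biennial waves. The
dementia outcome is a continuous probability score in $[0,1]$, defined only
at ages 65+ (the underlying cognitive instrument is not administered
earlier); the memory outcome is a composite score standardized by the
first-wave standard deviation.

`fit_pooled_logistic()` stacks the person-waves and fits a logistic model by
quasi-binomial IRLS (`stats::glm`), which accepts fractional outcomes; with
a binary outcome it is ordinary logistic regression. `fit_linear_clustered()`
is OLS. Whether the original analyses treated the probability score as
fractional or dichotomized it is not stated in the source material; both
modes are provided and the binary mode is the test bed for parameter
recovery, since its estimand is cleanly identified.

Every model adjusts for age (linear, centered at 70 for conditioning of the
design matrix — a pure reparameterization, verified by test), sex, and
assessment year. A covariate that is constant within an analysis frame (one
wave; a sex stratum) is dropped as vacuous rather than raising an error;
genuine collinearity among varying columns errors with the aliased column
names.

Inference uses the CR0 cluster-robust sandwich over persons,

$$ \widehat{V} = \Big(X^\top W X\Big)^{-1}
   \Big( \textstyle\sum_g S_g S_g^\top \Big)
   \Big(X^\top W X\Big)^{-1}, \qquad
   S_g = \sum_{i \in g} x_i (y_i - \hat\mu_i), $$

evaluated at the converged coefficients. CR0 (no small-sample correction) is
the default because the cluster counts in the intended analyses are in the
thousands; CR1 scaling is available. With singleton clusters the estimator
collapses to HC0 exactly. Wald intervals use the normal reference
distribution. Tests pin the implementation to an independently coded
brute-force version of the same formula at 1e-10 and cross-check against
`sandwich::vcovCL`.

Effects are reported per 0.1 score units ($e^{0.1\hat\beta}$ for dementia,
$0.1\hat\beta$ SD for memory). `run_model_battery()` lays the cells out as a
race-comparative analysis: pooled, NHW-stratified, NHB-stratified, and
race-interaction columns per outcome and score variant, with optional
age-band (a survival-bias probe: a genetic effect confined to 65+ with
stable allele frequencies across age bands argues against strong selective
mortality), gender, APOE-carrier and single-SNP blocks. Cells that cannot
be estimated are flagged, not fatal.

## 3. Relative versus additive effects

Odds ratios are non-collapsible: groups with different baseline risks can
show different odds ratios yet nearly identical probability changes.
`shift_probability(baseline, or, delta, scale)` moves a baseline probability
along the odds scale by $\mathrm{OR}^{\delta/\text{scale}}$;
`risk_difference()` is the same computation expressed in percentage points.
A printed-number mode exists precisely so published worked examples can be
reproduced without the underlying data; `predict_from_fit()` is the
model-based analogue, and the two code paths agree to 1e-6 by test. Shifting
is an odds-scale group action (composition in $\delta$ is exact), which the
tests verify to 1e-12.

With the published inputs — baselines 1.10% (NHW) and 3.30% (NHB), odds
ratios 2.22 and 1.33 per 0.1 units, a one-SD shift of +0.037 — the shifted
probabilities are 1.47% and 3.65%: both races gain roughly 0.4 percentage
points per SD of genetic risk despite a 1.7-fold difference in odds ratios.

## 4. The synthetic cohort

`simulate_study()` emulates the structure the analysis assumes, with
defaults set to the published characteristics of the dementia-analysis
sample of a national aging cohort: 7,690 persons of whom 1,015 (13.2%) are
NHB; first-wave ages truncated-normal 74.0 (SD 7.08) for NHW and 71.6
(SD 6.62) for NHB on [50, 95]; 43.3% / 37.7% male; waves 2006/2008/2010 with
ages advancing two years per wave.

**Genotypes** are Hardy–Weinberg: dosage $\sim$ Binomial(2, $f_{rj}$) with
race-specific frequencies and linkage equilibrium between loci (sufficient
for testing every downstream operation; real LD structure is deliberately
not modeled).

**Calibration.** Race-specific frequencies are found so the population mean
probability-scale score hits 0.092 (NHW) and 0.122 (NHB). The expected mean
is computed exactly by enumerating the weighted-sum distribution ($3^L$
genotype classes, capped at 13 loci), and a one-dimensional root search
moves a shared logit-scale shift of the base frequencies. The shift is
*signed* by each locus's effect direction, which makes the expected mean
strictly monotone in the shift — an unsigned shift is not monotone when
weights have mixed signs. Base frequencies in the bundled table are
literature-typical values (e.g. APOE $\varepsilon 4$ near 0.285 / 0.415 in
the two groups) and act as starting points; with the bundled synthetic APOE
weight the calibrated $\varepsilon 4$ frequencies land lower (near 0.14 /
0.23), because holding them fixed would put the NHW target below the
achievable range. Only the *mean* score is calibrated: the synthetic score
SD (about 0.07 in NHW) is roughly twice the published 0.034, since the
large synthetic APOE weight dominates the variance. Parameter-recovery
conclusions are unaffected (the generative slope is defined per score unit),
but the synthetic cohort should not be read as matching the real score
*distribution*, and the worked-example reconciliation correspondingly runs
in printed-number mode.

**Outcomes.** The dementia outcome's log-odds are linear in the score with
race-specific slope $\log(\mathrm{OR}_r)/0.1$ (defaults 2.22 NHW, 1.33 NHB
per 0.1 units), anchored so a male aged 70 at score 0.1 in the first wave
has probability 0.011 (NHW) or 0.033 (NHB) — the published model-predicted
baselines for that profile. Nuisance terms (0.08 log-odds per year of age,
−0.1 for female sex, 0.02 per calendar year) are fixed simulator choices
making the adjustment set non-vacuous. Binary mode draws Bernoulli outcomes;
fractional mode stores a logit-normal perturbation (SD 0.5 on the logit
scale) of the model probability — a simulator convention, not a claim about
how the real probability score is generated. The memory score is linear in
the score (−0.07 / −0.01 SD per 0.1 units), race (−0.49 SD), age (−0.02 per
year) and year, plus Gaussian noise with SD 0.95 chosen so the first-wave SD
is close to 1; standardization by the realized first-wave SD then leaves the
generative slopes interpretable in SD units to within a few percent.

**Dropout.** After wave 1, persons die with per-wave hazard 0.04 (absorbing)
or miss a wave with probability 0.03, values chosen to give exclusion shares
comparable to the published sample accounting. Death and nonresponse are
independent of genotype by default, so dropout is non-informative; survival-
bias scenarios are a configuration option, not a calibrated replication.

**What passing tests do and do not show.** The simulator shares the fitted
models' functional form, so parameter recovery demonstrates the correctness
of the estimation machinery — not robustness to misspecification, real LD,
population stratification, practice effects, or informative mortality, none
of which the generator emulates.

## 5. Sample-flow accounting

`run_exclusion_cascade()` applies ordered predicates to an observation
table, counting each observation at the first rule it fails; percentages are
recomputed from integer counts against the pre-cascade denominator at one
decimal. On the published dementia-sample accounting (10,444 persons × 3
waves = 31,332 candidates; 9,792 under-65, then 695 nonresponse, then 1,063
deceased) the cascade reproduces 19,782 surviving observations exactly, and
the genotyped-sample retention 10,444/12,123 rounds to 86.2%. The analogous
published memory-sample count (29,062) is *not* asserted anywhere: it is
inconsistent with naive sequential subtraction of its printed exclusions
(31,332 − 1,261 − 1,168 = 28,903), indicating overlapping rules or different
denominators in the original accounting; the discrepancy is flagged rather
than resolved.

## 6. Numerical choices and problem sizes

* IRLS runs to deviance tolerance 1e-10 with at most 100 iterations;
  non-convergence is reported on the fit, never silently accepted.
* The sandwich bread is recomputed from the converged fitted values rather
  than taken from the last IRLS step, so it equals the textbook formula to
  machine precision.
* Calibration root-finding uses `uniroot` on [−12, 12] logit units at
  tolerance 1e-10, with frequencies clamped to [0.01, 0.99]; unreachable
  targets error with the achievable range.
* Significance language follows the p ≤ 0.05 convention of the source
  analyses; no multiplicity correction is applied, matching them.
* Test problem sizes: parameter recovery uses 200 replicates of the full
  7,690 × 3 design; the null-calibration study uses 500 replicates of a
  600-person balanced design with equal slopes; calibration checks use
  20,000 simulated genomes. These sizes give Monte-Carlo error comfortably
  below the asserted tolerances while keeping the default suite around two
  minutes.

## 7. Known limitations

* Weights are taken as fixed and external; no estimation, LD pruning or
  clumping is provided.
* The genotype reader handles biallelic SNPs with GT fields; no imputation,
  phasing, or dosage-format (DS) input.
* Independence working correlation only; no GEE alternatives, mixed models
  or survival models.
* The synthetic cohort calibrates score means but not score variance, age-
  or race-specific mortality, or any dependence between genotype and
  dropout.
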