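---
title: "Family-based Mendelian randomization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based Mendelian randomization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

# The scientific problem

Observational associations between a maternal pregnancy exposure (coffee
consumption, cups/day) and offspring neurodevelopmental outcomes are
vulnerable to confounding by correlated behaviours (smoking, alcohol,
socioeconomic position) and by genetic transmission: variants that raise
maternal consumption are transmitted to the child with probability 1/2 and
may affect the child's outcome directly. `triomr` implements the designs
that separate these explanations: a paternal negative control (paternal
coffee cannot act through the intrauterine environment), within-family MR
conditioning on the transmitted genome, two-sample MR on summary statistics
with pleiotropy-robust estimators, partitioning of maternal vs offspring
direct genetic effects, and MR stratified by consumption status.

# The generative model

`sim_config()` + `simulate_trios()` + `simulate_phenotypes()` produce the
cohorts every analysis is tested on.

**Genotypes.** Parental dosages at each of `m` variants are Hardy–Weinberg
draws at a minor allele frequency sampled from `maf_range` (default
0.1–0.5); each offspring allele is drawn uniformly from the corresponding
parent's two alleles. Dosages are hard calls in {0, 1, 2}. Variants are
placed so each occupies its own 1 Mb-scale window, so GRM exclusion windows
are exercisable. By default variants are independent (the instrument set is
meant to be LD-pruned); an optional Gaussian copula on latent allele
variables induces pairwise LD, existing only to exercise clumping.

**Exposure.** A hurdle structure mirrors the fact that never-consumers are a
distinct group: consumer status is Bernoulli with logit
`qlogis(base_rate) + loadings' (G_m - 2p)` (default `base_rate` 0.8,
matching the roughly four-in-five consumer share reported in Norwegian
pregnancy cohorts; loadings default to 0), and consumption among consumers
is a zero-truncated normal `max(0, mu + PGS_m + gamma_x C + e)`, with mean
`exposure_mean` 2 cups/day and residual SD 1.5. `C` is a single latent
standard-normal confounder shared with the outcome; smoking, alcohol,
education and income columns are noisy proxies of `C`, so adjusted
observational models can be exercised.

**Outcome.** `nd_raw = beta_causal * coffee_wk15 + delta_offspring * PGS_o +
delta_paternal * PGS_f + gamma_y C + e`, with defaults `beta_causal` 0.2
outcome units per cup/day, both deltas 0, confounder loadings 0.5 (exposure)
and 0.3 (outcome), residual SD 1. `nd` is its rank-based inverse-normal
transform, which is what the analyses consume.

**What the generator does not emulate.** Imputation uncertainty (fractional
dosages), X-chromosome transmission, assortative mating, population
structure, genome-scale variant panels, questionnaire item structure of
specific instruments, and reporting biases. Passing tests therefore show
that the estimators recover the parameters of *this* structural model, not
that any real-data finding is correct; in particular the mixture form of
the exposure and the INT of the outcome mean PGS-scale coefficients are
converted to cups/day by dividing by the within-model PGS–exposure slope
(`wald_scale()`), and tests always scale with the slope fitted under the
same conditioning set as the outcome model.

# Phenotype derivation rules

* Coffee aggregation sums cups/day over coffee types; individuals above
  3.5 L/day are flagged for exclusion. The cup volume behind that rule is
  not standardized across studies, so it is a parameter with default 125 mL
  (3.5 L = 28 cups).
* Caffeine (mg/day) is a configured linear combination of source servings;
  `default_caffeine_contents()` documents plausible per-serving contents and
  is pure configuration, not a claim about any specific questionnaire.
* Scale scores use 50% mean imputation: with at least half the items
  observed, missing items take the mean of the observed ones; otherwise the
  score is missing.
* The inverse-normal transform uses the Blom offset 3/8 with average ranks
  for ties; no variant was mandated, and Blom is the common default in
  genetic epidemiology.
* The effective number of tests is the smallest number of principal
  components of the outcome correlation matrix (complete cases) reaching
  80% cumulative variance; the reporting threshold is 0.05 divided by that
  count. The boundary is inclusive (cumulative fraction >= target), so 20
  mutually independent outcomes give 16 components and alpha 0.003125.

# Estimators and numerical choices

* **IVW** defaults to multiplicative random effects with the
  `max(1, sqrt(Q/(L-1)))` floor for L >= 2; the point estimate is identical
  under the fixed model. p-values are two-sided normal.
* **MR-Egger** orients every SNP–exposure beta non-negative (flipping the
  outcome beta with it) before weighted least squares with intercept;
  estimates are invariant to per-variant re-orientation. Standard errors
  carry the same multiplicative floor (residual sigma not below 1) and use
  a t reference with L − 2 df. This makes all ratio-scale standard errors
  mutually consistent, and multivariable IVW with one exposure reduces
  exactly to IVW.
* **Weighted median** interpolates standardized cumulative weights
  `(S_j − w_j/2)/S_L` at 0.5, weights `bx^2/se_y^2`; the SE is a seeded
  parametric bootstrap (default 5000 draws) resampling both `bx` and `by`.
* **Mode estimators** maximize a Gaussian-kernel density of the Wald
  ratios with bandwidth `phi × 0.9 min(sd, mad) L^{-1/5}` (modified
  Silverman on the ratio spread; `phi` default 1). A floor of 1e-8 on the
  bandwidth keeps degenerate all-equal inputs well defined, returning the
  common ratio. The SE is the median absolute deviation of a seeded
  bootstrap; p uses t with L − 1 df.
* **Harmonization** removes palindromic (A/T, C/G) variants outright — no
  frequency-based rescue — flips outcome betas where the effect alleles are
  swapped, and drops unresolvable pairs, logging every removal with a
  reason code. Clumping breaks p-value ties lexicographically by variant id
  so results never depend on row order.
* **Collider screen** defaults to a linear probability model of consumer
  status on dosage (odds ratios near 1 make the linear and logistic screens
  equivalent in practice); the logistic link is available since the model
  family behind published screens is usually unstated.
* **REML mixed model**: with a GRM supplied, `conditional_mr()` fits one
  variance component by eigendecomposing the GRM once and optimizing the
  profile REML criterion over log(sigma_g^2/sigma_e^2) on [−20, 20] with
  tolerance 1e-8. The dense eigendecomposition bounds practical use at
  roughly n ≤ 20,000. With an identity GRM the profile likelihood is flat
  in the ratio and the fit coincides with OLS, which the tests assert to
  1e-6.
* **Partitioning** solves the per-variant 2×2 transmission system exactly;
  the covariance uses `Var(d) = B^{-1} Sigma B^{-T}`. Because the direct
  maternal effect is a *contrast* of the two GWAS betas, positive sampling
  correlation between them shrinks (not widens) its standard error. The
  sampling correlation is `n_shared × pheno_corr / sqrt(n_m n_o)`; for the
  simulated duo design — maternal and offspring GWAS of the same outcome in
  fully shared families — the effective correlation is the transmission
  coefficient 0.5, which is what the pipeline passes.

# Design choices that were genuinely open

* **Conditioning on "offspring genotype at all loci"** is implemented as
  conditioning on the offspring dosages at the instrument loci. Only the
  instrument loci can transmit instrument-mediated pleiotropy, so the
  8-locus block is statistically equivalent for blocking those paths, and
  genome-wide conditioning is neither feasible nor identifiable at desk
  scale.
* **GxE stratification and colliders.** Stratifying on consumption
  conditions on a variable caused by both the maternal score and the
  confounder, opening a collider path whenever the confounder loads on the
  exposure. The collider screen removes genotype-driven selection but not
  confounder-driven selection; for that reason the parameter-recovery
  scenario for the GxE design switches the confounder loadings off, and the
  stratified estimates under the default (confounded) settings should be
  read with this caveat — which is also the key interpretive caveat of the
  design itself.
* **Strata definition**: consumers are families reporting coffee at week 15
  or week 22; never-consumers report none at both.
* **One pregnancy per mother** is honoured trivially: the simulator
  generates one family per mother.

# Problem sizes and reproducibility

The test-suite and acceptance scenarios use 20,000 families and 8 variants
for parameter recovery (the scale at which a 2-standard-error band is
informative for the default effect sizes), 500 null variants for type-I
calibration, and 2000 replicates for the heterogeneity-p uniformity check;
the pipeline demo in the README uses 5000 families. Every stochastic step
takes an explicit seed, and a pipeline config fully determines its outputs:
the same config writes bit-identical result files.

# Known limitations

* The GRM mixed model is dense-eigendecomposition REML: no sparse-GRM or
  biobank-scale path.
* Two-sample weights ignore exposure-side uncertainty in the IVW weights
  (standard NOME-style approximation); the second-order Wald SE is exposed
  where relevant.
* The hurdle/truncated-normal exposure is a stand-in: real consumption
  distributions are discrete and questionnaire-binned.
* LD is available only as a pairwise copula for exercising clumping; no
  reference-panel LD estimation or proxy-variant lookup.
* I2GX computed on weak simulated instruments is low; it is a diagnostic of
  the instrument set at hand, not a constant of the method.
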