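# triomr

Family-based Mendelian randomization (MR) for prenatal exposures, built
around genotyped parent–offspring trios. The motivating question is whether a
maternal exposure during pregnancy — here, coffee consumption in cups/day —
causally affects offspring neurodevelopmental outcomes, or whether the
observational association is driven by familial confounding and pleiotropy.
The package is aimed at genetic epidemiologists who want a tested,
simulation-backed implementation of the full analysis chain: trio cohort
simulation, phenotype derivation, polygenic score (PGS) instruments,
observational models with a paternal negative control, within-family
conditional MR, two-sample MR with sensitivity estimators, maternal/fetal
effect partitioning, multivariable MR, and gene-by-environment (GxE)
stratified MR.

## The models at the core

**Within-family conditional MR.** For offspring outcome $Y$ (rank-based
inverse-normal transformed), maternal score $\mathrm{PGS}_m$, and the
offspring genome block $G_o$ (offspring PGS or instrument-locus genotypes):

$$Y = \alpha + \beta_m \mathrm{PGS}_m + \gamma^\top G_o
      \;[+\; \beta_f \mathrm{PGS}_f] + \text{covariates} + \varepsilon$$

Conditioning on $G_o$ blocks pleiotropic paths through the transmitted
genome; in trio mode the paternal coefficient $\beta_f$ is a negative
control for postnatal confounding. Optionally $\varepsilon$ carries a
genomic-relationship-matrix (GRM) random effect fitted by profile REML.
Dividing $\hat\beta_m$ by the PGS→exposure slope converts the estimate to
outcome SD per cup/day.

**Two-sample MR.** With per-variant SNP–exposure effects $b_{x_j}$ and
SNP–outcome effects $b_{y_j}$ (standard error $\sigma_{y_j}$), the
inverse-variance weighted (IVW) estimate is weighted regression through the
origin,

$$\hat\beta_{IVW} = \frac{\sum_j b_{x_j} b_{y_j} / \sigma_{y_j}^2}
                        {\sum_j b_{x_j}^2 / \sigma_{y_j}^2},$$

with MR-Egger (intercept = directional pleiotropy), weighted median,
simple/weighted mode, Cochran's Q and $I^2_{GX}$ as sensitivity analyses,
plus multivariable IVW for direct effects conditional on co-exposures.

**Maternal/fetal partitioning.** A maternal GWAS of an offspring outcome
mixes direct maternal and direct offspring effects through transmission:
$b_m = d_m + 0.5\,d_o$ and $b_o = d_o + 0.5\,d_m$. `partition_maternal_fetal()`
solves this per variant and propagates the sampling covariance, including
the overlapping-sample error correlation.

## Worked example

```r
library(triomr)
cfg <- pipeline_config(seed = 42, sim = sim_config(n = 5000, m = 8, seed = 42),
                       n_boot = 500)
rep <- run_pipeline(cfg)
rep$summary
```

```
   analysis                   term            beta      se         p significant
 1 observational_unadjusted   coffee_wk15  0.219   0.00771 2.14e-165 TRUE
 4 observational_unadjusted   coffee_f (…  0.00568 0.00960 5.54e-  1 FALSE
 5 duo_conditional            maternal_p…  0.279   0.0834  8.24e-  4 TRUE
 8 trio_conditional           paternal_p… -0.103   0.0910  2.59e-  1 FALSE
 9 two_sample_ivw             coffee       0.399   0.115   5.11e-  4 TRUE
11 two_sample_weighted_median coffee       0.465   0.142   1.10e-  3 TRUE
14 gxe_consumers              maternal_p…  0.207   0.108   5.61e-  2 FALSE
15 gxe_non_consumers          maternal_p…  0.146   0.185   4.31e-  1 FALSE
```

(Abbreviated; the full table has 15 rows.) Reading it: the unadjusted
observational association (0.219 outcome SD per cup/day) is strong while the
paternal negative control is null, as expected when the exposure acts
prenatally; the conditional duo MR estimate (0.279 per maternal-PGS unit)
and the two-sample IVW estimate (0.399 per cup/day) recover the simulated
causal effect (0.2 per cup/day, scaled by the PGS–exposure slope) within
sampling error; the GxE consumer-stratum estimate exceeds the non-consumer
one. The `significant` flag applies the PCA effective-number-of-tests
threshold. Instrument strength for this run: F = 33.6
(`rep$instrument_diagnostics`).

Single-purpose functions compose with the pipe, e.g.

```r
h <- harmonize_variants(exposure_stats, outcome_stats)
dplyr::bind_rows(mr_ivw(h), mr_egger(h),
                 mr_weighted_median(h, seed = 1)) |> plot_mr_forest()
```

## Vignette

`vignettes/family-mr-methods.Rmd` documents the generative model and its
assumptions, every tunable parameter with units and defaults, the numerical
choices inside the estimators, and known limitations.
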