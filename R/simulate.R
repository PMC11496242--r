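#' Simulation configuration for parent-offspring trio cohorts
#'
#' Bundles every parameter of the generative model behind the package's
#' analyses: Hardy-Weinberg parental genotypes with Mendelian transmission,
#' a hurdle-structured maternal coffee exposure driven by a small set of
#' instrument variants, and an offspring outcome with prenatal causal,
#' offspring-genome-mediated, paternal/postnatal and confounder paths.
#'
#' The structural model is
#' \deqn{E_m = Z \cdot \max(0,\; \mu + G_m\beta_{gx} + \gamma_x C + \epsilon_x)}
#' \deqn{Y = \beta_c E_m + \delta_o \mathrm{PGS}_o + \delta_f \mathrm{PGS}_f +
#'       \gamma_y C + \epsilon_y}
#' where \eqn{Z} is a Bernoulli consumer flag with logit equal to
#' `qlogis(hurdle$base_rate)` plus centred dosages times `hurdle$snp_loadings`,
#' \eqn{C} is a standard-normal latent confounder shared by exposure and
#' outcome, and the polygenic scores use `instrument_effects` as weights.
#'
#' @param n Number of families.
#' @param m Number of instrument variants.
#' @param seed Integer seed; the same config always yields an identical cohort.
#' @param maf_range Interval the per-variant minor allele frequencies are drawn
#'   from; values must lie in (0, 0.5].
#' @param instrument_effects Per-allele effects on the exposure level
#'   (cups/day per effect allele); recycled to length `m`.
#' @param beta_causal Prenatal causal effect, outcome units per cup/day.
#' @param delta_offspring Offspring-genome-mediated (pleiotropic) effect,
#'   outcome units per offspring-PGS unit.
#' @param delta_paternal Postnatal/paternal path, outcome units per
#'   paternal-PGS unit.
#' @param confounder_exposure,confounder_outcome Loadings of the latent
#'   confounder on maternal exposure level and on the outcome.
#' @param confounder_paternal Loading of the confounder on the paternal
#'   exposure level (0 keeps the paternal negative control clean).
#' @param hurdle List with `base_rate` (marginal consumer probability) and
#'   `snp_loadings` (per-variant log-odds on centred dosage, recycled to `m`).
#' @param exposure_mean,exposure_sd Mean and residual SD of the latent
#'   exposure level (cups/day) among consumers before truncation at zero.
#' @param noise_sd Outcome residual SD.
#' @param ld Optional m x m allele-level correlation matrix used by a Gaussian
#'   copula to induce linkage disequilibrium between instrument variants
#'   (default `NULL`: independent variants).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trios()], [simulate_phenotypes()]
#' @export
#' @examples
#' cfg <- sim_config(n = 500, m = 8, seed = 1)
#' trios <- simulate_trios(cfg)
sim_config <- function(n = 20000, m = 8, seed = 1,
                       maf_range = c(0.1, 0.5),
                       instrument_effects = 0.1,
                       beta_causal = 0.2,
                       delta_offspring = 0,
                       delta_paternal = 0,
                       confounder_exposure = 0.5,
                       confounder_outcome = 0.3,
                       confounder_paternal = 0,
                       hurdle = list(base_rate = 0.8, snp_loadings = 0),
                       exposure_mean = 2,
                       exposure_sd = 1.5,
                       noise_sd = 1,
                       ld = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a positive count.", class = "triomr_invalid_config")
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    abort("`m` must be a positive count.", class = "triomr_invalid_config")
  }
  n <- as.integer(n); m <- as.integer(m)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5].",
          class = "triomr_invalid_config")
  }
  if (is.null(hurdle$base_rate) || hurdle$base_rate < 0 || hurdle$base_rate > 1) {
    abort("`hurdle$base_rate` must be a probability.",
          class = "triomr_invalid_config")
  }
  hurdle$snp_loadings <- rep_len(hurdle$snp_loadings %||% 0, m)
  instrument_effects <- rep_len(instrument_effects, m)
  if (!is.null(ld)) {
    ld <- as.matrix(ld)
    if (!all(dim(ld) == m) || any(abs(ld - t(ld)) > 1e-8)) {
      abort("`ld` must be a symmetric m x m correlation matrix.",
            class = "triomr_invalid_config")
    }
  }
  structure(list(
    n = n, m = m, seed = as.integer(seed), maf_range = maf_range,
    instrument_effects = instrument_effects, beta_causal = beta_causal,
    delta_offspring = delta_offspring, delta_paternal = delta_paternal,
    confounder_exposure = confounder_exposure,
    confounder_outcome = confounder_outcome,
    confounder_paternal = confounder_paternal,
    hurdle = hurdle, exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    noise_sd = noise_sd, ld = ld
  ), class = "sim_config")
}

# draw one parental allele matrix (n x m of 0/1), optionally LD-correlated
draw_alleles <- function(n, mafs, ld = NULL) {
  m <- length(mafs)
  if (is.null(ld)) {
    matrix(rbinom(n * m, 1L, rep(mafs, each = n)), nrow = n)
  } else {
    # Gaussian copula on latent allele variables
    z <- matrix(rnorm(n * m), nrow = n) %*% chol(ld)
    sweep(pnorm(z), 2, mafs, `<`) + 0L
  }
}

#' Simulate parent-offspring trio genotypes
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at each
#' variant's minor allele frequency; each offspring allele is drawn uniformly
#' from the corresponding parent's two alleles (Mendelian transmission).
#' Dosages count copies of the effect allele and are hard calls in
#' \{0, 1, 2\}. Variant positions are spaced so that each variant sits in its
#' own chromosome-window, supporting exclusion windows around instruments.
#'
#' @param config A [sim_config()].
#' @return A `trio_cohort`: a list with dosage matrices `dosage_m`, `dosage_f`,
#'   `dosage_o` (families x variants, columns named by variant id), a
#'   `variants` tibble (`id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `maf`), `phenos` (filled by [simulate_phenotypes()]) and the `config`.
#' @export
simulate_trios <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "triomr_invalid_config")
  }
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n; m <- config$m
  mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  variants <- tibble::tibble(
    id = sprintf("rs%05d", seq_len(m)),
    chrom = ((seq_len(m) - 1L) %% 22L) + 1L,
    pos = 1000000L + ((seq_len(m) - 1L) %/% 22L) * 10000000L,
    effect_allele = ea, other_allele = oa, maf = mafs
  )

  dosage_m <- draw_alleles(n, mafs, config$ld) + draw_alleles(n, mafs, config$ld)
  dosage_f <- draw_alleles(n, mafs, config$ld) + draw_alleles(n, mafs, config$ld)
  # transmitted allele: Bernoulli(dosage / 2) per parent
  trans_m <- matrix(rbinom(n * m, 1L, as.vector(dosage_m) / 2), nrow = n)
  trans_f <- matrix(rbinom(n * m, 1L, as.vector(dosage_f) / 2), nrow = n)
  dosage_o <- trans_m + trans_f

  dimnames(dosage_m) <- dimnames(dosage_f) <- dimnames(dosage_o) <-
    list(NULL, variants$id)

  structure(list(
    n_families = n,
    dosage_m = dosage_m, dosage_f = dosage_f, dosage_o = dosage_o,
    variants = variants, phenos = NULL, config = config
  ), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("<trio_cohort> ", x$n_families, " families x ", nrow(x$variants),
      " variants; phenotypes ",
      if (is.null(x$phenos)) "not yet simulated" else "attached", "\n", sep = "")
  invisible(x)
}

#' Simulate exposure, outcome and covariate phenotypes for a trio cohort
#'
#' Adds a per-family phenotype table implementing the structural model
#' described in [sim_config()]: a hurdle-gated maternal coffee exposure
#' (cups/day, reported before pregnancy and at gestational weeks 15 and 22),
#' a paternal exposure, a latent confounder with proxy covariates
#' (smoking, alcohol, education, income), nuisance covariates (birth year,
#' parental ages) and the offspring neurodevelopmental outcome, both raw and
#' rank-based inverse-normal transformed.
#'
#' @param trios A `trio_cohort` from [simulate_trios()].
#' @param config Simulation config; defaults to the one stored in `trios`.
#' @return The `trio_cohort` with `$phenos` set to a tibble.
#' @export
simulate_phenotypes <- function(trios, config = trios$config) {
  if (!inherits(trios, "trio_cohort")) {
    abort("`trios` must be a trio_cohort.", class = "triomr_invalid_input")
  }
  if (length(config$instrument_effects) != ncol(trios$dosage_m)) {
    abort("Length of `instrument_effects` must match the cohort's variant count.",
          class = "triomr_dimension_mismatch")
  }
  set.seed(derive_seed(config$seed, 2L))
  n <- trios$n_families
  w <- config$instrument_effects
  pgs_m <- drop(trios$dosage_m %*% w)
  pgs_f <- drop(trios$dosage_f %*% w)
  pgs_o <- drop(trios$dosage_o %*% w)

  confounder <- rnorm(n)
  # hurdle consumer status: logistic on centred maternal dosages
  centred <- sweep(trios$dosage_m, 2, 2 * trios$variants$maf)
  logit <- qlogis(min(max(config$hurdle$base_rate, 1e-12), 1 - 1e-12)) +
    drop(centred %*% config$hurdle$snp_loadings)
  consumer <- if (config$hurdle$base_rate >= 1) {
    rep(TRUE, n)
  } else if (config$hurdle$base_rate <= 0) {
    rep(FALSE, n)
  } else {
    runif(n) < plogis(logit)
  }

  level <- config$exposure_mean + pgs_m +
    config$confounder_exposure * confounder + rnorm(n, 0, config$exposure_sd)
  coffee_wk15 <- ifelse(consumer, pmax(0, level), 0)
  coffee_wk22 <- ifelse(consumer, pmax(0, level + rnorm(n, 0, 0.3)), 0)
  coffee_pre <- pmax(0, level + rnorm(n, 0, 0.5))

  level_f <- config$exposure_mean + pgs_f +
    config$confounder_paternal * confounder + rnorm(n, 0, config$exposure_sd)
  coffee_f <- pmax(0, level_f)

  nd_raw <- config$beta_causal * coffee_wk15 +
    config$delta_offspring * pgs_o +
    config$delta_paternal * pgs_f +
    config$confounder_outcome * confounder +
    rnorm(n, 0, config$noise_sd)

  phenos <- tibble::tibble(
    family_id = seq_len(n),
    coffee_pre = coffee_pre,
    coffee_wk15 = coffee_wk15,
    coffee_wk22 = coffee_wk22,
    coffee_f = coffee_f,
    consumer_flag = coffee_wk15 > 0 | coffee_wk22 > 0,
    confounder = confounder,
    smoking = pmax(0, 5 * confounder + rnorm(n, 3, 4)),
    alcohol = pmax(0, 0.5 * confounder + rnorm(n, 0.5, 0.7)),
    education = 13 - confounder + rnorm(n, 0, 2),
    income = 450000 - 20000 * confounder + rnorm(n, 0, 80000),
    birth_year = sample(1999:2008, n, replace = TRUE),
    age_m = rnorm(n, 30, 4.5),
    age_f = rnorm(n, 32.5, 5),
    nd_raw = nd_raw,
    nd = rank_inverse_normal(nd_raw)
  )
  trios$phenos <- phenos
  trios$config <- config
  trios
}

#' Knock out scale items at random
#'
#' Sets each cell of an item matrix to missing independently with probability
#' `rate`; used to exercise the scale-score mean-imputation rule.
#'
#' @param items Numeric matrix of questionnaire items (rows = individuals).
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed; the mask is reproducible.
#' @return The matrix with `NA` entries injected.
#' @export
inject_item_missingness <- function(items, rate, seed) {
  items <- as.matrix(items)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    abort("`rate` must be in [0, 1).", class = "triomr_invalid_config")
  }
  set.seed(as.integer(seed))
  mask <- matrix(runif(length(items)) < rate, nrow = nrow(items))
  items[mask] <- NA_real_
  items
}
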