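#' Observational regression of offspring outcome on parental coffee exposure
#'
#' Ordinary least squares of an (inverse-normal transformed) offspring
#' neurodevelopmental outcome on a parental coffee exposure, with three
#' covariate presets:
#'
#' * `unadjusted` - offspring birth year and both parental ages at birth;
#' * `adjusted`   - additionally maternal smoking and alcohol (continuous and
#'   binary), education and income, the classic behavioural/socioeconomic
#'   confounder set;
#' * `intrauterine` - the adjusted set plus pre-pregnancy coffee consumption,
#'   isolating consumption during pregnancy.
#'
#' Using the paternal exposure (`exposure = "coffee_f"`) provides the negative
#' control: paternal coffee cannot act through the intrauterine environment,
#' so a nonzero paternal coefficient flags familial confounding.
#'
#' Analysis is complete-case for the preset's columns. A rank-deficient design
#' raises a collinearity error naming the aliased columns.
#'
#' @param pheno Phenotype data frame (e.g. `trio_cohort$phenos`).
#' @param exposure Name of the exposure column (cups/day).
#' @param outcome Name of the outcome column.
#' @param preset One of `"unadjusted"`, `"adjusted"`, `"intrauterine"`.
#' @param covariates Optional character vector overriding/extending the
#'   preset's covariate list (columns of `pheno`).
#' @return One-row tibble: `term`, `beta`, `se`, `p`, `n`, `preset`,
#'   `outcome` (class `triomr_regression`).
#' @export
fit_observational <- function(pheno, exposure, outcome = "nd",
                              preset = c("unadjusted", "adjusted",
                                         "intrauterine"),
                              covariates = NULL) {
  preset <- match.arg(preset)
  base <- intersect(c("birth_year", "age_m", "age_f"), names(pheno))
  conf <- intersect(c("smoking", "smoking_bin", "alcohol", "alcohol_bin",
                      "education", "income"), names(pheno))
  covs <- switch(preset,
    unadjusted = base,
    adjusted = c(base, conf),
    intrauterine = c(base, conf, "coffee_pre")
  )
  covs <- setdiff(union(covs, covariates), exposure)
  missing_cols <- setdiff(c(exposure, outcome, covs), names(pheno))
  if (length(missing_cols)) {
    abort(paste0("Columns not found in `pheno`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "triomr_validation_error")
  }
  dat <- pheno[complete.cases(pheno[, c(exposure, outcome, covs)]),
               c(exposure, outcome, covs), drop = FALSE]
  fml <- stats::reformulate(c(exposure, covs), response = outcome)
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Design is rank deficient; aliased columns: ",
                 paste(bad, collapse = ", ")),
          class = "triomr_collinearity_error")
  }
  cf <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = exposure,
    beta = cf[exposure, 1],
    se = cf[exposure, 2],
    p = cf[exposure, 4],
    n = nrow(dat),
    preset = preset,
    outcome = outcome
  )
  class(out) <- c("triomr_regression", class(out))
  out
}
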