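#' Per-variant GWAS on a trio cohort
#'
#' Ordinary least squares of the outcome on each variant's dosage plus shared
#' covariates, computed exactly via Frisch-Waugh residualization (outcome and
#' dosages are residualized on the covariates once, then each variant is a
#' simple regression on its residualized dosage). Monomorphic variants are
#' flagged and reported with missing beta.
#'
#' @param trios A `trio_cohort` with phenotypes attached.
#' @param outcome Outcome column name in `trios$phenos` (default `"nd"`).
#' @param who Whose dosages to test: `"maternal"`, `"offspring"` or
#'   `"paternal"`.
#' @param covariates Character vector of covariate columns in `trios$phenos`.
#' @return Tibble of summary-statistic rows: `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`,
#'   `monomorphic`.
#' @export
per_snp_gwas <- function(trios, outcome = "nd",
                         who = c("maternal", "offspring", "paternal"),
                         covariates = c("birth_year", "age_m", "age_f")) {
  who <- match.arg(who)
  if (is.null(trios$phenos) || !outcome %in% names(trios$phenos)) {
    abort("Outcome column not found in the cohort's phenotype table.",
          class = "triomr_validation_error")
  }
  dos <- switch(who, maternal = trios$dosage_m, offspring = trios$dosage_o,
                paternal = trios$dosage_f)
  y <- trios$phenos[[outcome]]
  covariates <- intersect(covariates, names(trios$phenos))
  C <- cbind(1, as.matrix(trios$phenos[, covariates, drop = FALSE]))
  ok <- complete.cases(cbind(y, C))
  y <- y[ok]; C <- C[ok, , drop = FALSE]; dos <- dos[ok, , drop = FALSE]
  n <- length(y)
  q <- qr(C)
  ry <- qr.resid(q, y)
  rg <- qr.resid(q, dos)
  sgg <- colSums(rg^2)
  mono <- sgg < 1e-12
  beta <- se <- p <- rep(NA_real_, ncol(dos))
  df <- n - ncol(C) - 1
  sgy <- colSums(rg * ry)
  beta[!mono] <- sgy[!mono] / sgg[!mono]
  rss <- sum(ry^2) - beta[!mono]^2 * sgg[!mono]
  se[!mono] <- sqrt(pmax(rss, 0) / df / sgg[!mono])
  p[!mono] <- p_from_t(beta[!mono] / se[!mono], df)
  tibble::tibble(
    id = colnames(dos),
    chrom = trios$variants$chrom[match(colnames(dos), trios$variants$id)],
    pos = trios$variants$pos[match(colnames(dos), trios$variants$id)],
    effect_allele = trios$variants$effect_allele[match(colnames(dos),
                                                       trios$variants$id)],
    other_allele = trios$variants$other_allele[match(colnames(dos),
                                                     trios$variants$id)],
    eaf = colMeans(dos) / 2,
    beta = beta, se = se, p = p, n = n, monomorphic = mono
  )
}

#' Sampling correlation between overlapping GWAS
#'
#' Closed-form correlation between the estimation errors of two GWAS sharing
#' `n_shared` individuals:
#' \eqn{r = n_{shared} \cdot \rho / \sqrt{n_m n_o}}.
#' In applications to real cohorts this quantity is usually estimated with
#' bivariate LD score regression; in simulation the overlap is known.
#'
#' @param n_m,n_o Sample sizes of the two GWAS.
#' @param n_shared Number of shared individuals (0 <= n_shared <= min(n_m,
#'   n_o)).
#' @param pheno_corr Phenotypic correlation between the two analysed traits
#'   in the shared individuals.
#' @return Scalar correlation in \[-1, 1\].
#' @export
overlap_correlation <- function(n_m, n_o, n_shared, pheno_corr) {
  if (n_m < 1 || n_o < 1 || n_shared < 0 || n_shared > min(n_m, n_o)) {
    abort("Invalid sample counts.", class = "triomr_validation_error")
  }
  n_shared * pheno_corr / sqrt(n_m * n_o)
}

#' Partition maternal and offspring GWAS effects into direct effects
#'
#' A maternal GWAS of the offspring outcome mixes the direct maternal effect
#' with half the direct offspring effect (and vice versa), because parents
#' transmit each allele with probability 1/2 under random mating:
#' \deqn{b_m = d_m + 0.5\, d_o, \qquad b_o = d_o + 0.5\, d_m.}
#' Solving the 2 x 2 system per variant gives
#' \eqn{d_m = (4 b_m - 2 b_o)/3} and \eqn{d_o = (4 b_o - 2 b_m)/3}, with
#' sampling covariance \eqn{B^{-1} \Sigma B^{-\top}} where \eqn{\Sigma} uses
#' the overlap correlation `r_overlap` between the two GWAS errors.
#'
#' @param b_m,se_m Maternal GWAS effect(s) and SE(s); vectors are allowed.
#' @param b_o,se_o Offspring GWAS effect(s) and SE(s).
#' @param r_overlap Sampling correlation (scalar or per-variant), see
#'   [overlap_correlation()].
#' @return Tibble with `d_m`, `se_dm`, `d_o`, `se_do`, `cov_dm_do` (plus the
#'   inputs). The reconstruction identities `d_m + 0.5 d_o = b_m` and
#'   `d_o + 0.5 d_m = b_o` hold exactly.
#' @export
partition_maternal_fetal <- function(b_m, se_m, b_o, se_o, r_overlap = 0) {
  check_positive_se(se_m, "se_m")
  check_positive_se(se_o, "se_o")
  if (any(abs(r_overlap) > 1)) {
    abort("`r_overlap` must lie in [-1, 1].", class = "triomr_validation_error")
  }
  # B = [[1, .5], [.5, 1]]; B^{-1} = [[4/3, -2/3], [-2/3, 4/3]]
  d_m <- (4 * b_m - 2 * b_o) / 3
  d_o <- (4 * b_o - 2 * b_m) / 3
  cov_bm_bo <- r_overlap * se_m * se_o
  var_dm <- (16 * se_m^2 + 4 * se_o^2 - 16 * cov_bm_bo) / 9
  var_do <- (4 * se_m^2 + 16 * se_o^2 - 16 * cov_bm_bo) / 9
  cov_dm_do <- (-8 * se_m^2 - 8 * se_o^2 + 20 * cov_bm_bo) / 9
  tibble::tibble(
    b_m = b_m, se_m = se_m, b_o = b_o, se_o = se_o,
    r_overlap = rep_len(r_overlap, length(d_m)),
    d_m = d_m, se_dm = sqrt(var_dm),
    d_o = d_o, se_do = sqrt(var_do),
    cov_dm_do = cov_dm_do
  )
}
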