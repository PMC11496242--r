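#' Build a polygenic score from dosages and instrument weights
#'
#' Weighted mode: the score is the dosage of each weight's effect allele times
#' its per-allele effect (cups/day), summed over variants. Unweighted mode
#' counts consumption-increasing alleles: a variant with a negative weight
#' contributes `2 - dosage` (its other allele raises consumption).
#'
#' @param dosages Families x variants matrix with columns named by variant id;
#'   entries count copies of the stored allele.
#' @param weights Data frame with columns `id`, `effect_allele`, `weight`
#'   (cups/day per allele). Weights not present in `dosages` raise an error.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param variants Optional variant metadata (`id`, `effect_allele`) declaring
#'   which allele the dosage columns count; where it differs from the weight's
#'   effect allele the dosage is flipped to `2 - d`.
#' @return Numeric score vector, one value per family.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2), 1, dimnames = list(NULL, c("v1", "v2", "v3")))
#' w <- tibble::tibble(id = c("v1", "v2", "v3"),
#'                     effect_allele = "A", weight = 0.1)
#' build_pgs(d, w) # 0.3
build_pgs <- function(dosages, weights, mode = c("weighted", "unweighted"),
                      variants = NULL) {
  mode <- match.arg(mode)
  missing_v <- setdiff(weights$id, colnames(dosages))
  if (length(missing_v)) {
    abort(paste0("Variant(s) in weights absent from dosages: ",
                 paste(missing_v, collapse = ", ")),
          class = "triomr_missing_variant")
  }
  d <- dosages[, weights$id, drop = FALSE]
  if (!is.null(variants)) {
    stored <- variants$effect_allele[match(weights$id, variants$id)]
    flip <- !is.na(stored) & stored != weights$effect_allele
    if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  }
  if (mode == "weighted") {
    drop(d %*% weights$weight)
  } else {
    oriented <- d
    neg <- weights$weight < 0
    if (any(neg)) oriented[, neg] <- 2 - oriented[, neg, drop = FALSE]
    rowSums(oriented)
  }
}

#' Instrument-strength diagnostics for a polygenic score
#'
#' Regresses the exposure on the score (plus covariates) and reports the
#' score coefficient, its F statistic (the squared t statistic for a single
#' instrument) and sample size. F > 10 is the conventional weak-instrument
#' bar.
#'
#' @param score Numeric instrument vector (PGS).
#' @param exposure Numeric exposure vector (cups/day).
#' @param covariates Optional data frame or matrix of covariates.
#' @return One-row tibble: `beta_gx`, `se`, `F`, `p`, `n`.
#' @export
benchmark_instrument <- function(score, exposure, covariates = NULL) {
  if (sd(score, na.rm = TRUE) == 0) {
    abort("Instrument score is constant.", class = "triomr_degenerate_instrument")
  }
  dat <- data.frame(.exposure = exposure, .score = score)
  covs <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covs <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- lm(stats::reformulate(c(".score", covs), response = ".exposure"),
            data = dat)
  cf <- summary(fit)$coefficients
  tstat <- cf[".score", 3]
  tibble::tibble(beta_gx = cf[".score", 1], se = cf[".score", 2],
                 F = tstat^2, p = cf[".score", 4], n = nrow(dat))
}

#' I-squared (GX) statistic for MR-Egger weak-instrument dilution
#'
#' Heterogeneity of the SNP-exposure associations relative to their standard
#' errors: \eqn{I^2_{GX} = \max(0, (Q - (L - 1)) / Q)} with Q the
#' inverse-variance weighted heterogeneity statistic of the `bx`. Values near
#' 1 indicate that measurement error in the SNP-exposure estimates causes
#' little regression-dilution bias in MR-Egger.
#'
#' @param bx Per-variant SNP-exposure effects.
#' @param se_x Their standard errors (all > 0).
#' @return Fraction in \[0, 1\].
#' @export
i2_gx <- function(bx, se_x) {
  if (length(bx) < 2) {
    abort("Need at least two variants.", class = "triomr_validation_error")
  }
  check_positive_se(se_x, "se_x")
  w <- 1 / se_x^2
  b_bar <- sum(w * bx) / sum(w)
  q <- sum(w * (bx - b_bar)^2)
  if (q <= 0) return(0)
  max(0, (q - (length(bx) - 1)) / q)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effect alleles to the exposure's: variants present in both
#' sets are retained; where the outcome's effect allele equals the exposure's
#' other allele, the outcome beta is sign-flipped (and EAF complemented if
#' present); palindromic variants (A/T or C/G pairs) are removed outright (no
#' frequency-based rescue); unresolvable allele pairs are removed. Every
#' removal is recorded in an audit log attached as the `"audit"` attribute
#' (retrieve with [audit_log()]).
#'
#' @param exposure,outcome Data frames with columns `id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (optionally `eaf`, `p`). Duplicate ids
#'   within a set raise an error.
#' @return A tibble of class `harmonized_set` with per-variant columns `id`,
#'   `effect_allele`, `other_allele`, `bx`, `se_x`, `by`, `se_y`.
#' @export
harmonize_variants <- function(exposure, outcome) {
  for (nm in list(list(exposure, "exposure"), list(outcome, "outcome"))) {
    if (anyDuplicated(nm[[1]]$id)) {
      abort(paste0("Duplicate variant ids in ", nm[[2]], " set."),
            class = "triomr_duplicate_variant")
    }
  }
  log <- tibble::tibble(id = character(), action = character(),
                        reason = character())
  add_log <- function(ids, action, reason) {
    if (length(ids)) {
      log <<- dplyr::bind_rows(log, tibble::tibble(id = ids, action = action,
                                                   reason = reason))
    }
  }
  add_log(setdiff(exposure$id, outcome$id), "dropped", "unmatched")
  add_log(setdiff(outcome$id, exposure$id), "dropped", "unmatched")

  j <- dplyr::inner_join(
    dplyr::select(exposure, "id", "effect_allele", "other_allele",
                  bx = "beta", se_x = "se"),
    dplyr::select(outcome, "id", ea_out = "effect_allele",
                  nea_out = "other_allele", by = "beta", se_y = "se"),
    by = "id"
  )

  pal <- is_palindromic(j$effect_allele, j$other_allele) |
    is_palindromic(j$ea_out, j$nea_out)
  add_log(j$id[pal], "removed", "palindromic")
  j <- j[!pal, , drop = FALSE]

  same <- j$ea_out == j$effect_allele & j$nea_out == j$other_allele
  swapped <- j$ea_out == j$other_allele & j$nea_out == j$effect_allele
  bad <- !(same | swapped)
  add_log(j$id[bad], "removed", "allele_mismatch")
  add_log(j$id[swapped], "flipped", "effect_allele_swap")
  j <- j[!bad, , drop = FALSE]
  swapped <- j$ea_out == j$other_allele
  j$by[swapped] <- -j$by[swapped]

  out <- tibble::as_tibble(j[, c("id", "effect_allele", "other_allele",
                                 "bx", "se_x", "by", "se_y")])
  class(out) <- c("harmonized_set", class(out))
  attr(out, "audit") <- log
  out
}

#' @rdname harmonize_variants
#' @param x A `harmonized_set`.
#' @export
audit_log <- function(x) attr(x, "audit") %||%
  tibble::tibble(id = character(), action = character(), reason = character())

#' Greedy LD clumping of summary statistics
#'
#' Among variants with p below `p_thresh`, iterates in ascending p (ties
#' broken lexicographically by id for determinism) and keeps a variant unless
#' its r-squared with any already-kept variant exceeds `r2_thresh`.
#'
#' @param rows Data frame with columns `id` and `p`.
#' @param ld_matrix Symmetric matrix of r-squared values with unit diagonal,
#'   dimnames covering the ids in `rows`.
#' @param p_thresh Significance threshold (default 5e-8).
#' @param r2_thresh LD threshold (default 0.001).
#' @return The retained rows, in ascending p order.
#' @export
clump_variants <- function(rows, ld_matrix, p_thresh = 5e-8,
                           r2_thresh = 0.001) {
  ld_matrix <- as.matrix(ld_matrix)
  if (is.null(dimnames(ld_matrix))) {
    if (nrow(ld_matrix) != nrow(rows)) {
      abort("`ld_matrix` dimension does not match `rows`.",
            class = "triomr_dimension_mismatch")
    }
    dimnames(ld_matrix) <- list(rows$id, rows$id)
  }
  if (!all(rows$id %in% rownames(ld_matrix))) {
    abort("`ld_matrix` does not cover all variant ids.",
          class = "triomr_dimension_mismatch")
  }
  cand <- rows[rows$p < p_thresh, , drop = FALSE]
  cand <- cand[order(cand$p, cand$id), , drop = FALSE]
  kept <- character(0)
  for (id in cand$id) {
    if (!length(kept) || all(ld_matrix[id, kept] <= r2_thresh)) {
      kept <- c(kept, id)
    }
  }
  cand[match(kept, cand$id), , drop = FALSE]
}

#' Screen instruments for association with consumer status (collider screen)
#'
#' Conditioning a stratified MR on consumption status opens a collider path
#' for any variant that itself predicts ever/never consuming. The binary
#' consumer flag is regressed on each variant's maternal dosage (linear
#' probability model by default, logistic as an option); variants with p below
#' `alpha` are listed for exclusion from the stratified-analysis score.
#'
#' @param trios A `trio_cohort`, or a maternal dosage matrix with named
#'   columns.
#' @param consumer_flag Logical/0-1 vector; must not be constant.
#' @param alpha Exclusion threshold (default 0.05).
#' @param covariates Optional covariate data frame.
#' @param link `"linear"` (linear probability model) or `"logistic"`.
#' @return Tibble with `id`, `beta`, `se`, `p`, `excluded`.
#' @export
collider_screen <- function(trios, consumer_flag, alpha = 0.05,
                            covariates = NULL,
                            link = c("linear", "logistic")) {
  link <- match.arg(link)
  dos <- if (inherits(trios, "trio_cohort")) trios$dosage_m else as.matrix(trios)
  y <- as.numeric(consumer_flag)
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("`consumer_flag` is constant.", class = "triomr_degenerate_outcome")
  }
  fit_one <- function(g) {
    dat <- data.frame(.y = y, .g = g)
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    fml <- stats::reformulate(setdiff(names(dat), ".y"), response = ".y")
    cf <- if (link == "linear") {
      summary(lm(fml, data = dat))$coefficients
    } else {
      summary(stats::glm(fml, data = dat, family = stats::binomial()))$coefficients
    }
    cf[".g", c(1, 2, 4)]
  }
  res <- t(apply(dos, 2, fit_one))
  out <- tibble::tibble(id = colnames(dos), beta = res[, 1], se = res[, 2],
                        p = res[, 3], excluded = res[, 3] < alpha)
  out
}
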