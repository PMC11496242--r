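#' Genomic relationship matrix from standardized dosages
#'
#' \eqn{K = Z Z^\top / m^*} over columnwise standardized dosages
#' \eqn{z_{ij} = (d_{ij} - 2\hat p_j) / \sqrt{2 \hat p_j (1 - \hat p_j)}} of
#' the variants outside the exclusion windows. Excluding the instrument loci
#' (plus a flanking window, conventionally 1 Mb either side) keeps the same
#' signal out of the fixed and random parts of a mixed model.
#'
#' @param dosages Individuals x variants dosage matrix, columns named by id.
#' @param variants Variant metadata (`id`, `chrom`, `pos`); required when
#'   `exclusions` is given.
#' @param exclusions Optional data frame of regions `chrom`, `start`, `end`;
#'   variants inside any region are dropped before standardization.
#' @return A `grm` object: the n x n matrix with attributes `m_variants`
#'   (count used) and `excluded` (ids dropped).
#' @export
build_grm <- function(dosages, variants = NULL, exclusions = NULL) {
  dosages <- as.matrix(dosages)
  keep <- rep(TRUE, ncol(dosages))
  excluded_ids <- character(0)
  if (!is.null(exclusions) && nrow(exclusions)) {
    if (is.null(variants)) {
      abort("`variants` metadata required to apply `exclusions`.",
            class = "triomr_validation_error")
    }
    meta <- variants[match(colnames(dosages), variants$id), ]
    inside <- rep(FALSE, ncol(dosages))
    for (k in seq_len(nrow(exclusions))) {
      inside <- inside | (meta$chrom == exclusions$chrom[k] &
                            meta$pos >= exclusions$start[k] &
                            meta$pos <= exclusions$end[k])
    }
    keep <- !inside
    excluded_ids <- colnames(dosages)[inside]
  }
  p_hat <- colMeans(dosages, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1
  keep <- keep & poly
  if (sum(keep) < 2) {
    abort("Fewer than two polymorphic variants remain outside exclusions.",
          class = "triomr_validation_error")
  }
  d <- dosages[, keep, drop = FALSE]
  p <- p_hat[keep]
  z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  k <- tcrossprod(z) / ncol(z)
  structure(k, m_variants = ncol(z), excluded = excluded_ids, class = "grm")
}

#' Exclusion windows around instrument variants
#'
#' @param variants Variant metadata (`id`, `chrom`, `pos`).
#' @param flank_bp Window half-width in base pairs (default 1e6, i.e. 1 Mb
#'   either side).
#' @return Tibble `chrom`, `start`, `end`, one row per variant.
#' @export
instrument_exclusion_windows <- function(variants, flank_bp = 1e6) {
  tibble::tibble(chrom = variants$chrom,
                 start = pmax(0, variants$pos - flank_bp),
                 end = variants$pos + flank_bp)
}

# Profile-REML fit of y = X b + g + e with g ~ N(0, sigma_g^2 K).
# Eigendecompose K once, then 1-D optimization of the REML criterion over
# log(lambda), lambda = sigma_g^2 / sigma_e^2.
reml_grm_fit <- function(y, X, K, tol = 1e-8) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)

  reml_nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    XtWX <- crossprod(Xs / w, Xs)
    beta <- solve(XtWX, crossprod(Xs / w, ys))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    sigma_e2 <- rss / (n - p)
    0.5 * ((n - p) * log(sigma_e2) + sum(log(w)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- optimize(reml_nll, interval = c(-20, 20), tol = tol)
  lam <- exp(opt$minimum)
  w <- lam * d + 1
  XtWX <- crossprod(Xs / w, Xs)
  beta <- drop(solve(XtWX, crossprod(Xs / w, ys)))
  r <- ys - Xs %*% beta
  sigma_e2 <- sum(r^2 / w) / (n - p)
  list(beta = beta, vcov = sigma_e2 * solve(XtWX),
       sigma_g2 = lam * sigma_e2, sigma_e2 = sigma_e2, df = n - p)
}

#' Individual-level conditional Mendelian randomization
#'
#' Regresses the offspring outcome on the maternal polygenic score while
#' conditioning on an offspring block - the offspring PGS or the offspring
#' dosages at the instrument loci - to block pleiotropic paths through the
#' transmitted genome. In trio mode a paternal block is conditioned on as
#' well, and the paternal coefficient doubles as a negative control for
#' postnatal confounding. With a `grm` supplied the model is a
#' one-variance-component linear mixed model fitted by profile REML
#' (dense eigendecomposition; intended for n up to ~20,000), otherwise OLS.
#'
#' @param outcome Numeric outcome vector (typically INT-transformed).
#' @param pgs_m Maternal score vector.
#' @param offspring Offspring conditioning block: vector (PGS) or matrix
#'   (dosage columns); `NULL` for the unconditional model.
#' @param pgs_f Optional paternal block (vector or matrix); enables trio mode.
#' @param covariates Optional covariate data frame/matrix.
#' @param grm Optional [build_grm()] matrix aligned with the rows.
#' @param stratum Label stored in the result (default `"all"`).
#' @return Tibble of class `conditional_estimate`, one row per parental term:
#'   `term`, `beta`, `se`, `p`, `n`, `conditioning`, `stratum`.
#' @export
conditional_mr <- function(outcome, pgs_m, offspring = NULL, pgs_f = NULL,
                           covariates = NULL, grm = NULL, stratum = "all") {
  n <- length(outcome)
  X <- cbind(`(Intercept)` = 1, pgs_m = pgs_m)
  conditioning <- "none"
  if (!is.null(offspring)) {
    ob <- as.matrix(offspring)
    conditioning <- if (ncol(ob) > 1) "offspring_genotypes" else "offspring_pgs"
    colnames(ob) <- paste0("offspring_", seq_len(ncol(ob)))
    X <- cbind(X, ob)
  }
  trio <- !is.null(pgs_f)
  if (trio) {
    pb <- as.matrix(pgs_f)
    colnames(pb) <- if (ncol(pb) > 1) {
      paste0("paternal_", seq_len(ncol(pb)))
    } else "pgs_f"
    X <- cbind(X, pb)
  }
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    colnames(cm) <- paste0("cov_", colnames(cm))
    X <- cbind(X, cm)
  }
  ok <- complete.cases(cbind(outcome, X))
  X <- X[ok, , drop = FALSE]
  y <- outcome[ok]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("Conditioning block is collinear with the maternal score.",
          class = "triomr_collinearity_error")
  }
  if (is.null(grm)) {
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - ncol(X)
    vc <- rss / df * chol2inv(qr.R(qrX))
    beta <- fit$coefficients
    ses <- sqrt(diag(vc))
  } else {
    fit <- reml_grm_fit(y, X, unclass(grm)[ok, ok])
    beta <- fit$beta
    ses <- sqrt(diag(fit$vcov))
    df <- fit$df
  }
  names(ses) <- colnames(X)
  terms <- c("pgs_m", if (trio && "pgs_f" %in% colnames(X)) "pgs_f")
  est <- unname(beta[terms])
  ese <- unname(ses[terms])
  out <- tibble::tibble(
    term = sub("pgs_m", "maternal_pgs", sub("pgs_f", "paternal_pgs", terms)),
    beta = est,
    se = ese,
    p = p_from_t(est / ese, df),
    n = length(y),
    conditioning = conditioning,
    stratum = stratum
  )
  class(out) <- c("conditional_estimate", class(out))
  out
}

#' Rescale a PGS-unit effect to exposure units
#'
#' Individual-level MR reports outcome change per PGS unit; dividing by the
#' PGS-exposure coefficient (Wald ratio, first-order delta-method standard
#' error) converts it to outcome change per cup/day.
#'
#' @param beta_pgs_outcome,se_out PGS-outcome coefficient and SE.
#' @param beta_pgs_exposure,se_exp PGS-exposure coefficient and (optional) SE.
#' @param second_order Use the second-order delta SE including `se_exp`.
#' @return One-row tibble `beta`, `se`.
#' @export
wald_scale <- function(beta_pgs_outcome, se_out, beta_pgs_exposure,
                       se_exp = NULL, second_order = FALSE) {
  if (beta_pgs_exposure == 0) {
    abort("PGS-exposure coefficient is zero.", class = "triomr_validation_error")
  }
  beta <- beta_pgs_outcome / beta_pgs_exposure
  se <- if (second_order) {
    if (is.null(se_exp)) {
      abort("`se_exp` required for the second-order SE.",
            class = "triomr_validation_error")
    }
    sqrt(se_out^2 / beta_pgs_exposure^2 +
           beta_pgs_outcome^2 * se_exp^2 / beta_pgs_exposure^4)
  } else {
    se_out / abs(beta_pgs_exposure)
  }
  tibble::tibble(beta = beta, se = se)
}

#' Gene-by-environment stratified conditional MR
#'
#' Runs [conditional_mr()] separately in the consumer and non-consumer strata
#' and compares the two maternal estimates with a two-estimate Cochran's Q
#' (1 df). Under a genuine intrauterine effect the signal should appear only
#' in the consumer stratum; similar estimates in both strata point to
#' pleiotropy. The score should be built from collider-screened weights.
#'
#' @param outcome,pgs_m,offspring,pgs_f,covariates,grm As [conditional_mr()].
#' @param strata_flag Logical vector; `TRUE` = consumer.
#' @return A `gxe_mr` object: list with `estimates` (stacked
#'   `conditional_estimate` rows) and `heterogeneity` (`Q`, `df`, `p`).
#' @export
gxe_stratified <- function(outcome, pgs_m, offspring = NULL, pgs_f = NULL,
                           covariates = NULL, strata_flag, grm = NULL) {
  strata_flag <- as.logical(strata_flag)
  if (!any(strata_flag, na.rm = TRUE) || !any(!strata_flag, na.rm = TRUE)) {
    abort("Both strata must be non-empty.", class = "triomr_validation_error")
  }
  run <- function(sel, label) {
    conditional_mr(
      outcome[sel], pgs_m[sel],
      offspring = if (!is.null(offspring)) as.matrix(offspring)[sel, , drop = FALSE],
      pgs_f = if (!is.null(pgs_f)) as.matrix(pgs_f)[sel, , drop = FALSE],
      covariates = if (!is.null(covariates)) {
        as.data.frame(covariates)[sel, , drop = FALSE]
      },
      grm = if (!is.null(grm)) structure(unclass(grm)[sel, sel], class = "grm"),
      stratum = label
    )
  }
  cons <- run(which(strata_flag), "consumers")
  non <- run(which(!strata_flag), "non_consumers")
  est <- dplyr::bind_rows(cons, non)
  mat <- dplyr::filter(est, .data$term == "maternal_pgs")
  het <- heterogeneity_test(mat$beta[1], mat$se[1], mat$beta[2], mat$se[2])
  structure(list(estimates = est, heterogeneity = het), class = "gxe_mr")
}

#' @export
print.gxe_mr <- function(x, ...) {
  cat("<gxe_mr> stratified conditional MR\n")
  print(x$estimates)
  cat(sprintf("Heterogeneity: Q = %.4g (df 1), p = %.4g\n",
              x$heterogeneity$Q, x$heterogeneity$p))
  invisible(x)
}

#' @export
tidy.gxe_mr <- function(x, ...) x$estimates

#' @export
glance.gxe_mr <- function(x, ...) {
  tibble::tibble(Q = x$heterogeneity$Q, df = x$heterogeneity$df,
                 p_heterogeneity = x$heterogeneity$p)
}
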