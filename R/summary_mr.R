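
# internal: assemble one result row
mr_row <- function(method, beta, se, p, n_snps, Q = NA_real_, Q_df = NA_real_,
                   Q_p = NA_real_, egger_intercept = NA_real_,
                   egger_intercept_se = NA_real_,
                   egger_intercept_p = NA_real_) {
  out <- tibble::tibble(
    method = method, beta = beta, se = se, p = p, n_snps = as.integer(n_snps),
    Q = Q, Q_df = Q_df, Q_p = Q_p, egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p
  )
  class(out) <- c("mr_result", class(out))
  out
}

as_hset <- function(set) {
  need <- c("bx", "se_x", "by", "se_y")
  if (!all(need %in% names(set))) {
    abort("A harmonized set needs columns bx, se_x, by, se_y.",
          class = "triomr_validation_error")
  }
  check_positive_se(set$se_y, "se_y")
  set
}

#' Wald ratio causal estimate for a single variant
#'
#' `beta = by / bx` with first-order standard error `se_y / |bx|`
#' (optionally the second-order delta SE including exposure uncertainty).
#'
#' @param bx,se_x SNP-exposure effect (cups/day per allele) and SE.
#' @param by,se_y SNP-outcome effect (outcome SD per allele) and SE.
#' @param second_order Include the exposure-uncertainty term in the SE.
#' @return One-row `mr_result` tibble.
#' @export
mr_wald_ratio <- function(bx, se_x, by, se_y, second_order = FALSE) {
  if (bx == 0) {
    abort("`bx` must be nonzero for a Wald ratio.",
          class = "triomr_validation_error")
  }
  beta <- by / bx
  se <- if (second_order) {
    sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  } else {
    se_y / abs(bx)
  }
  mr_row("wald_ratio", beta, se, p_from_z(beta / se), 1L)
}

#' Inverse-variance weighted two-sample MR
#'
#' The IVW estimate is the weighted regression-through-origin of outcome on
#' exposure betas with weights \eqn{1/se_y^2}:
#' \eqn{\hat\beta = \sum b_x b_y / se_y^2 \big/ \sum b_x^2 / se_y^2}.
#' The default multiplicative random-effects model inflates the fixed-effect
#' SE by \eqn{\max(1, \sqrt{Q/(L-1)})}; the point estimate is identical under
#' both models. Cochran's Q of the per-variant ratios about the pooled slope
#' is reported alongside.
#'
#' @param set Harmonized set (tibble with `bx`, `se_x`, `by`, `se_y`).
#' @param model `"multiplicative_random"` (default for L >= 2) or `"fixed"`.
#' @return One-row `mr_result` tibble.
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  set <- as_hset(set)
  L <- nrow(set)
  if (L < 1) abort("Empty instrument set.", class = "triomr_validation_error")
  w <- 1 / set$se_y^2
  sxx <- sum(w * set$bx^2)
  beta <- sum(w * set$bx * set$by) / sxx
  se_fixed <- sqrt(1 / sxx)
  Q <- sum(w * (set$by - beta * set$bx)^2)
  if (L >= 2 && model == "multiplicative_random") {
    se <- se_fixed * max(1, sqrt(Q / (L - 1)))
  } else {
    se <- se_fixed
  }
  Q_df <- if (L >= 2) L - 1 else NA_real_
  Q_p <- if (L >= 2) pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_
  mr_row("ivw", beta, se, p_from_z(beta / se), L,
         Q = if (L >= 2) Q else NA_real_, Q_df = Q_df, Q_p = Q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights \eqn{1/se_y^2}, after orienting every exposure beta to
#' be non-negative (flipping the outcome beta with it; estimates are
#' invariant to per-variant re-orientation). The intercept estimates the
#' average directional pleiotropy; the slope is the pleiotropy-adjusted
#' causal effect. Standard errors use a multiplicative random-effects floor
#' (residual sigma not allowed below 1) and t reference with L - 2 df.
#'
#' @param set Harmonized set with at least 3 variants.
#' @return One-row `mr_result` tibble including `egger_intercept` columns.
#' @export
mr_egger <- function(set) {
  set <- as_hset(set)
  L <- nrow(set)
  if (L < 3) {
    abort("MR-Egger needs at least 3 variants.",
          class = "triomr_validation_error")
  }
  flip <- sign(set$bx)
  flip[flip == 0] <- 1
  bx <- set$bx * flip
  by <- set$by * flip
  w <- 1 / set$se_y^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  infl <- 1 / min(1, sm$sigma)  # floor residual sd at 1
  slope <- coef(fit)["bx"]
  slope_se <- sm$coefficients["bx", 2] * infl
  int <- coef(fit)["(Intercept)"]
  int_se <- sm$coefficients["(Intercept)", 2] * infl
  Q <- sum(w * residuals(fit)^2)
  mr_row("mr_egger",
         unname(slope), unname(slope_se),
         p_from_t(slope / slope_se, L - 2), L,
         Q = Q, Q_df = L - 2, Q_p = pchisq(Q, L - 2, lower.tail = FALSE),
         egger_intercept = unname(int), egger_intercept_se = unname(int_se),
         egger_intercept_p = p_from_t(unname(int / int_se), L - 2))
}

# internal: weighted median of values v with weights w (cumulative-weight
# interpolation at probability 0.5)
weighted_median_core <- function(v, w) {
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(v[1])
  if (cw[length(cw)] < 0.5) return(v[length(v)])
  k <- max(which(cw < 0.5))
  v[k] + (v[k + 1] - v[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

#' Weighted median two-sample MR
#'
#' The weighted median of the per-variant Wald ratios, with inverse-variance
#' weights \eqn{b_x^2 / se_y^2}: consistent when at least half the weight
#' comes from valid instruments. The standard error is estimated by a seeded
#' parametric bootstrap (resampling `bx` and `by` from their standard errors).
#'
#' @param set Harmonized set with at least 3 variants.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed for the bootstrap (mandatory for reproducibility).
#' @return One-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(set, n_boot = 5000, seed = 1) {
  set <- as_hset(set)
  L <- nrow(set)
  if (L < 3) {
    abort("Weighted median needs at least 3 variants.",
          class = "triomr_validation_error")
  }
  ratios <- set$by / set$bx
  w <- set$bx^2 / set$se_y^2
  beta <- weighted_median_core(ratios, w)
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(L, set$bx, set$se_x)
    by <- rnorm(L, set$by, set$se_y)
    weighted_median_core(by / bx, bx^2 / set$se_y^2)
  }, numeric(1))
  se <- sd(boots)
  mr_row("weighted_median", beta, se, p_from_z(beta / se), L)
}

# internal: kernel-density mode of ratios with weights and bandwidth h
density_mode <- function(v, w, h) {
  dens <- density(v, weights = w / sum(w), bw = h, n = 2048)
  dens$x[which.max(dens$y)]
}

mode_bandwidth <- function(v, phi) {
  s <- 0.9 * min(sd(v), mad(v)) * length(v)^(-1 / 5)
  max(1e-8, phi * s)
}

#' Mode-based two-sample MR (simple and weighted mode)
#'
#' The mode of the smoothed empirical density of per-variant Wald ratios:
#' consistent when the largest group of instruments sharing the same ratio is
#' valid (ZEMPA). The Gaussian kernel bandwidth is `phi` times the modified
#' Silverman rule \eqn{0.9\,\min(sd, mad)\,L^{-1/5}} on the ratios. The
#' simple mode weighs ratios equally; the weighted mode uses
#' \eqn{b_x^2 / se_y^2}. The standard error is the median absolute deviation
#' of a seeded parametric bootstrap; p uses a t reference with L - 1 df.
#'
#' @param set Harmonized set with at least 3 variants.
#' @param weighting `"simple"` or `"weighted"`.
#' @param phi Bandwidth multiplier (default 1; must be > 0).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row `mr_result` tibble.
#' @export
mr_mode <- function(set, weighting = c("simple", "weighted"), phi = 1,
                    n_boot = 5000, seed = 1) {
  weighting <- match.arg(weighting)
  set <- as_hset(set)
  L <- nrow(set)
  if (L < 3) {
    abort("Mode estimators need at least 3 variants.",
          class = "triomr_validation_error")
  }
  if (phi <= 0) abort("`phi` must be > 0.", class = "triomr_validation_error")
  ratios <- set$by / set$bx
  wts <- if (weighting == "weighted") set$bx^2 / set$se_y^2 else rep(1, L)
  beta <- density_mode(ratios, wts, mode_bandwidth(ratios, phi))
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(L, set$bx, set$se_x)
    by <- rnorm(L, set$by, set$se_y)
    r <- by / bx
    wb <- if (weighting == "weighted") bx^2 / set$se_y^2 else rep(1, L)
    density_mode(r, wb, mode_bandwidth(r, phi))
  }, numeric(1))
  se <- mad(boots)
  mr_row(paste0(weighting, "_mode"), beta, se,
         p_from_t(beta / se, L - 1), L)
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum w_j (b_j - \bar b_w)^2} with inverse-variance weights,
#' referred to a chi-squared distribution with L - 1 df.
#'
#' @param estimates Numeric vector of estimates (length >= 2).
#' @param ses Their standard errors (all > 0).
#' @return One-row tibble `Q`, `df`, `p`.
#' @export
cochrans_q <- function(estimates, ses) {
  if (length(estimates) < 2) {
    abort("Need at least two estimates.", class = "triomr_validation_error")
  }
  check_positive_se(ses, "ses")
  w <- 1 / ses^2
  b_bar <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - b_bar)^2)
  df <- length(estimates) - 1
  tibble::tibble(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Two-estimate heterogeneity test
#'
#' Cochran's Q with exactly two estimates (1 df); used to compare the
#' consumer and non-consumer stratified MR estimates.
#'
#' @param b1,se1,b2,se2 The two estimates and their standard errors.
#' @return One-row tibble `Q`, `df`, `p`.
#' @export
heterogeneity_test <- function(b1, se1, b2, se2) {
  cochrans_q(c(b1, b2), c(se1, se2))
}

#' Multivariable IVW MR
#'
#' Weighted least squares of outcome betas on the matrix of exposure betas
#' (no intercept), weights \eqn{1/se_y^2}; each coefficient is the direct
#' causal effect of that exposure conditional on the others. With a single
#' exposure this reduces exactly to [mr_ivw()]. Standard errors carry the
#' same multiplicative random-effects floor as the IVW model; p uses a t
#' reference with L - K df.
#'
#' @param exposure_matrix L x K matrix (or data frame) of SNP-exposure betas,
#'   columns named by exposure; the pooled instrument set must be harmonized
#'   to a common effect allele per variant beforehand.
#' @param by SNP-outcome betas (length L).
#' @param se_y SNP-outcome standard errors.
#' @return `mr_result` tibble with one row per exposure (`method =
#'   "mvmr_ivw"`, `term` column holds the exposure name).
#' @export
mr_mvmr_ivw <- function(exposure_matrix, by, se_y) {
  X <- as.matrix(exposure_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure_", seq_len(ncol(X)))
  L <- nrow(X); K <- ncol(X)
  if (L <= K) {
    abort("Need more variants than exposures.",
          class = "triomr_validation_error")
  }
  check_positive_se(se_y, "se_y")
  if (qr(X)$rank < K) {
    abort("Exposure beta matrix is rank deficient.",
          class = "triomr_collinearity_error")
  }
  w <- 1 / se_y^2
  XtWX <- crossprod(X * w, X)
  beta <- unname(drop(solve(XtWX, crossprod(X * w, by))))
  resid <- by - drop(X %*% beta)
  Q <- sum(w * resid^2)
  sigma2 <- max(1, Q / (L - K))  # multiplicative random effects, floored
  ses <- unname(sqrt(diag(solve(XtWX)) * sigma2))
  out <- mr_row("mvmr_ivw", beta, ses, p_from_t(beta / ses, L - K), L,
                Q = Q, Q_df = L - K,
                Q_p = pchisq(Q, L - K, lower.tail = FALSE))
  out$term <- colnames(X)
  dplyr::relocate(out, "term")
}

#' @export
tidy.mr_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(n_methods = nrow(x), n_snps = max(x$n_snps))
}
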