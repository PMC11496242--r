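test_that("GRM has the expected structure", {
  set.seed(20)
  n <- 60; m <- 3000
  dos <- matrix(rbinom(n * m, 2, 0.3), n, dimnames = list(NULL, paste0("v", 1:m)))
  dos[2, ] <- dos[1, ] # duplicate individuals
  K <- build_grm(dos)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_true(isSymmetric(unclass(K)))
  # unrelated pairs: off-diagonals centre on -1/(n-1) (in-sample allele
  # frequencies force each standardized column to sum to zero) with
  # per-entry sd ~ sqrt(1/m)
  off <- K[lower.tri(K)][-1] # drop the duplicated pair
  expect_lt(abs(mean(off) + 1 / (n - 1)), 0.01)
  expect_lt(abs(sd(off) - sqrt(1 / m)), 0.01)
  # diagonal ~ 1 for standardized genotypes
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
})

test_that("exclusion windows remove exactly the covered variants", {
  set.seed(21)
  dos <- matrix(rbinom(200 * 5, 2, 0.4), 200,
                dimnames = list(NULL, paste0("v", 1:5)))
  meta <- tibble::tibble(id = paste0("v", 1:5), chrom = 1L,
                         pos = c(1e6, 5e6, 9e6, 13e6, 17e6))
  K_all <- build_grm(dos)
  K_ex <- build_grm(dos, meta,
                    exclusions = tibble::tibble(chrom = 1L, start = 4e6,
                                                end = 6e6))
  expect_equal(attr(K_all, "m_variants") - attr(K_ex, "m_variants"), 1L)
  expect_equal(attr(K_ex, "excluded"), "v2")
  expect_error(build_grm(dos, meta,
                         exclusions = tibble::tibble(chrom = 1L, start = 0,
                                                     end = 2e7)),
               class = "triomr_validation_error")
  # helper builds 1 Mb flanks
  win <- instrument_exclusion_windows(meta[1, ])
  expect_equal(c(win$start, win$end), c(0, 2e6))
})

test_that("mixed model with identity GRM reproduces OLS", {
  set.seed(22)
  n <- 150
  y <- rnorm(n); g <- rnorm(n); o <- 0.5 * g + rnorm(n, 0, 0.9)
  ols <- conditional_mr(y, g, offspring = o)
  mm <- conditional_mr(y, g, offspring = o,
                       grm = structure(diag(n), class = "grm"))
  expect_equal(mm$beta, ols$beta, tolerance = 1e-6)
  expect_equal(mm$se, ols$se, tolerance = 1e-6)
})

test_that("REML absorbs genetic relatedness induced by duplicated families", {
  # pairs of identical individuals share a polygenic background; REML with
  # the true block GRM should not underestimate uncertainty vs naive OLS
  set.seed(23)
  n2 <- 80
  u <- rep(rnorm(n2), each = 2) # shared random effect within pairs
  g <- rnorm(2 * n2)
  y <- 0.3 * g + u + rnorm(2 * n2, 0, 0.5)
  K <- kronecker(diag(n2), matrix(1, 2, 2))
  mm <- conditional_mr(y, g, grm = structure(K, class = "grm"))
  expect_within_se(mm$beta[1], 0.3, mm$se[1])
  expect_gt(mm$se[1], 0) # well-defined
})

test_that("conditional duo MR blocks offspring-mediated pleiotropy", {
  cc <- quick_cohort(n = 20000, seed = 24, beta_causal = 0,
                     delta_offspring = 0.5, confounder_exposure = 0,
                     confounder_outcome = 0)
  nd <- cc$trios$phenos$nd
  uncond <- conditional_mr(nd, cc$pgs_m)
  cond <- conditional_mr(nd, cc$pgs_m, offspring = cc$pgs_o)
  expect_gt(abs(uncond$beta) / uncond$se, 2) # biased
  expect_within_se(cond$beta, 0, cond$se)    # blocked
  expect_lt(abs(cond$beta), 0.1 * abs(uncond$beta)) # >90% bias reduction
})

test_that("trio MR recovers the causal path and nulls the paternal control", {
  cc <- quick_cohort(n = 20000, seed = 25, beta_causal = 0.2,
                     delta_offspring = 0, delta_paternal = 0)
  ph <- cc$trios$phenos
  est <- conditional_mr(ph$nd, cc$pgs_m, offspring = cc$trios$dosage_o,
                        pgs_f = cc$pgs_f)
  # PGS-scale truth: beta_causal times the exposure-PGS slope under the
  # same conditioning set
  bgx <- coef(lm(ph$coffee_wk15 ~ cc$pgs_m + cc$trios$dosage_o + cc$pgs_f))[2]
  expect_within_se(est$beta[1], 0.2 * bgx, est$se[1])
  expect_within_se(est$beta[2], 0, est$se[2]) # paternal negative control
  # rescaling to cups/day recovers beta_causal
  scaled <- wald_scale(est$beta[1], est$se[1], bgx)
  expect_within_se(scaled$beta, 0.2, scaled$se)
})

test_that("wald_scale converts PGS units to exposure units", {
  ws <- wald_scale(0.05, 0.01, 0.1)
  expect_equal(ws$beta, 0.5)
  expect_equal(ws$se, 0.1)
  expect_equal(wald_scale(0, 0.01, 0.1)$beta, 0)
  expect_equal(wald_scale(0.1, 0.01, 0.2)$beta,
               wald_scale(0.2, 0.01, 0.4)$beta) # scale invariance
  so <- wald_scale(0.05, 0.01, 0.1, se_exp = 0.02, second_order = TRUE)
  expect_gt(so$se, ws$se)
  expect_error(wald_scale(0.05, 0.01, 0), class = "triomr_validation_error")
})

test_that("offspring block collinear with the maternal score errors out", {
  set.seed(26)
  g <- rnorm(100); y <- rnorm(100)
  expect_error(conditional_mr(y, g, offspring = 2 * g),
               class = "triomr_collinearity_error")
})

test_that("identical strata give zero heterogeneity", {
  set.seed(27)
  n <- 400
  g <- rnorm(n); y <- 0.2 * g + rnorm(n)
  flag <- rep(c(TRUE, FALSE), n / 2)
  # duplicate the same data into both strata
  gx <- gxe_stratified(c(y, y), c(g, g),
                       strata_flag = c(rep(TRUE, n), rep(FALSE, n)))
  expect_equal(gx$heterogeneity$Q, 0, tolerance = 1e-12)
  expect_equal(gx$heterogeneity$p, 1)
  expect_error(gxe_stratified(y, g, strata_flag = rep(TRUE, n)),
               class = "triomr_validation_error")
})
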