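test_that("Wald ratio and its orientation behave as ratios must", {
  r <- mr_wald_ratio(bx = 0.1, se_x = 0.001, by = 0.05, se_y = 0.01)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(mr_wald_ratio(0.1, 0.001, 0, 0.01)$beta, 0)
  expect_equal(mr_wald_ratio(-0.1, 0.001, 0.05, 0.01)$beta, -0.5)
  so <- mr_wald_ratio(0.1, 0.02, 0.05, 0.01, second_order = TRUE)
  expect_gt(so$se, r$se)
  expect_error(mr_wald_ratio(0, 0.001, 0.05, 0.01),
               class = "triomr_validation_error")
})

test_that("IVW matches the worked example and reduces to Wald at L = 1", {
  h <- toy_hset(bx = c(0.1, 0.2), by = c(0.05, 0.08),
                se_y = c(0.01, 0.02))
  res <- mr_ivw(h, model = "fixed")
  expect_equal(res$beta, 0.45, tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / 200), tolerance = 1e-12)

  h1 <- toy_hset(bx = 0.1, by = 0.05, se_y = 0.01)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(0.1, 0.01, 0.05, 0.01)$beta)
  expect_equal(mr_ivw(h1)$se, mr_wald_ratio(0.1, 0.01, 0.05, 0.01)$se)

  # exact proportionality: beta = c and Q = 0
  hp <- toy_hset(bx = c(0.1, 0.2, 0.3), by = 0.7 * c(0.1, 0.2, 0.3))
  resp <- mr_ivw(hp)
  expect_equal(resp$beta, 0.7, tolerance = 1e-12)
  expect_equal(resp$Q, 0, tolerance = 1e-12)
})

test_that("IVW equals the weighted regression-through-origin oracle", {
  for (seed in 1:100) {
    h <- random_hset(sample(3:15, 1), seed)
    ours <- mr_ivw(h, model = "fixed")
    oracle <- lm(by ~ 0 + bx, data = h, weights = 1 / h$se_y^2)
    expect_equal(ours$beta, unname(coef(oracle)), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact linear construction", {
  h <- toy_hset(bx = c(0.1, 0.2, 0.3), by = 0.01 + 0.5 * c(0.1, 0.2, 0.3))
  res <- mr_egger(h)
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_equal(res$egger_intercept, 0.01, tolerance = 1e-10)

  # proportional data: intercept exactly 0, slope equals IVW
  hp <- toy_hset(bx = c(0.1, 0.2, 0.3), by = 0.4 * c(0.1, 0.2, 0.3))
  rp <- mr_egger(hp)
  expect_equal(rp$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(rp$beta, mr_ivw(hp)$beta, tolerance = 1e-10)

  # invariance under re-orientation of one variant
  h2 <- h
  h2$bx[2] <- -h2$bx[2]
  h2$by[2] <- -h2$by[2]
  r2 <- mr_egger(h2)
  expect_equal(r2$beta, res$beta, tolerance = 1e-12)
  expect_equal(r2$egger_intercept, res$egger_intercept, tolerance = 1e-12)

  expect_error(mr_egger(toy_hset(bx = c(0.1, 0.2), by = c(0.1, 0.2))),
               class = "triomr_validation_error")
})

test_that("weighted median interpolates cumulative weights at one half", {
  h <- toy_hset(bx = c(1, 1, 1), by = c(0.2, 0.5, 0.9))
  res <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(res$beta, 0.5, tolerance = 1e-12)

  # all ratios equal c -> c
  hc <- toy_hset(bx = c(0.1, 0.2, 0.4), by = 0.3 * c(0.1, 0.2, 0.4),
                 se_y = 0.01)
  expect_equal(mr_weighted_median(hc, n_boot = 100, seed = 1)$beta, 0.3)

  # deterministic bootstrap under a fixed seed
  a <- mr_weighted_median(h, n_boot = 300, seed = 7)
  b <- mr_weighted_median(h, n_boot = 300, seed = 7)
  expect_identical(a$se, b$se)

  # estimate lies within the range of the Wald ratios
  for (seed in 1:20) {
    hr <- random_hset(7, seed + 100)
    est <- mr_weighted_median(hr, n_boot = 50, seed = 1)$beta
    ratios <- hr$by / hr$bx
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
  }
})

test_that("weighted median agrees with an independent cumulative-weight oracle", {
  oracle <- function(ratios, w) {
    ord <- order(ratios)
    r <- ratios[ord]; w <- w[ord]
    p <- (cumsum(w) - w / 2) / sum(w)
    if (p[1] >= 0.5) return(r[1])
    k <- max(which(p < 0.5))
    stats::approx(p[c(k, k + 1)], r[c(k, k + 1)], xout = 0.5)$y
  }
  for (seed in 1:50) {
    h <- random_hset(sample(3:12, 1), seed + 500)
    est <- mr_weighted_median(h, n_boot = 10, seed = 1)$beta
    expect_equal(est, oracle(h$by / h$bx, h$bx^2 / h$se_y^2),
                 tolerance = 1e-10)
  }
})

test_that("mode estimators find the kernel-density maximum", {
  h <- toy_hset(bx = c(1, 1, 1, 1), by = c(0.5, 0.5, 0.5, 0.9))
  res <- mr_mode(h, "simple", n_boot = 100, seed = 1)
  expect_equal(res$beta, 0.5, tolerance = 0.02)

  # all ratios equal -> that ratio
  hc <- toy_hset(bx = c(0.1, 0.2, 0.4), by = 0.3 * c(0.1, 0.2, 0.4))
  expect_equal(mr_mode(hc, "simple", n_boot = 50, seed = 1)$beta, 0.3,
               tolerance = 1e-6)

  # a dominant weight pulls the weighted mode toward its ratio
  hw <- toy_hset(bx = c(1, 1, 1, 1), by = c(0.2, 0.25, 0.3, 0.8),
                 se_y = c(0.2, 0.2, 0.2, 0.005))
  mw <- mr_mode(hw, "weighted", n_boot = 50, seed = 1)$beta
  ms <- mr_mode(hw, "simple", n_boot = 50, seed = 1)$beta
  expect_gt(mw, ms)
  expect_lt(abs(mw - 0.8), 0.1)

  # fine-grid density-maximum oracle
  grid_mode <- function(r, w, h_bw) {
    grid <- seq(min(r) - 3 * h_bw, max(r) + 3 * h_bw, length.out = 20000)
    dens <- vapply(grid, function(g) {
      sum(w / sum(w) * stats::dnorm((g - r) / h_bw))
    }, numeric(1))
    grid[which.max(dens)]
  }
  for (seed in 1:10) {
    hr <- random_hset(9, seed + 900)
    r <- hr$by / hr$bx
    w <- hr$bx^2 / hr$se_y^2
    bw <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
    est <- mr_mode(hr, "weighted", n_boot = 10, seed = 1)$beta
    expect_equal(est, grid_mode(r, w, bw), tolerance = max(0.02, bw / 5))
  }

  expect_error(mr_mode(h, phi = 0), class = "triomr_validation_error")
})

test_that("Cochran's Q matches hand computation and scales correctly", {
  q0 <- cochrans_q(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  q1 <- cochrans_q(c(0, 1), c(1, 1))
  expect_equal(q1$Q, 0.5, tolerance = 1e-12)
  expect_equal(q1$p, pchisq(0.5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(q1$p, 4), 0.4795)

  # scaling all ses by k divides Q by k^2
  qa <- cochrans_q(c(0.1, 0.4, 0.3), c(0.05, 0.1, 0.2))
  qb <- cochrans_q(c(0.1, 0.4, 0.3), 2 * c(0.05, 0.1, 0.2))
  expect_equal(qb$Q, qa$Q / 4, tolerance = 1e-12)
  expect_error(cochrans_q(0.1, 0.1), class = "triomr_validation_error")
})

test_that("two-estimate heterogeneity reproduces the stratified comparison", {
  het <- heterogeneity_test(0.153, 0.071, 0.107, 0.134)
  expect_equal(het$Q, 0.092, tolerance = 0.005)
  expect_equal(het$p, 0.762, tolerance = 0.005)
  expect_equal(heterogeneity_test(0.2, 0.1, 0.2, 0.3)$p, 1)
  # p decreases as the gap grows at fixed ses
  ps <- vapply(seq(0, 1, by = 0.2), function(d) {
    heterogeneity_test(0.1, 0.1, 0.1 + d, 0.1)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 1e-12))
})

test_that("multivariable IVW reduces to IVW and solves exact constructions", {
  h <- random_hset(10, 3)
  uni <- mr_mvmr_ivw(matrix(h$bx, ncol = 1, dimnames = list(NULL, "x")),
                     h$by, h$se_y)
  ivw <- mr_ivw(h)
  expect_equal(uni$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(uni$se, ivw$se, tolerance = 1e-12)

  set.seed(30)
  X <- cbind(x1 = runif(12, 0.05, 0.3), x2 = runif(12, 0.05, 0.3))
  by <- 0.3 * X[, "x1"] + 0 * X[, "x2"]
  res <- mr_mvmr_ivw(X, by, rep(0.01, 12))
  expect_equal(res$beta, c(0.3, 0), tolerance = 1e-10)

  # permutation invariance
  idx <- sample(12)
  res2 <- mr_mvmr_ivw(X[idx, ], by[idx], rep(0.01, 12))
  expect_equal(res2$beta, res$beta, tolerance = 1e-12)

  expect_error(mr_mvmr_ivw(cbind(X[, 1], 2 * X[, 1]), by, rep(0.01, 12)),
               class = "triomr_collinearity_error")
  expect_error(mr_mvmr_ivw(X[1:2, ], by[1:2], rep(0.01, 2)),
               class = "triomr_validation_error")
})

test_that("all estimators are invariant to joint sign flips of a variant", {
  h <- random_hset(8, 77)
  h2 <- h
  h2$bx[3] <- -h2$bx[3]
  h2$by[3] <- -h2$by[3]
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mr_mode(h2, "weighted", n_boot = 10, seed = 1)$beta,
               mr_mode(h, "weighted", n_boot = 10, seed = 1)$beta,
               tolerance = 1e-9)
})
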