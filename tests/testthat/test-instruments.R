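test_that("polygenic scores follow the orientation rules", {
  d <- matrix(c(0, 1, 2), 1, dimnames = list(NULL, c("v1", "v2", "v3")))
  w <- tibble::tibble(id = c("v1", "v2", "v3"), effect_allele = "A",
                      weight = c(0.1, 0.1, 0.1))
  expect_equal(build_pgs(d, w), 0.3)

  # negative weight at dosage 2 contributes 2 - 2 = 0 unweighted
  w2 <- w
  w2$weight[3] <- -0.1
  expect_equal(build_pgs(d, w2, mode = "unweighted"), 0 + 1 + 0)
  expect_equal(build_pgs(d, w2), 0.1 - 0.2)

  expect_equal(build_pgs(d * 0, w), 0)

  # linearity of the weighted score in the weights
  set.seed(14)
  dm <- matrix(rbinom(50 * 3, 2, 0.3), 50, dimnames = list(NULL, w$id))
  wa <- w; wa$weight <- runif(3)
  wb <- w; wb$weight <- runif(3)
  wsum <- w; wsum$weight <- wa$weight + wb$weight
  expect_equal(build_pgs(dm, wsum),
               build_pgs(dm, wa) + build_pgs(dm, wb), tolerance = 1e-12)

  # allele bookkeeping: dosages stored for the other allele are flipped
  meta <- tibble::tibble(id = w$id, effect_allele = c("G", "A", "A"))
  flipped <- build_pgs(d, w, variants = meta)
  expect_equal(flipped, (2 - 0) * 0.1 + 1 * 0.1 + 2 * 0.1)

  expect_error(build_pgs(d, dplyr::mutate(w, id = c("v1", "v2", "zz"))),
               class = "triomr_missing_variant")
})

test_that("instrument benchmarking recovers the PGS-exposure slope", {
  cc <- quick_cohort(n = 20000, seed = 15, instrument_effects = 0.1)
  bench <- benchmark_instrument(cc$pgs_m, cc$trios$phenos$coffee_wk15)
  # truth: attenuated by the hurdle (consumer fraction) and truncation;
  # compare against the oracle slope from the same model family
  oracle <- coef(lm(cc$trios$phenos$coffee_wk15 ~ cc$pgs_m))[2]
  expect_within_se(bench$beta_gx, oracle, bench$se, k = 1e-6) # same fit
  expect_equal(bench$F, (bench$beta_gx / bench$se)^2, tolerance = 1e-12)
  expect_gt(bench$F, 10)
  expect_error(benchmark_instrument(rep(1, 100), rnorm(100)),
               class = "triomr_degenerate_instrument")
})

test_that("I2GX matches hand computation and truncates at zero", {
  # Q = 200 on the stated example: I2 = (200 - 2)/200
  expect_equal(i2_gx(c(0.1, 0.2, 0.3), rep(0.01, 3)), 0.99)
  expect_equal(i2_gx(c(0.2, 0.2, 0.2), rep(0.01, 3)), 0)
  # inflating the ses decreases I2
  expect_lt(i2_gx(c(0.1, 0.2, 0.3), rep(0.1, 3)),
            i2_gx(c(0.1, 0.2, 0.3), rep(0.01, 3)))
  expect_error(i2_gx(c(0.1, 0.2), c(0.01, 0)), class = "triomr_invalid_se")
})

test_that("harmonization flips, removes palindromes, logs removals", {
  exposure <- tibble::tibble(
    id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "A", "A", "C"),
    other_allele = c("G", "T", "G", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4), se = 0.01
  )
  outcome <- tibble::tibble(
    id = c("rs1", "rs2", "rs3", "rs5"),
    effect_allele = c("G", "A", "C", "A"),
    other_allele = c("A", "T", "T", "G"),
    beta = c(-0.05, 0.1, 0.2, 0.3), se = 0.02
  )
  h <- harmonize_variants(exposure, outcome)
  expect_equal(h$id, "rs1")
  expect_equal(h$by, 0.05) # swapped alleles: sign flipped
  log <- audit_log(h)
  expect_setequal(log$reason[log$id == "rs2"], "palindromic")
  expect_setequal(log$reason[log$id == "rs3"], "allele_mismatch")
  expect_true(all(c("rs4", "rs5") %in% log$id[log$reason == "unmatched"]))

  # idempotence: re-harmonizing the aligned pair changes nothing
  exp2 <- tibble::tibble(id = h$id, effect_allele = h$effect_allele,
                         other_allele = h$other_allele, beta = h$bx,
                         se = h$se_x)
  out2 <- tibble::tibble(id = h$id, effect_allele = h$effect_allele,
                         other_allele = h$other_allele, beta = h$by,
                         se = h$se_y)
  h2 <- harmonize_variants(exp2, out2)
  expect_equal(h2$bx, h$bx)
  expect_equal(h2$by, h$by)

  expect_error(harmonize_variants(exposure[c(1, 1), ], outcome),
               class = "triomr_duplicate_variant")
})

test_that("greedy clumping keeps the best variant per LD block", {
  rows <- tibble::tibble(id = c("a", "b"), p = c(1e-10, 1e-9))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(rows$id, rows$id))
  expect_equal(clump_variants(rows, ld)$id, "a")

  # independent variants all survive
  ld0 <- diag(2); dimnames(ld0) <- list(rows$id, rows$id)
  expect_equal(nrow(clump_variants(rows, ld0)), 2L)

  # p threshold applied before clumping
  rows2 <- tibble::tibble(id = c("a", "b"), p = c(1e-9, 1e-7))
  expect_equal(clump_variants(rows2, ld0)$id, "a")

  # row order never matters; p ties break by id
  rows3 <- tibble::tibble(id = c("d", "c", "b"), p = c(1e-9, 1e-9, 1e-10))
  ld3 <- diag(3) + 0.5 - diag(0.5, 3)
  dimnames(ld3) <- list(rows3$id, rows3$id)
  r1 <- clump_variants(rows3, ld3)
  r2 <- clump_variants(rows3[3:1, ], ld3)
  expect_equal(r1$id, r2$id)
  expect_equal(r1$id, "b")
})

test_that("collider screen flags hurdle-loaded variants and respects alpha", {
  cc <- quick_cohort(n = 20000, seed = 16,
                     hurdle = list(base_rate = 0.6,
                                   snp_loadings = c(0.6, rep(0, 7))))
  scr <- collider_screen(cc$trios, cc$trios$phenos$consumer_flag)
  expect_true(scr$excluded[1]) # the loaded variant is caught
  # alpha = 0 excludes nothing
  scr0 <- collider_screen(cc$trios, cc$trios$phenos$consumer_flag, alpha = 0)
  expect_false(any(scr0$excluded))
  # logistic link gives the same qualitative call on the loaded variant
  scr_log <- collider_screen(cc$trios, cc$trios$phenos$consumer_flag,
                             link = "logistic")
  expect_true(scr_log$excluded[1])
  expect_error(collider_screen(cc$trios, rep(TRUE, 20000)),
               class = "triomr_degenerate_outcome")
})
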