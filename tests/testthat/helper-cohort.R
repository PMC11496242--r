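# shared fixtures, built in code

# simulate a cohort and return it together with the three true-weight PGS
quick_cohort <- function(n = 2000, seed = 1, ...) {
  cfg <- sim_config(n = n, m = 8, seed = seed, ...)
  tr <- simulate_phenotypes(simulate_trios(cfg))
  wt <- tibble::tibble(id = tr$variants$id,
                       effect_allele = tr$variants$effect_allele,
                       weight = cfg$instrument_effects)
  list(cfg = cfg, trios = tr, weights = wt,
       pgs_m = build_pgs(tr$dosage_m, wt),
       pgs_f = build_pgs(tr$dosage_f, wt),
       pgs_o = build_pgs(tr$dosage_o, wt))
}

# small harmonized set with exact allele bookkeeping
toy_hset <- function(bx, by, se_x = 0.01, se_y = 0.01) {
  tibble::tibble(
    id = sprintf("v%02d", seq_along(bx)),
    effect_allele = "A", other_allele = "G",
    bx = bx, se_x = rep_len(se_x, length(bx)),
    by = by, se_y = rep_len(se_y, length(bx))
  )
}

# random harmonized set for property checks
random_hset <- function(L, seed) {
  set.seed(seed)
  toy_hset(bx = runif(L, 0.05, 0.3), by = rnorm(L, 0.1, 0.05),
           se_x = runif(L, 0.005, 0.05), se_y = runif(L, 0.005, 0.05))
}

expect_within_se <- function(est, truth, se, k = 2) {
  expect_lt(abs(est - truth), k * se)
}
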