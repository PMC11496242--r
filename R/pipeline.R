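#' Pipeline configuration
#'
#' Bundles the simulation config, stage toggles, estimator options and
#' thresholds for [run_pipeline()]. Every stochastic stage draws its seed
#' deterministically from `seed`, so a config fully determines the output.
#'
#' @param seed Master integer seed.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param stages Character vector of stages to run, any of
#'   `"observational"`, `"duo"`, `"trio"`, `"partition"`, `"two_sample"`,
#'   `"mvmr"`, `"gxe"` (simulation and instrument building always run).
#' @param ivw_model IVW variance model (see [mr_ivw()]).
#' @param phi Mode-estimator bandwidth multiplier.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param alpha_total Family-wise alpha for the effective-tests threshold.
#' @param variance_target Variance fraction for the effective-tests PCA.
#' @param collider_alpha Exclusion threshold for the collider screen.
#' @param n_null_outcomes Extra correlated null outcomes simulated to form
#'   the outcome battery the effective-tests PCA runs on.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed = seed),
                            stages = c("observational", "duo", "trio",
                                       "partition", "two_sample", "mvmr",
                                       "gxe"),
                            ivw_model = "multiplicative_random",
                            phi = 1, n_boot = 1000,
                            alpha_total = 0.05, variance_target = 0.8,
                            collider_alpha = 0.05, n_null_outcomes = 4) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, stages = stages,
                 ivw_model = ivw_model, phi = phi, n_boot = n_boot,
                 alpha_total = alpha_total, variance_target = variance_target,
                 collider_alpha = collider_alpha,
                 n_null_outcomes = n_null_outcomes),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "triomr_pipeline_error")
  })
}

#' Run the full family-based MR pipeline on a simulated cohort
#'
#' Executes, in order: trio simulation, phenotype derivation, instrument
#' construction and benchmarking, observational models with the paternal
#' negative control, duo and trio conditional MR, maternal/offspring
#' per-variant GWAS with direct-effect partitioning, two-sample MR with
#' sensitivity estimators, multivariable MR (coffee conditional on smoking
#' and alcohol), and gene-by-environment stratified MR after the collider
#' screen. A summary table flags results against the PCA effective-tests
#' threshold. When `out_dir` is given every table is written as TSV with a
#' provenance header plus a run log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return An `mr_pipeline_report`: named list of result tibbles plus the
#'   cohort and config.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "triomr_invalid_config")
  }
  on <- function(stage) stage %in% config$stages
  res <- list()

  trios <- run_stage("simulate", {
    simulate_phenotypes(simulate_trios(config$sim))
  })
  ph <- trios$phenos

  inst <- run_stage("instruments", {
    weights <- tibble::tibble(
      id = trios$variants$id,
      effect_allele = trios$variants$effect_allele,
      weight = config$sim$instrument_effects
    )
    pgs_m <- build_pgs(trios$dosage_m, weights)
    pgs_f <- build_pgs(trios$dosage_f, weights)
    pgs_o <- build_pgs(trios$dosage_o, weights)
    covs <- ph[, c("birth_year", "age_m", "age_f")]
    bench <- benchmark_instrument(pgs_m, ph$coffee_wk15, covs)
    exp_gwas <- per_snp_gwas(trios, outcome = "coffee_wk15", who = "maternal")
    diag <- dplyr::mutate(bench,
                          i2_gx = i2_gx(exp_gwas$beta, exp_gwas$se))
    list(weights = weights, pgs_m = pgs_m, pgs_f = pgs_f, pgs_o = pgs_o,
         exposure_gwas = exp_gwas, diagnostics = diag, covariates = covs)
  })
  res$instrument_diagnostics <- inst$diagnostics
  res$exposure_gwas <- inst$exposure_gwas

  if (on("observational")) {
    res$observational <- run_stage("observational", {
      dplyr::bind_rows(
        fit_observational(ph, "coffee_wk15", "nd", "unadjusted"),
        fit_observational(ph, "coffee_wk15", "nd", "adjusted"),
        fit_observational(ph, "coffee_wk15", "nd", "intrauterine"),
        dplyr::mutate(fit_observational(ph, "coffee_f", "nd", "unadjusted"),
                      term = "coffee_f (negative control)")
      )
    })
  }

  if (on("duo")) {
    res$duo_mr <- run_stage("duo", {
      dplyr::bind_rows(
        dplyr::mutate(
          conditional_mr(ph$nd, inst$pgs_m, offspring = trios$dosage_o,
                         covariates = inst$covariates),
          model = "duo_conditional"),
        dplyr::mutate(
          conditional_mr(ph$nd, inst$pgs_m, covariates = inst$covariates),
          model = "duo_unconditional")
      )
    })
  }

  if (on("trio")) {
    res$trio_mr <- run_stage("trio", {
      dplyr::mutate(
        conditional_mr(ph$nd, inst$pgs_m, offspring = trios$dosage_o,
                       pgs_f = inst$pgs_f, covariates = inst$covariates),
        model = "trio_conditional")
    })
  }

  need_partition <- on("partition") || on("two_sample") || on("mvmr")
  if (need_partition) {
    part <- run_stage("partition", {
      gm <- per_snp_gwas(trios, outcome = "nd", who = "maternal")
      go <- per_snp_gwas(trios, outcome = "nd", who = "offspring")
      # duo GWAS of the same outcome in fully shared families: the error
      # correlation is the transmission coefficient (0.5) times the (unit)
      # phenotypic correlation between the two analysed traits
      r <- overlap_correlation(gm$n[1], go$n[1], min(gm$n[1], go$n[1]), 0.5)
      dplyr::bind_cols(
        gm[, c("id", "effect_allele", "other_allele", "eaf")],
        partition_maternal_fetal(gm$beta, gm$se, go$beta, go$se, r)
      )
    })
    if (on("partition")) res$partitioned_effects <- part
  }

  if (on("two_sample")) {
    res$two_sample_mr <- run_stage("two_sample", {
      hset <- tibble::tibble(
        id = part$id, bx = inst$exposure_gwas$beta,
        se_x = inst$exposure_gwas$se, by = part$d_m, se_y = part$se_dm
      )
      boot_seed <- derive_seed(config$seed, 3L)
      dplyr::bind_rows(
        mr_ivw(hset, model = config$ivw_model),
        mr_egger(hset),
        mr_weighted_median(hset, n_boot = config$n_boot, seed = boot_seed),
        mr_mode(hset, "simple", phi = config$phi, n_boot = config$n_boot,
                seed = boot_seed),
        mr_mode(hset, "weighted", phi = config$phi, n_boot = config$n_boot,
                seed = boot_seed)
      )
    })
  }

  if (on("mvmr")) {
    res$mvmr <- run_stage("mvmr", {
      smoke <- per_snp_gwas(trios, outcome = "smoking", who = "maternal")
      alc <- per_snp_gwas(trios, outcome = "alcohol", who = "maternal")
      X <- cbind(coffee = inst$exposure_gwas$beta, smoking = smoke$beta,
                 alcohol = alc$beta)
      mr_mvmr_ivw(X, part$d_m, part$se_dm)
    })
  }

  if (on("gxe")) {
    res$gxe <- run_stage("gxe", {
      screen <- collider_screen(trios, ph$consumer_flag,
                                alpha = config$collider_alpha,
                                covariates = inst$covariates)
      kept <- dplyr::filter(inst$weights, !.data$id %in%
                              screen$id[screen$excluded])
      pgs_scr <- build_pgs(trios$dosage_m, kept)
      g <- gxe_stratified(ph$nd, pgs_scr,
                          offspring = trios$dosage_o[, kept$id, drop = FALSE],
                          covariates = inst$covariates,
                          strata_flag = ph$consumer_flag)
      list(collider_screen = screen, estimates = g$estimates,
           heterogeneity = g$heterogeneity)
    })
    res$collider_screen <- res$gxe$collider_screen
    res$gxe_mr <- res$gxe$estimates
    res$gxe_heterogeneity <- res$gxe$heterogeneity
    res$gxe <- NULL
  }

  eff <- run_stage("effective_tests", {
    set.seed(derive_seed(config$seed, 4L))
    k <- config$n_null_outcomes
    batt <- cbind(nd = ph$nd_raw,
                  sapply(seq_len(k), function(i) {
                    config$sim$confounder_outcome * ph$confounder +
                      rnorm(nrow(ph), 0, config$sim$noise_sd)
                  }))
    colnames(batt) <- c("nd", paste0("nd_null", seq_len(k)))
    effective_tests_threshold(batt, config$variance_target,
                              config$alpha_total)
  })
  res$effective_tests <- glance(eff)

  res$summary <- run_stage("summary", {
    pick <- list(
      if (!is.null(res$observational)) {
        dplyr::transmute(res$observational,
                         analysis = paste0("observational_", .data$preset),
                         term = .data$term, beta = .data$beta, se = .data$se,
                         p = .data$p)
      },
      if (!is.null(res$duo_mr)) {
        dplyr::transmute(res$duo_mr, analysis = .data$model,
                         term = .data$term,
                         beta = .data$beta, se = .data$se, p = .data$p)
      },
      if (!is.null(res$trio_mr)) {
        dplyr::transmute(res$trio_mr, analysis = .data$model,
                         term = .data$term,
                         beta = .data$beta, se = .data$se, p = .data$p)
      },
      if (!is.null(res$two_sample_mr)) {
        dplyr::transmute(res$two_sample_mr,
                         analysis = paste0("two_sample_", .data$method),
                         term = "coffee", beta = .data$beta, se = .data$se,
                         p = .data$p)
      },
      if (!is.null(res$gxe_mr)) {
        dplyr::transmute(res$gxe_mr,
                         analysis = paste0("gxe_", .data$stratum),
                         term = .data$term, beta = .data$beta, se = .data$se,
                         p = .data$p)
      }
    )
    out <- dplyr::bind_rows(pick[!vapply(pick, is.null, logical(1))])
    dplyr::mutate(out, significant = .data$p < eff$alpha)
  })

  report <- structure(c(res, list(trios = trios, config = config)),
                      class = "mr_pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mr_pipeline_report <- function(x, ...) {
  cat("<mr_pipeline_report> stages:",
      paste(x$config$stages, collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.mr_pipeline_report <- function(x, ...) {
  tibble::tibble(
    n_families = x$trios$n_families,
    n_variants = nrow(x$trios$variants),
    seed = x$config$seed,
    alpha = x$effective_tests$alpha
  )
}

# write every tabular element of a report plus a run log
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(report$config)
  seed <- report$config$seed
  tables <- Filter(is.data.frame, report)
  for (nm in names(tables)) {
    write_results(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  seed = seed, config_hash = h)
  }
  log <- c(
    sprintf("triomr %s", as.character(utils::packageVersion("triomr"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d", seed),
    sprintf("config %s", h),
    sprintf("stages %s", paste(report$config$stages, collapse = ","))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
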