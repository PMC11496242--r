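#' Aggregate coffee intake across beverage types
#'
#' Total daily coffee consumption (cups/day) is the sum over coffee types
#' (filtered, instant, boiled, latte, espresso, ...). Individuals whose total
#' volume exceeds 3.5 litres per day are flagged for exclusion; the
#' cup-to-volume conversion is configurable because questionnaire cup sizes
#' vary by study.
#'
#' @param per_type_cups Either a named numeric vector of cups/day per coffee
#'   type (one individual) or a data frame whose numeric columns are coffee
#'   types (one row per individual).
#' @param cup_volume_ml Assumed cup volume in millilitres (default 125).
#' @param max_volume_ml Daily-volume exclusion threshold (default 3500 mL).
#' @return A tibble with columns `cups_day`, `excluded` and `consumer_flag`.
#' @export
#' @examples
#' aggregate_coffee(c(filtered = 2, instant = 1, espresso = 1))
aggregate_coffee <- function(per_type_cups, cup_volume_ml = 125,
                             max_volume_ml = 3500) {
  if (is.data.frame(per_type_cups)) {
    num <- dplyr::select(per_type_cups, dplyr::where(is.numeric))
    vals <- as.matrix(num)
  } else {
    vals <- matrix(as.numeric(per_type_cups), nrow = 1)
  }
  if (anyNA(vals) || any(vals < 0)) {
    abort("Coffee intakes must be non-negative and non-missing.",
          class = "triomr_validation_error")
  }
  cups <- rowSums(vals)
  tibble::tibble(
    cups_day = cups,
    excluded = cups * cup_volume_ml > max_volume_ml,
    consumer_flag = cups > 0
  )
}

#' Aggregate caffeine intake across sources
#'
#' Caffeine (mg/day) is the sum over sources of daily servings times the
#' configured caffeine content per serving. The content table is pure
#' configuration; `default_caffeine_contents()` ships plausible per-serving
#' values for the common questionnaire sources.
#'
#' @param source_amounts Named numeric vector (servings/day per source) or a
#'   data frame with one numeric column per source.
#' @param content_table Named numeric vector, mg caffeine per serving.
#' @return Numeric vector of mg/day (one value per individual).
#' @export
#' @examples
#' aggregate_caffeine(c(coffee = 2, tea = 1),
#'                    content_table = c(coffee = 100, tea = 30))
aggregate_caffeine <- function(source_amounts,
                               content_table = default_caffeine_contents()) {
  if (is.data.frame(source_amounts)) {
    num <- dplyr::select(source_amounts, dplyr::where(is.numeric))
    vals <- as.matrix(num)
    sources <- colnames(num)
  } else {
    vals <- matrix(as.numeric(source_amounts), nrow = 1)
    sources <- names(source_amounts)
  }
  if (ncol(vals) == 0) return(rep(0, nrow(vals)))
  unknown <- setdiff(sources, names(content_table))
  if (length(unknown)) {
    abort(paste0("Unknown caffeine source(s): ", paste(unknown, collapse = ", ")),
          class = "triomr_configuration_error")
  }
  drop(vals %*% content_table[sources])
}

#' @rdname aggregate_caffeine
#' @export
default_caffeine_contents <- function() {
  c(filtered_coffee = 90, instant_coffee = 60, boiled_coffee = 100,
    espresso = 75, latte = 75, black_tea = 40, herbal_tea = 0,
    soft_drink = 30, energy_drink = 80, chocolate = 10)
}

#' Scale score with 50% mean imputation
#'
#' Sums questionnaire items into a scale score. If at least half the items are
#' observed, missing items are replaced by the mean of the observed items
#' before summing; otherwise the score is missing.
#'
#' @param items Numeric vector of item responses (may contain `NA`).
#' @return The imputed sum, or `NA` when fewer than 50% of items are observed.
#' @export
#' @examples
#' impute_scale_score(c(2, NA, 4, 2)) # 8 + 8/3
impute_scale_score <- function(items) {
  if (length(items) < 1L) {
    abort("`items` must contain at least one item.",
          class = "triomr_validation_error")
  }
  obs <- !is.na(items)
  if (mean(obs) < 0.5) return(NA_real_)
  sum(items[obs]) + sum(!obs) * mean(items[obs])
}

#' @rdname impute_scale_score
#' @param item_matrix Numeric matrix, individuals in rows.
#' @return For `impute_scale_scores()`, a numeric vector of scores.
#' @export
impute_scale_scores <- function(item_matrix) {
  apply(as.matrix(item_matrix), 1, impute_scale_score)
}

#' Rank-based inverse normal transformation
#'
#' Maps the value of rank r among n non-missing observations to
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} with the Blom offset c = 3/8 by
#' default. Ties receive average ranks; missing values stay missing.
#'
#' @param values Numeric vector.
#' @param offset Rank offset c (default 3/8, the Blom constant).
#' @return Transformed vector, same length and missingness as the input.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n == 0) {
    abort("All values are missing.", class = "triomr_validation_error")
  }
  if (n < 2) {
    abort("Need at least 2 non-missing values.",
          class = "triomr_validation_error")
  }
  r <- rank(values[obs], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Effective number of tests from outcome covariance
#'
#' Because correlated outcomes do not contribute independent tests, the
#' multiple-testing burden is taken as the smallest number of principal
#' components whose cumulative variance fraction reaches `variance_target`;
#' the significance threshold is `alpha_total` divided by that count. PCA is
#' run on the correlation matrix of complete cases.
#'
#' @param x Either a numeric outcome matrix/data frame (individuals x
#'   outcomes) or a numeric vector of eigenvalue fractions summing to 1.
#' @param variance_target Cumulative variance fraction to reach (default 0.8).
#' @param alpha_total Family-wise alpha to divide (default 0.05).
#' @return An `effective_tests` object: list with `eigen_fractions`,
#'   `n_components`, `alpha`, `variance_target`.
#' @export
#' @examples
#' effective_tests_threshold(c(0.5, 0.3, 0.2)) # 2 components, alpha 0.025
effective_tests_threshold <- function(x, variance_target = 0.8,
                                      alpha_total = 0.05) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (ncol(x) < 2) {
      abort("Need at least two outcomes.", class = "triomr_validation_error")
    }
    x <- x[complete.cases(x), , drop = FALSE]
    pca <- prcomp(x, center = TRUE, scale. = TRUE)
    fractions <- pca$sdev^2 / sum(pca$sdev^2)
  } else {
    fractions <- as.numeric(x)
    if (length(fractions) < 2) {
      abort("Need at least two outcomes.", class = "triomr_validation_error")
    }
    if (abs(sum(fractions) - 1) > 1e-6 || any(fractions < 0)) {
      abort("Eigenvalue fractions must be non-negative and sum to 1.",
            class = "triomr_validation_error")
    }
  }
  cum <- cumsum(fractions)
  n_components <- which(cum >= variance_target - 1e-12)[1]
  structure(list(
    eigen_fractions = fractions,
    n_components = as.integer(n_components),
    alpha = alpha_total / n_components,
    variance_target = variance_target
  ), class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat("<effective_tests> ", x$n_components, " components reach ",
      100 * x$variance_target, "% of outcome variance; alpha = ",
      signif(x$alpha, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.effective_tests <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigen_fractions),
    eigen_fraction = x$eigen_fractions,
    cumulative = cumsum(x$eigen_fractions)
  )
}

#' @export
glance.effective_tests <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, alpha = x$alpha,
                 variance_target = x$variance_target)
}
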