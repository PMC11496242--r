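
# internal validation helpers

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, deparse(substitute(x))),
          class = "triomr_invalid_config")
  }
  invisible(as.integer(x))
}

check_positive_se <- function(se, name = "se") {
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort(sprintf("All `%s` must be finite and > 0.", name),
          class = "triomr_invalid_se")
  }
  invisible(se)
}

# two-sided normal p-value
p_from_z <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

# two-sided t p-value
p_from_t <- function(t, df) 2 * pt(abs(t), df = df, lower.tail = FALSE)

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

valid_allele <- function(a) a %in% c("A", "C", "G", "T")

# deterministic child stream for a stage, kept under 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) + 1009L * as.integer(stage)) %% 2147483629L
}
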