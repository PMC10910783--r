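# Internal assertion helpers. Kept deliberately small: user-facing
# validation with informative messages lives in the constructors.

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Region label used to key matrix rows/columns: "<acronym>_<hemisphere>".
region_label <- function(acronym, hemisphere) {
  paste(acronym, hemisphere, sep = "_")
}

# Add-one empirical p-value for permutation/resampling tests: the true
# statistic is counted among the draws, so p can never be exactly 0 and
# its minimum is 1 / (1 + n_draws).
empirical_p <- function(observed, draws, larger_is_extreme = TRUE) {
  if (larger_is_extreme) {
    (1 + sum(draws >= observed)) / (1 + length(draws))
  } else {
    (1 + sum(draws <= observed)) / (1 + length(draws))
  }
}
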