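# Bootstrap distributions of bidirectional-fit statistics per
# experimental group, and descriptive paired comparison between groups.

#' Bootstrap the bidirectional fit within one experimental group
#'
#' Resamples the group's mice with replacement (same count as observed,
#' within each timepoint), recomputes the group-mean regional pathology
#' vectors, refits the bidirectional spread model, and records the pooled
#' Pearson r, both time constants, and both standardized regression
#' weights for every resample. Groups measured at a single timepoint are
#' bootstrapped on that timepoint alone.
#'
#' @param data Region table restricted to one experimental group.
#' @inheritParams fit_spread_model
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param rng_seed Integer seed controlling the resampling.
#' @param group_label Optional label carried into the result.
#' @return Object of class `bootstrap_result`: `draws` (tibble with one
#'   row per resample: `pearson_r`, `c_a`, `c_r`, `std_beta_a`,
#'   `std_beta_r`), percentile `intervals` (2.5%, 50%, 97.5%), `n_boot`,
#'   `group_label`. [tidy()] returns the draws, [glance()] the intervals
#'   in wide form, [autoplot()] the densities.
#' @export
bootstrap_group <- function(data, connectome, seeds = connectome$seeds,
                            n_boot = 500, rng_seed = NULL,
                            timepoints = NULL, normalize = TRUE,
                            n_starts = 5, group_label = NULL) {
  stop_if_not_count(n_boot, "n_boot")
  if (nrow(data) == 0) abort("`data` contains no mice.")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!is.null(timepoints)) data <- data[data$mpi %in% timepoints, ]
  x0 <- make_seed_vector(connectome, seeds)
  props <- build_props(connectome, "bidirectional", normalize = normalize)
  comps <- comps_for(props, "bidirectional", x0)
  mice <- dplyr::distinct(data, .data$mouse_id, .data$mpi)
  per_tp <- lapply(split(mice$mouse_id, mice$mpi), sort)
  rows_by_mouse <- split(seq_len(nrow(data)), data$mouse_id)
  draws <- vector("list", n_boot)
  n_refit <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      picked <- unlist(lapply(per_tp, function(ids) {
        sample(ids, length(ids), replace = TRUE)
      }), use.names = FALSE)
      # duplicated mice contribute their rows once per pick, so the
      # group mean weights them accordingly
      resampled <- data[unlist(rows_by_mouse[picked], use.names = FALSE), ]
      Y <- obs_matrix(resampled, connectome)
      eng <- tryCatch(
        fit_engine(Y, attr(Y, "timepoints"), comps, n_starts = n_starts),
        error = function(e) NULL
      )
      if (!is.null(eng)) break
      n_refit <- n_refit + 1L
      if (n_refit > n_boot) {
        abort("Too many bootstrap resamples failed to fit; the group may be degenerate.")
      }
    }
    draws[[b]] <- tibble::tibble(
      resample = b,
      pearson_r = eng$r_pooled,
      c_a = unname(eng$rates["a"]), c_r = unname(eng$rates["r"]),
      std_beta_a = unname(eng$std_betas["a"]),
      std_beta_r = unname(eng$std_betas["r"])
    )
  }
  if (n_refit > 0) {
    inform(sprintf("%d bootstrap resample(s) failed to fit and were re-drawn.",
                   n_refit))
  }
  draws <- dplyr::bind_rows(draws)
  stats <- c("pearson_r", "c_a", "c_r", "std_beta_a", "std_beta_r")
  intervals <- purrr::map_dfr(stats, function(s) {
    q <- quantile(draws[[s]], c(0.025, 0.5, 0.975), na.rm = TRUE,
                  names = FALSE)
    tibble::tibble(statistic = s, lower = q[1], median = q[2],
                   upper = q[3])
  })
  structure(
    list(group_label = group_label %||% "group", n_boot = n_boot,
         draws = draws, intervals = intervals, rng_seed = rng_seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: %d resamples\n",
              x$group_label, x$n_boot))
  print(x$intervals)
  invisible(x)
}

#' @describeIn bootstrap_group Bootstrap draws, one row per resample.
#' @param x A `bootstrap_result`.
#' @exportS3Method generics::tidy
tidy.bootstrap_result <- function(x, ...) {
  x$draws
}

#' @describeIn bootstrap_group One-row wide summary of medians and 95%
#'   percentile intervals.
#' @exportS3Method generics::glance
glance.bootstrap_result <- function(x, ...) {
  wide <- x$intervals |>
    tidyr::pivot_wider(names_from = "statistic",
                       values_from = c("lower", "median", "upper"),
                       names_glue = "{statistic}_{.value}")
  dplyr::bind_cols(
    tibble::tibble(group_label = x$group_label, n_boot = x$n_boot),
    wide
  )
}

#' Compare bootstrap distributions between two groups
#'
#' Descriptive comparison of one fit statistic across two
#' [bootstrap_group()] results computed with the same number of
#' resamples: the difference of medians and the fraction of index-paired
#' draws where group `a`'s value is below group `b`'s. Each resample
#' index is an independent replicate, so pairing draws is a natural
#' coupling; no formal p-value is claimed.
#'
#' @param a,b `bootstrap_result` objects with equal `n_boot`.
#' @param statistic One of `"pearson_r"`, `"c_a"`, `"c_r"`,
#'   `"std_beta_a"`, `"std_beta_r"`.
#' @return One-row tibble: medians, `median_diff` (`b - a`), and
#'   `frac_a_lt_b`.
#' @export
compare_groups <- function(a, b, statistic = c("std_beta_r", "std_beta_a",
                                               "pearson_r", "c_a", "c_r")) {
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  statistic <- match.arg(statistic)
  if (a$n_boot != b$n_boot) {
    abort(sprintf("`a` has %d resamples but `b` has %d; they must match.",
                  a$n_boot, b$n_boot))
  }
  va <- a$draws[[statistic]]
  vb <- b$draws[[statistic]]
  tibble::tibble(
    statistic = statistic,
    group_a = a$group_label, group_b = b$group_label,
    median_a = median(va), median_b = median(vb),
    median_diff = median(vb) - median(va),
    frac_a_lt_b = mean(va < vb)
  )
}
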