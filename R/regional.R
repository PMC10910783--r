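# Region-wise group comparison: section aggregation, zero-variance
# filtering, ranked robust regression (Huber M-estimation via MASS::rlm,
# marginal contrasts via emmeans) and second-generation P-values.

#' Average section-level quantifications into one value per region
#'
#' Histological quantification yields one percent-area value per region
#' per coronal section; a region appearing in several of a mouse's
#' sections is summarized by the mean across those sections.
#'
#' @param sections Data frame with columns `mouse_id`, `section_id`,
#'   `hemisphere`, `region`, `pct_area`, plus any mouse-level covariates
#'   (`genotype`, `treatment`, `sex`, `mpi`, `n_daughters`), which are
#'   carried through unchanged.
#' @return A region table: one row per (mouse, hemisphere, region).
#' @export
aggregate_sections <- function(sections) {
  required <- c("mouse_id", "section_id", "hemisphere", "region",
                "pct_area")
  missing_cols <- setdiff(required, names(sections))
  if (length(missing_cols) > 0) {
    abort(paste0("`sections` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  key <- paste(sections$mouse_id, sections$section_id,
               sections$hemisphere, sections$region, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- sections[duplicated(key), c("mouse_id", "section_id",
                                       "hemisphere", "region")]
    abort(paste0(
      "Duplicate (mouse, section, hemisphere, region) rows, e.g.: ",
      paste(unlist(dup[1, ]), collapse = " / ")))
  }
  covars <- setdiff(names(sections), c("section_id", "pct_area"))
  sections |>
    dplyr::group_by(dplyr::across(dplyr::all_of(covars))) |>
    dplyr::summarise(pct_area = mean(.data$pct_area), .groups = "drop")
}

#' Remove strata with zero variance in pathology
#'
#' Drops every (hemisphere, region, timepoint) stratum whose percent-area
#' values are identical across all mice of all groups — typically regions
#' with no measurable pathology in anyone — since no comparison is
#' possible there.
#'
#' @param data A region table.
#' @return The filtered table, with attribute `n_filtered` (number of
#'   strata removed); a message reports the count.
#' @export
filter_zero_variance <- function(data) {
  strata <- data |>
    dplyr::group_by(.data$hemisphere, .data$region, .data$mpi) |>
    dplyr::summarise(constant = dplyr::n_distinct(.data$pct_area) == 1,
                     .groups = "drop")
  n_removed <- sum(strata$constant)
  keep <- strata |> dplyr::filter(!.data$constant)
  out <- dplyr::semi_join(data, keep,
                          by = c("hemisphere", "region", "mpi"))
  inform(sprintf("Filtered %d zero-variance stratum/strata (of %d).",
                 n_removed, nrow(strata)))
  attr(out, "n_filtered") <- n_removed
  out
}

#' Rank-transform a numeric vector
#'
#' Midranks: ties receive the average of the ranks they span, so the
#' ranks always sum to `n (n + 1) / 2`.
#'
#' @param values Numeric vector.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) < 1) abort("`values` must have length >= 1.")
  rank(values, ties.method = "average")
}

#' Robust rank regression for one stratum
#'
#' Huber M-estimation (tuning constant 1.345, iteratively reweighted
#' least squares) of the rank-transformed percent area on a two-level
#' explanatory factor, optionally adjusted for sex and for the
#' daughter-region count (the latter only when it reaches 2 and varies
#' within the stratum — a constant covariate carries no information and
#' would make the design rank-deficient). The effect is the marginal
#' contrast between the explanatory levels averaged over covariate
#' levels, with a 95% interval from the asymptotic covariance of the
#' robust fit.
#'
#' @param data Rows of a single (hemisphere, region, timepoint) stratum,
#'   already conditioned on the non-tested grouping variable.
#' @param explanatory `"genotype"` or `"treatment"`.
#' @param adjust_sex Adjust for sex when both sexes are present.
#' @param adjust_daughters Adjust for the daughter-region count as a
#'   numeric covariate, subject to the rule above.
#' @return One-row tibble: `effect` (first level minus second, on the
#'   rank scale), `ci_low`, `ci_high`, `se`, `n`, `rank_range`.
#' @export
robust_region_fit <- function(data, explanatory = c("genotype", "treatment"),
                              adjust_sex = TRUE, adjust_daughters = TRUE) {
  explanatory <- match.arg(explanatory)
  g <- factor(data[[explanatory]])
  if (nlevels(g) != 2) {
    abort(sprintf("`%s` must have exactly 2 levels in the stratum (found %d).",
                  explanatory, nlevels(g)))
  }
  counts <- table(g)
  if (any(counts < 3)) {
    abort(sprintf("Each compared level needs >= 3 observations (found %s).",
                  paste(counts, collapse = "/")))
  }
  rk <- rank_transform(data$pct_area)
  df <- data.frame(rk = rk, group = g)
  terms <- "group"
  if (adjust_sex && "sex" %in% names(data) &&
      length(unique(data$sex)) > 1) {
    df$sex <- factor(data$sex)
    terms <- c(terms, "sex")
  }
  if (adjust_daughters && "n_daughters" %in% names(data) &&
      max(data$n_daughters) >= 2 && length(unique(data$n_daughters)) > 1) {
    df$n_daughters <- as.numeric(data$n_daughters)
    terms <- c(terms, "n_daughters")
  }
  form <- stats::reformulate(terms, response = "rk")
  fit <- suppressWarnings(
    MASS::rlm(form, data = df, psi = MASS::psi.huber, k = 1.345,
              maxit = 50, acc = 1e-8)
  )
  if (!fit$converged) {
    warn("Robust fit did not converge within 50 iterations; estimates may be unstable.")
  }
  emm <- emmeans::emmeans(fit, "group")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"))
  # t-quantile interval with residual df: the asymptotic normal interval
  # undercovers at the cohort sizes typical here (6-10 mice per arm)
  df_resid <- nrow(df) - length(coef(fit))
  crit <- stats::qt(0.975, df_resid)
  tibble::tibble(
    effect = ctr$estimate,
    ci_low = ctr$estimate - crit * ctr$SE,
    ci_high = ctr$estimate + crit * ctr$SE,
    se = ctr$SE,
    n = nrow(df),
    rank_range = diff(range(rk))
  )
}

#' Second-generation P-value of an interval estimate
#'
#' The fraction of the interval estimate `I = [ci_low, ci_high]` that
#' overlaps the null interval `N = [null_low, null_high]`, with the
#' small-sample correction for very wide estimates: when
#' `|I| > 2 |N|` the overlap is reported relative to `2 |N|` instead of
#' `|I|`. A value of 0 means the estimate is wholly incompatible with the
#' null interval; 1 means it lies entirely inside it. Degenerate point
#' estimates give 1 if the point is in `N`, else 0; infinite intervals
#' return the inconclusive value 0.5.
#'
#' @param ci_low,ci_high Interval estimate bounds (vectorized).
#' @param null_low,null_high Null interval bounds.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
#' @examples
#' second_generation_p(10, 20, -5, 5)   # disjoint -> 0
#' second_generation_p(-5, 5, -5, 5)    # identical -> 1
#' second_generation_p(0, 10, -5, 5)    # half overlap -> 0.5
#' second_generation_p(-20, 20, -5, 5)  # wide-interval correction -> 0.5
second_generation_p <- function(ci_low, ci_high, null_low, null_high) {
  n <- max(length(ci_low), length(ci_high),
           length(null_low), length(null_high))
  ci_low <- rep_len(ci_low, n); ci_high <- rep_len(ci_high, n)
  null_low <- rep_len(null_low, n); null_high <- rep_len(null_high, n)
  if (any(ci_low > ci_high, na.rm = TRUE)) {
    abort("`ci_low` must be <= `ci_high`.")
  }
  if (any(null_low >= null_high, na.rm = TRUE)) {
    abort("`null_low` must be < `null_high`.")
  }
  li <- ci_high - ci_low
  ln <- null_high - null_low
  overlap <- pmax(0, pmin(ci_high, null_high) - pmax(ci_low, null_low))
  p <- ifelse(li == 0,
              as.numeric(ci_low >= null_low & ci_low <= null_high),
              ifelse(li <= 2 * ln, overlap / li, overlap / (2 * ln)))
  p[is.infinite(ci_low) | is.infinite(ci_high)] <- 0.5
  p
}

#' Region-wise group comparison with second-generation P-values
#'
#' Runs [robust_region_fit()] in every stratum — (hemisphere, region,
#' timepoint), conditioned on each level of the non-tested grouping
#' variable — and evaluates a second-generation P-value against a null
#' interval of +/- `null_frac` (default 5%) of the stratum's rank range.
#' A region is flagged significant only when its SGPV equals 0, i.e. its
#' 95% interval is wholly incompatible with the null band. Strata that
#' cannot be analyzed (a missing level, too few mice, a failed fit) are
#' returned with a reason code rather than dropped.
#'
#' @param data A region table, normally after [filter_zero_variance()].
#' @param hypothesis `"genotype"` or `"treatment"`: the tested variable.
#'   Strata are additionally conditioned on the other one.
#' @param levels Optional length-2 vector picking the two levels of the
#'   tested variable to compare (required when it has more than two).
#' @param adjust_sex,adjust_daughters Passed to [robust_region_fit()].
#' @param null_frac Half-width of the null interval as a fraction of the
#'   stratum's rank range.
#' @return Tibble with one row per stratum: `hemisphere`, `region`,
#'   `mpi`, the conditioning column, `n`, `effect`, `ci_low`, `ci_high`,
#'   `sgpv`, `significant`, `reason` (`NA` when analyzed).
#' @export
regional_comparison <- function(data,
                                hypothesis = c("genotype", "treatment"),
                                levels = NULL,
                                adjust_sex = TRUE, adjust_daughters = TRUE,
                                null_frac = 0.05) {
  hypothesis <- match.arg(hypothesis)
  conditioning <- setdiff(c("genotype", "treatment"), hypothesis)
  vals <- unique(data[[hypothesis]])
  if (!is.null(levels)) {
    if (length(levels) != 2) abort("`levels` must have length 2.")
    data <- data[data[[hypothesis]] %in% levels, ]
  } else if (length(vals) > 2) {
    abort(sprintf(
      "`%s` has %d levels; supply `levels` to pick the two to compare.",
      hypothesis, length(vals)))
  }
  strata <- data |>
    dplyr::group_by(.data$hemisphere, .data$region, .data$mpi,
                    dplyr::across(dplyr::all_of(conditioning))) |>
    dplyr::group_split()
  rows <- purrr::map(strata, function(stratum) {
    id <- stratum[1, c("hemisphere", "region", "mpi", conditioning)]
    present <- unique(stratum[[hypothesis]])
    base <- dplyr::bind_cols(id, tibble::tibble(
      n = nrow(stratum), effect = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, sgpv = NA_real_, significant = NA,
      reason = NA_character_))
    if (length(present) < 2) {
      base$reason <- "single_level"
      return(base)
    }
    if (any(table(stratum[[hypothesis]]) < 3)) {
      base$reason <- "too_few_per_level"
      return(base)
    }
    res <- tryCatch(
      robust_region_fit(stratum, explanatory = hypothesis,
                        adjust_sex = adjust_sex,
                        adjust_daughters = adjust_daughters),
      error = function(e) NULL
    )
    if (is.null(res)) {
      base$reason <- "fit_failed"
      return(base)
    }
    if (res$rank_range == 0) {
      base$reason <- "constant_outcome"
      return(base)
    }
    band <- null_frac * res$rank_range
    p <- second_generation_p(res$ci_low, res$ci_high, -band, band)
    base$effect <- res$effect
    base$ci_low <- res$ci_low
    base$ci_high <- res$ci_high
    base$sgpv <- p
    base$significant <- p == 0
    base
  })
  dplyr::bind_rows(rows)
}
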