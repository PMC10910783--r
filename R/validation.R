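# Model validation: seed-specificity permutation test with
# distance-matched random seed sets, and held-out comparison of the
# bidirectional model against Euclidean-distance and unidirectional
# alternatives.

# Inverse-distance proximity graph and its out-degree Laplacian, used by
# the Euclidean (connectivity-free) reference model.
euclidean_laplacian <- function(cn) {
  d <- pairwise_centroid_distances(cn)
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    abort("Two distinct regions have coincident centroids; the inverse-distance proximity graph is undefined.")
  }
  P <- 1 / d
  diag(P) <- 0
  L <- diag(rowSums(P)) - P
  dimnames(L) <- dimnames(d)
  L
}

#' Euclidean-distance diffusion predictor
#'
#' The spatial reference model replaces the connectome with a symmetric
#' inverse-distance proximity graph (`P[i,j] = 1 / d(i,j)`, zero diagonal)
#' and diffuses the seed vector over its out-degree Laplacian. Because the
#' graph is symmetric there is a single direction and a single predictor.
#'
#' @param connectome A [connectome] with centroids.
#' @param c_rate Positive diffusion rate, per month.
#' @param t Non-negative time in months.
#' @param x0 A [make_seed_vector()] object or numeric indicator.
#' @return A tibble as from [spread_predictor()].
#' @export
euclidean_predictor <- function(connectome, c_rate, t, x0) {
  spread_predictor(euclidean_laplacian(connectome), c_rate, t, x0)
}

mean_pairwise_distance <- function(D, idx) {
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Sample random seed sets matched on mean pairwise distance
#'
#' Rejection-samples sets of regions with the same cardinality as the true
#' seed set and a mean pairwise centroid distance within `rel_tol` of the
#' true seeds' mean pairwise distance. Matching on spatial spread isolates
#' the connectome-topological specificity of the true seeds from their
#' mere spatial configuration.
#'
#' @param connectome A [connectome] with centroids.
#' @param true_seeds Character vector of true seed acronyms (ipsilateral).
#' @param n_sets Number of matched sets to return (default 500).
#' @param rel_tol Relative tolerance on the mean pairwise distance
#'   (default 0.10, i.e. +/- 10%).
#' @param hemisphere Optional `"ipsi"`/`"contra"` restriction on the
#'   candidate pool; default uses all connectome regions.
#' @param rng_seed Optional integer seed for reproducibility.
#' @param max_draws Bound on raw draws before giving up.
#' @return List of integer index vectors (into the connectome's regions),
#'   with attributes `target_distance` (mm) and `tolerance_band` (mm).
#' @export
sample_matched_seed_sets <- function(connectome, true_seeds = connectome$seeds,
                                     n_sets = 500, rel_tol = 0.10,
                                     hemisphere = NULL, rng_seed = NULL,
                                     max_draws = 2000 * n_sets) {
  stop_if_not_count(n_sets, "n_sets")
  stop_if_not_scalar_number(rel_tol, "rel_tol", positive = TRUE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x0 <- make_seed_vector(connectome, true_seeds)
  D <- pairwise_centroid_distances(connectome)
  d0 <- mean_pairwise_distance(D, x0$index)
  band <- c(d0 * (1 - rel_tol), d0 * (1 + rel_tol))
  pool <- seq_len(nrow(connectome$adjacency))
  if (!is.null(hemisphere)) {
    pool <- pool[connectome$regions$hemisphere == hemisphere]
  }
  k <- length(x0$index)
  if (length(pool) <= k) {
    abort("Candidate pool is not larger than the seed set.")
  }
  true_sorted <- sort(x0$index)
  sets <- vector("list", n_sets)
  found <- 0L
  draws <- 0L
  while (found < n_sets) {
    if (draws >= max_draws) {
      abort(sprintf(
        "Only %d of %d matched seed sets found in %d draws; the distance band may be too narrow for this connectome.",
        found, n_sets, draws))
    }
    draws <- draws + 1L
    cand <- sort(sample(pool, k))
    if (identical(cand, true_sorted)) next
    m <- mean_pairwise_distance(D, cand)
    if (m >= band[1] && m <= band[2]) {
      found <- found + 1L
      sets[[found]] <- cand
    }
  }
  attr(sets, "target_distance") <- d0
  attr(sets, "tolerance_band") <- band
  attr(sets, "acceptance_rate") <- found / draws
  sets
}

#' Seed-specificity permutation test
#'
#' Fits the bidirectional spread model at the true injection seeds and at
#' `n_null` distance-matched random seed sets (full re-optimization of
#' both time constants per set) and reports the add-one empirical
#' p-value for the true-seed fit:
#' `p = (1 + #\{null r >= observed r\}) / (1 + n_null)`.
#' With 500 null sets the smallest attainable p is 1/501, just under
#' 0.002.
#'
#' @inheritParams fit_spread_model
#' @param n_null Number of matched null seed sets (default 500).
#' @param rel_tol Distance-matching tolerance (see
#'   [sample_matched_seed_sets()]).
#' @param hemisphere Optional hemisphere restriction for null seed sets.
#' @param rng_seed Integer seed controlling the null draws.
#' @return Object of class `seed_null` with `observed_r`, `null_rs`,
#'   `empirical_p`, `seed_sets`, `tolerance_band`. [tidy()] returns the
#'   null draws, [glance()] the one-row summary, [autoplot()] a histogram.
#' @export
seed_specificity_test <- function(data, connectome,
                                  seeds = connectome$seeds,
                                  n_null = 500, rel_tol = 0.10,
                                  hemisphere = NULL, rng_seed = NULL,
                                  timepoints = NULL, normalize = TRUE,
                                  n_starts = 5) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x0 <- make_seed_vector(connectome, seeds)
  Y <- obs_matrix(data, connectome, timepoints)
  tp <- attr(Y, "timepoints")
  props <- build_props(connectome, "bidirectional", normalize = normalize)
  fit_at <- function(x0i) {
    comps <- comps_for(props, "bidirectional", x0i)
    fit_engine(Y, tp, comps, n_starts = n_starts)
  }
  observed <- fit_at(x0)
  sets <- sample_matched_seed_sets(connectome, seeds, n_sets = n_null,
                                   rel_tol = rel_tol,
                                   hemisphere = hemisphere)
  null_rs <- numeric(n_null)
  n_refail <- 0L
  for (i in seq_len(n_null)) {
    repeat {
      res <- tryCatch(
        fit_at(seed_vector_from_index(connectome, sets[[i]])),
        error = function(e) NULL
      )
      if (!is.null(res)) break
      n_refail <- n_refail + 1L
      if (n_refail > n_null) {
        abort("Too many null seed sets failed to fit; the data may be degenerate.")
      }
      sets[i] <- sample_matched_seed_sets(connectome, seeds, n_sets = 1,
                                          rel_tol = rel_tol,
                                          hemisphere = hemisphere)
    }
    null_rs[i] <- res$r_pooled
  }
  if (n_refail > 0) {
    inform(sprintf("%d null seed set(s) failed to fit and were re-drawn.",
                   n_refail))
  }
  labels <- rownames(connectome$adjacency)
  structure(
    list(
      observed_r = observed$r_pooled,
      null_rs = null_rs,
      empirical_p = empirical_p(observed$r_pooled, null_rs),
      seed_sets = lapply(sets, function(idx) labels[idx]),
      tolerance_band = attr(sets, "tolerance_band"),
      target_distance = attr(sets, "target_distance"),
      n_null = n_null,
      true_fit = observed
    ),
    class = "seed_null"
  )
}

#' @export
print.seed_null <- function(x, ...) {
  cat(sprintf(
    "<seed_null> observed r = %.4f vs %d distance-matched null sets\n",
    x$observed_r, x$n_null))
  cat(sprintf("  matched mean pairwise distance: %.2f mm (band %.2f-%.2f)\n",
              x$target_distance, x$tolerance_band[1], x$tolerance_band[2]))
  cat(sprintf("  empirical p = %.4g (minimum attainable %.4g)\n",
              x$empirical_p, 1 / (1 + x$n_null)))
  invisible(x)
}

#' @describeIn seed_specificity_test Null draws as a tibble.
#' @param x A `seed_null`.
#' @exportS3Method generics::tidy
tidy.seed_null <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_rs), null_r = x$null_rs)
}

#' @describeIn seed_specificity_test One-row summary of the test.
#' @exportS3Method generics::glance
glance.seed_null <- function(x, ...) {
  tibble::tibble(
    observed_r = x$observed_r,
    null_median_r = median(x$null_rs),
    null_max_r = max(x$null_rs),
    empirical_p = x$empirical_p,
    n_null = x$n_null,
    target_distance_mm = x$target_distance
  )
}

#' Cross-validated comparison of spread models
#'
#' Repeatedly splits the mice into random disjoint halves (stratified by
#' timepoint so both halves retain every timepoint), computes group-mean
#' log pathology per half, fits each candidate model — Euclidean,
#' anterograde-only, retrograde-only, bidirectional — on the training
#' half (time constants and weights), and scores the Pearson correlation
#' of its predictions against the held-out half. Pairwise superiority is
#' summarized by add-one empirical p-values over the paired iterations:
#' `p[A > B] = (1 + #\{r_A <= r_B\}) / (1 + n_iter)`.
#'
#' @inheritParams fit_spread_model
#' @param models Model types to compare.
#' @param n_iter Number of random half-splits (default 500).
#' @param rng_seed Integer seed controlling the splits.
#' @return Object of class `model_comparison`: `draws` (tibble of held-out
#'   r per iteration and model), `pairwise_p` (matrix, entry \[A, B\] =
#'   empirical p that model A beats model B), `n_iter`.
#' @export
crossval_compare <- function(data, connectome, seeds = connectome$seeds,
                             models = c("euclidean", "anterograde",
                                        "retrograde", "bidirectional"),
                             n_iter = 500, rng_seed = NULL,
                             timepoints = NULL, normalize = TRUE,
                             n_starts = 5) {
  models <- match.arg(models, several.ok = TRUE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x0 <- make_seed_vector(connectome, seeds)
  if (!is.null(timepoints)) data <- data[data$mpi %in% timepoints, ]
  mice <- dplyr::distinct(data, .data$mouse_id, .data$mpi)
  per_tp <- lapply(split(mice$mouse_id, mice$mpi), sort)
  too_few <- vapply(per_tp, length, integer(1)) < 4
  if (any(too_few)) {
    abort(sprintf("Need >= 4 mice per timepoint to split; timepoint(s) %s have fewer.",
                  paste(names(per_tp)[too_few], collapse = ", ")))
  }
  props <- build_props(connectome, models, normalize = normalize)
  comps <- lapply(setNames(models, models), function(m) {
    comps_for(props, m, x0)
  })
  draws <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    train_ids <- unlist(lapply(per_tp, function(ids) {
      sample(ids, floor(length(ids) / 2))
    }), use.names = FALSE)
    train <- data[data$mouse_id %in% train_ids, ]
    test <- data[!data$mouse_id %in% train_ids, ]
    Y_tr <- obs_matrix(train, connectome)
    Y_te <- obs_matrix(test, connectome, attr(Y_tr, "timepoints"))
    tp <- attr(Y_tr, "timepoints")
    r_te <- vapply(models, function(m) {
      eng <- tryCatch(fit_engine(Y_tr, tp, comps[[m]], n_starts = n_starts),
                      error = function(e) NULL)
      if (is.null(eng)) return(NA_real_)
      score_engine(eng, Y_te, tp, comps[[m]])
    }, numeric(1))
    draws[[it]] <- tibble::tibble(iter = it, model = models,
                                  r_test = unname(r_te))
  }
  draws <- dplyr::bind_rows(draws)
  wide <- tidyr::pivot_wider(draws, names_from = "model",
                             values_from = "r_test")
  pairwise_p <- matrix(NA_real_, length(models), length(models),
                       dimnames = list(models, models))
  for (a in models) {
    for (b in setdiff(models, a)) {
      ra <- wide[[a]]
      rb <- wide[[b]]
      keep <- is.finite(ra) & is.finite(rb)
      pairwise_p[a, b] <- (1 + sum(ra[keep] <= rb[keep])) / (1 + sum(keep))
    }
  }
  structure(
    list(draws = draws, pairwise_p = pairwise_p, n_iter = n_iter,
         models = models),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d half-split iterations\n", x$n_iter))
  med <- x$draws |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(median_r = median(.data$r_test, na.rm = TRUE),
                     .groups = "drop")
  for (i in seq_len(nrow(med))) {
    cat(sprintf("  %-13s median held-out r = %.4f\n",
                med$model[i], med$median_r[i]))
  }
  cat("  pairwise empirical p (row beats column):\n")
  print(round(x$pairwise_p, 4))
  invisible(x)
}

#' @describeIn crossval_compare Held-out correlations, one row per
#'   iteration and model.
#' @param x A `model_comparison`.
#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  x$draws
}

#' @describeIn crossval_compare One row per model: median and interquartile
#'   held-out r, and the empirical p that the model beats each rival.
#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  out <- x$draws |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      median_r = median(.data$r_test, na.rm = TRUE),
      q25_r = quantile(.data$r_test, 0.25, na.rm = TRUE),
      q75_r = quantile(.data$r_test, 0.75, na.rm = TRUE),
      .groups = "drop"
    )
  pbeat <- apply(x$pairwise_p, 1, max, na.rm = TRUE)
  out$max_p_vs_rivals <- pbeat[out$model]
  out
}
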