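# Core linear-diffusion machinery.
#
# The spread operator is expm(-c * t * t(L)) %*% x0, with L an out-degree
# Laplacian (D_out - A). Under this pairing -t(L) has non-negative
# off-diagonals and zero column sums, so the semigroup preserves
# non-negativity and total mass: pathology seeded at the injection sites
# redistributes along (anterograde) or against (retrograde) projections
# without being created or destroyed.
#
# Repeated evaluations at different rates dominate the fitting and
# resampling work, so the operator is applied through a one-off
# eigendecomposition of t(L): expm(-s t(L)) x0 = V exp(-s Lambda) V^-1 x0,
# an O(n^2) apply per candidate rate instead of a fresh O(n^3) matrix
# exponential. If the eigenbasis is numerically unreliable (defective or
# ill-conditioned Laplacian) the propagator falls back to Matrix::expm.

# Values below this are numerically indistinguishable from zero mass
# (the eigen route carries absolute error ~1e-13 at n ~ 200); they are
# clipped to exactly 0 and excluded from log-scale predictors.
.zero_tol <- 1e-12

propagator <- function(L) {
  Lt <- t(as.matrix(L))
  e <- eigen(Lt)
  Vinv <- tryCatch(solve(e$vectors), error = function(err) NULL)
  ok <- FALSE
  if (!is.null(Vinv)) {
    recon <- e$vectors %*% (e$values * Vinv)
    ok <- max(Mod(recon - Lt)) < 1e-8 * max(1, max(abs(Lt)))
  }
  structure(list(Lt = Lt, V = e$vectors, lam = e$values, Vinv = Vinv,
                 ok = ok, n = nrow(Lt)),
            class = "netspread_propagator")
}

# Project a seed vector into the eigenbasis (or keep it raw for the
# expm fallback).
prop_weights <- function(p, x0) {
  x0 <- as_x0(x0, p$n)
  if (p$ok) p$Vinv %*% x0 else x0
}

# Apply the semigroup at scaled times s = c * t. Returns an n x length(s)
# matrix of non-negative diffusion values.
prop_apply <- function(p, w, s) {
  if (p$ok) {
    E <- exp(outer(-p$lam, s))
    out <- Re(p$V %*% (E * as.vector(w)))
  } else {
    out <- vapply(
      s,
      function(si) as.numeric(Matrix::expm(-si * p$Lt) %*% w),
      numeric(p$n)
    )
    out <- matrix(out, nrow = p$n)
  }
  out[out < .zero_tol] <- 0
  out
}

as_x0 <- function(x0, n) {
  if (inherits(x0, "seed_vector")) x0 <- x0$x0
  x0 <- as.numeric(x0)
  if (length(x0) != n) {
    abort(sprintf("Seed vector has length %d but the system is %d-dimensional.",
                  length(x0), n))
  }
  x0
}

#' Diffuse seeded pathology along a graph Laplacian
#'
#' Evaluates the linear spread operator `expm(-c * t * t(L)) %*% x0`: the
#' distribution of pathology mass after `t` months of diffusion at global
#' rate `c` per month, starting from the seed indicator `x0`. Total mass is
#' conserved and entries stay non-negative (values below `1e-12` are
#' clipped to exactly zero).
#'
#' @param L Square Laplacian matrix (e.g. one of [build_laplacians()]).
#' @param c_rate Positive diffusion rate constant, per month.
#' @param t Non-negative time in months.
#' @param x0 A [make_seed_vector()] object or numeric indicator vector.
#' @return Numeric vector of diffusion values, named like `L`'s rows.
#' @export
#' @examples
#' L <- matrix(c(1, -1, -1, 1), 2, 2)  # symmetric 2-node graph
#' diffuse(L, c_rate = 1, t = log(2) / 2, x0 = c(1, 0))  # -> 0.75, 0.25
diffuse <- function(L, c_rate, t, x0) {
  stop_if_not_scalar_number(c_rate, "c_rate", positive = TRUE)
  stop_if_not_scalar_number(t, "t", nonneg = TRUE)
  p <- if (inherits(L, "netspread_propagator")) L else propagator(L)
  x0n <- as_x0(x0, p$n)
  if (t == 0) {
    return(setNames(x0n, rownames(p$Lt)))
  }
  out <- prop_apply(p, prop_weights(p, x0n), c_rate * t)[, 1]
  setNames(out, rownames(p$Lt))
}

#' Log-scale diffusion predictor with usability mask
#'
#' The model regresses observed log10 pathology on `log10` of the diffusion
#' values. Regions whose diffusion value is (numerically) zero — e.g.
#' unreachable from the seeds — have no defined log predictor and are
#' masked out.
#'
#' @inheritParams diffuse
#' @return A tibble with columns `region` (label), `value` (log10 diffusion
#'   value, `NA` where masked) and `usable` (logical).
#' @export
spread_predictor <- function(L, c_rate, t, x0) {
  d <- diffuse(L, c_rate, t, x0)
  value <- ifelse(d > 0, log10(d), NA_real_)
  tibble::tibble(
    region = names(d) %||% as.character(seq_along(d)),
    value = value,
    usable = d > 0
  )
}

# ---------------------------------------------------------------------------
# Observed group-level pathology: regions x timepoints matrix of
# log10(mean percent area), NA where the mean is zero/missing or the
# region has no connectivity data.

obs_matrix <- function(data, cn, timepoints = NULL) {
  labels <- rownames(cn$adjacency)
  lab <- region_label(data$region, data$hemisphere)
  dropped <- setdiff(unique(lab), labels)
  tp <- sort(unique(data$mpi))
  if (!is.null(timepoints)) tp <- sort(timepoints)
  Y <- matrix(NA_real_, length(labels), length(tp),
              dimnames = list(labels, as.character(tp)))
  keep <- lab %in% labels
  for (k in seq_along(tp)) {
    sel <- keep & data$mpi == tp[k]
    if (!any(sel)) next
    m <- tapply(data$pct_area[sel], lab[sel], mean)
    v <- ifelse(m > 0, log10(m), NA_real_)
    Y[names(m), k] <- v
  }
  attr(Y, "timepoints") <- tp
  attr(Y, "dropped_regions") <- dropped
  Y
}

#' Group-mean regional pathology profile
#'
#' Averages percent area occupied across the mice in `data` for every
#' (region, hemisphere, timepoint) and attaches the log10 value used as the
#' modelling outcome (`NA` where the mean is zero, since log10(0) is
#' undefined) and whether the region has connectivity data.
#'
#' @param data A region table (see [simulate_pathology()] /
#'   [read_region_table()]).
#' @param connectome A [connectome].
#' @return Tibble with columns `acronym`, `hemisphere`, `mpi`,
#'   `mean_pct_area`, `log10_pct`, `in_connectome`.
#' @export
pathology_profile <- function(data, connectome) {
  labels <- rownames(connectome$adjacency)
  data |>
    dplyr::group_by(.data$region, .data$hemisphere, .data$mpi) |>
    dplyr::summarise(mean_pct_area = mean(.data$pct_area),
                     .groups = "drop") |>
    dplyr::mutate(
      log10_pct = dplyr::if_else(.data$mean_pct_area > 0,
                                 log10(.data$mean_pct_area), NA_real_),
      in_connectome = region_label(.data$region, .data$hemisphere) %in%
        labels
    ) |>
    dplyr::rename(acronym = "region")
}

# ---------------------------------------------------------------------------
# Fitting engine. `comps` is a named list of spread components
# ("a" anterograde, "r" retrograde, "e" Euclidean proximity), each holding
# a propagator and the eigen-projected seed weights. The linear step is
# re-solved by OLS at every candidate rate vector; the objective is the
# pooled Pearson r between fitted and observed log pathology.

component_predictors <- function(comps, rates, timepoints) {
  lapply(seq_along(comps), function(i) {
    D <- prop_apply(comps[[i]]$prop, comps[[i]]$w, rates[i] * timepoints)
    P <- matrix(NA_real_, nrow(D), ncol(D))
    pos <- D > 0
    P[pos] <- log10(D[pos])
    P
  })
}

linear_step <- function(Y, Plist) {
  yv <- as.vector(Y)
  Xp <- vapply(Plist, as.vector, numeric(length(yv)))
  Xp <- matrix(Xp, ncol = length(Plist))
  ok <- is.finite(yv) & apply(is.finite(Xp), 1, all)
  n_ok <- sum(ok)
  if (n_ok < 3) {
    return(list(status = "too_few", n = n_ok))
  }
  X <- cbind(1, Xp[ok, , drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    return(list(status = "collinear", n = n_ok))
  }
  beta <- qr.coef(qrx, yv[ok])
  fitted <- drop(X %*% beta)
  r <- suppressWarnings(cor(fitted, yv[ok]))
  if (!is.finite(r)) {
    return(list(status = "degenerate", n = n_ok))
  }
  list(status = "ok", beta = beta, r = r, ok = ok, n = n_ok,
       fitted = fitted, y = yv[ok], X = X)
}

fit_engine <- function(Y, timepoints, comps,
                       n_starts = 5, rate_range = c(1e-3, 1e2),
                       reltol = 1e-6, maxit = 500) {
  k <- length(comps)
  lr <- log(rate_range)
  objective <- function(theta) {
    Plist <- component_predictors(comps, exp(theta), timepoints)
    ls <- linear_step(Y, Plist)
    if (ls$status != "ok") return(2)  # worse than any attainable -r
    -ls$r
  }
  if (k == 1) {
    opt <- optimize(objective, interval = lr, tol = 1e-8)
    best <- list(par = opt$minimum, value = opt$objective)
    starts_used <- 1L
  } else {
    grid1 <- seq(lr[1], lr[2], length.out = 7)
    grid <- as.matrix(expand.grid(rep(list(grid1), k)))
    vals <- apply(grid, 1, objective)
    ord <- order(vals)[seq_len(min(n_starts, nrow(grid)))]
    runs <- lapply(ord, function(i) {
      optim(grid[i, ], objective, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit))
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    starts_used <- length(runs)
  }
  if (best$value >= 2) {
    abort(paste0("Diffusion model fit failed from every start: fewer than ",
                 "3 usable observations or collinear predictors."))
  }
  rates <- exp(best$par)
  Plist <- component_predictors(comps, rates, timepoints)
  ls <- linear_step(Y, Plist)
  beta <- ls$beta
  # standardized betas: z-score pooled predictors and outcome, re-solve
  Xs <- scale(ls$X[, -1, drop = FALSE])
  std_beta <- rep(NA_real_, k)
  if (all(is.finite(attr(Xs, "scaled:scale"))) &&
      all(attr(Xs, "scaled:scale") > 0) && sd(ls$y) > 0) {
    std_beta <- qr.coef(qr(cbind(1, Xs)), as.vector(scale(ls$y)))[-1]
  }
  # per-timepoint detail
  pred_mat <- matrix(beta[1], nrow(Y), ncol(Y))
  for (i in seq_len(k)) pred_mat <- pred_mat + beta[i + 1] * Plist[[i]]
  used <- is.finite(as.vector(Y)) &
    apply(is.finite(matrix(vapply(Plist, as.vector,
                                  numeric(length(Y))), ncol = k)), 1, all)
  used <- matrix(used, nrow(Y), ncol(Y))
  r_by_t <- vapply(seq_len(ncol(Y)), function(j) {
    u <- used[, j]
    if (sum(u) < 3) return(NA_real_)
    suppressWarnings(cor(pred_mat[u, j], Y[u, j]))
  }, numeric(1))
  list(
    rates = setNames(rates, names(comps)),
    beta0 = unname(beta[1]),
    betas = setNames(unname(beta[-1]), names(comps)),
    std_betas = setNames(unname(std_beta), names(comps)),
    r_pooled = ls$r,
    r_by_timepoint = setNames(r_by_t, colnames(Y)),
    n_used = setNames(colSums(used), colnames(Y)),
    predicted = pred_mat,
    used = used
  )
}

# Score fitted parameters against a held-out observation matrix: Pearson r
# between the model's predictions (train-fitted betas and rates) and the
# test log pathology, over jointly usable entries.
score_engine <- function(eng, Y_test, timepoints, comps) {
  Plist <- component_predictors(comps, eng$rates, timepoints)
  pred <- matrix(eng$beta0, nrow(Y_test), ncol(Y_test))
  for (i in seq_along(comps)) pred <- pred + eng$betas[i] * Plist[[i]]
  ok <- is.finite(as.vector(Y_test)) & is.finite(as.vector(pred))
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(cor(as.vector(pred)[ok], as.vector(Y_test)[ok]))
}

model_components <- function(model) {
  switch(model,
    bidirectional = c("a", "r"),
    anterograde = "a",
    retrograde = "r",
    euclidean = "e",
    abort(sprintf("Unknown model type \"%s\".", model))
  )
}

# Build the propagators a set of models needs, once per connectome.
build_props <- function(cn, models, normalize = TRUE) {
  need <- unique(unlist(lapply(models, model_components)))
  props <- list()
  if (any(c("a", "r") %in% need)) {
    cnn <- if (normalize) normalize_by_source_size(cn) else cn
    pair <- build_laplacians(cnn)
    if ("a" %in% need) props$a <- propagator(pair$L_a)
    if ("r" %in% need) props$r <- propagator(pair$L_r)
  }
  if ("e" %in% need) props$e <- propagator(euclidean_laplacian(cn))
  props
}

comps_for <- function(props, model, x0) {
  keys <- model_components(model)
  comps <- lapply(keys, function(kk) {
    list(prop = props[[kk]], w = prop_weights(props[[kk]], x0))
  })
  names(comps) <- keys
  comps
}

# ---------------------------------------------------------------------------
# User-facing fits

#' Fit a connectome diffusion model of pathology spread
#'
#' Fits the linear spread model
#' \deqn{\hat y(t) = \beta_0 + \beta_a \log_{10} e^{-c_a L_a t} x_0 +
#'   \beta_r \log_{10} e^{-c_r L_r t} x_0}
#' to group-mean log10 regional pathology, jointly optimizing the time
#' constants (derivative-free search on the log scale, multi-started) with
#' the linear weights re-solved by least squares at every candidate, to
#' maximize the pooled Pearson correlation between predicted and observed
#' values across all supplied timepoints. Unidirectional variants drop one
#' term; the Euclidean variant replaces connectivity with an
#' inverse-distance proximity graph (see [euclidean_predictor()]).
#'
#' A region-timepoint observation enters the fit only if the observed mean
#' percent area is positive, every required diffusion predictor is
#' positive, and the region is present in the connectome.
#'
#' @param data Region table of per-mouse pathology (columns `mouse_id`,
#'   `mpi`, `hemisphere`, `region`, `pct_area`, ...).
#' @param connectome A [connectome].
#' @param seeds Character vector of seed acronyms (default: seeds stored in
#'   the connectome).
#' @param model One of `"bidirectional"`, `"anterograde"`, `"retrograde"`,
#'   `"euclidean"`.
#' @param timepoints Optional subset of `mpi` values to fit on (default:
#'   all present in `data`).
#' @param normalize Divide projection strengths by source-region size
#'   before building Laplacians (default `TRUE`).
#' @param n_starts Number of Nelder-Mead multi-starts seeded from a coarse
#'   log-spaced grid of rate constants.
#' @param rate_range Search range for the rate constants, per month.
#' @param reltol Relative convergence tolerance on the objective.
#' @return An object of class `diffusion_fit`. Use [tidy()] for the
#'   region-level table, [glance()] for the one-row parameter summary, and
#'   [autoplot()] for an observed-vs-predicted plot.
#' @seealso [fit_bidirectional()], [standardized_betas()]
#' @export
fit_spread_model <- function(data, connectome, seeds = connectome$seeds,
                             model = c("bidirectional", "anterograde",
                                       "retrograde", "euclidean"),
                             timepoints = NULL, normalize = TRUE,
                             n_starts = 5, rate_range = c(1e-3, 1e2),
                             reltol = 1e-6) {
  model <- match.arg(model)
  x0 <- make_seed_vector(connectome, seeds)
  Y <- obs_matrix(data, connectome, timepoints)
  dropped <- attr(Y, "dropped_regions")
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d region(s) in the pathology table have no connectivity data and were dropped.",
      length(dropped)))
  }
  props <- build_props(connectome, model, normalize = normalize)
  comps <- comps_for(props, model, x0)
  tp <- attr(Y, "timepoints")
  eng <- fit_engine(Y, tp, comps, n_starts = n_starts,
                    rate_range = rate_range, reltol = reltol)
  new_diffusion_fit(eng, Y, tp, model, connectome, x0)
}

new_diffusion_fit <- function(eng, Y, tp, model, cn, x0) {
  detail <- tibble::tibble(
    region = rep(rownames(Y), times = ncol(Y)),
    acronym = rep(cn$regions$acronym, times = ncol(Y)),
    hemisphere = rep(cn$regions$hemisphere, times = ncol(Y)),
    mpi = rep(tp, each = nrow(Y)),
    observed = as.vector(Y),
    predicted = as.vector(eng$predicted),
    used = as.vector(eng$used)
  ) |>
    dplyr::mutate(residual = .data$observed - .data$predicted)
  structure(
    list(
      model = model,
      beta0 = eng$beta0,
      betas = eng$betas,
      std_betas = eng$std_betas,
      rates = eng$rates,
      r_pooled = eng$r_pooled,
      r_by_timepoint = eng$r_by_timepoint,
      n_used = eng$n_used,
      timepoints = tp,
      detail = detail,
      seeds = x0$seed_acronyms
    ),
    class = "diffusion_fit"
  )
}

#' Fit the bidirectional spread model
#'
#' Convenience wrapper for [fit_spread_model()] with
#' `model = "bidirectional"`: anterograde and retrograde diffusion
#' predictors, each with its own time constant and regression weight.
#'
#' @inheritParams fit_spread_model
#' @param ... Passed on to [fit_spread_model()].
#' @return A `diffusion_fit`.
#' @export
fit_bidirectional <- function(data, connectome, seeds = connectome$seeds,
                              ...) {
  fit_spread_model(data, connectome, seeds, model = "bidirectional", ...)
}

#' Linear fit of pathology on diffusion predictors at fixed time constants
#'
#' Solves only the linear step of the spread model: ordinary least squares
#' of observed log10 group-mean pathology on the anterograde and retrograde
#' log-diffusion predictors evaluated at the supplied `c_a`, `c_r`, pooling
#' region-timepoint observations.
#'
#' @inheritParams fit_spread_model
#' @param c_a,c_r Positive anterograde / retrograde time constants, per
#'   month.
#' @return A one-row tibble: `beta0`, `beta_a`, `beta_r`, `r_pooled`,
#'   `n_used`.
#' @export
fit_linear_given_constants <- function(data, connectome,
                                       seeds = connectome$seeds,
                                       c_a, c_r, timepoints = NULL,
                                       normalize = TRUE) {
  stop_if_not_scalar_number(c_a, "c_a", positive = TRUE)
  stop_if_not_scalar_number(c_r, "c_r", positive = TRUE)
  x0 <- make_seed_vector(connectome, seeds)
  Y <- obs_matrix(data, connectome, timepoints)
  props <- build_props(connectome, "bidirectional", normalize = normalize)
  comps <- comps_for(props, "bidirectional", x0)
  Plist <- component_predictors(comps, c(c_a, c_r), attr(Y, "timepoints"))
  ls <- linear_step(Y, Plist)
  if (ls$status == "too_few") {
    abort(sprintf("Only %d usable observations after masking; need >= 3.",
                  ls$n))
  }
  if (ls$status %in% c("collinear", "degenerate")) {
    abort("Diffusion predictors are collinear (or outcome is constant); cannot solve the linear step.")
  }
  tibble::tibble(
    beta0 = ls$beta[1], beta_a = ls$beta[2], beta_r = ls$beta[3],
    r_pooled = ls$r, n_used = ls$n
  )
}

#' Standardized regression weights of a fitted spread model
#'
#' Re-solves the linear step after z-scoring each diffusion predictor and
#' the outcome over the pooled usable observations, yielding
#' scale-free weights comparable across directions and groups.
#'
#' @param fit A `diffusion_fit`.
#' @return Named numeric vector of standardized slopes (`a`, `r` for the
#'   bidirectional model).
#' @export
standardized_betas <- function(fit) {
  stopifnot(inherits(fit, "diffusion_fit"))
  if (anyNA(fit$std_betas)) {
    abort("A predictor or the outcome has zero variance; standardized weights are undefined.")
  }
  fit$std_betas
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %s model, %d timepoint(s)\n",
              x$model, length(x$timepoints)))
  cat(sprintf("  pooled Pearson r = %.4f\n", x$r_pooled))
  cat("  rates (/month):",
      paste(sprintf("c_%s = %.4g", names(x$rates), x$rates),
            collapse = ", "), "\n")
  cat("  weights:", sprintf("beta0 = %.4g", x$beta0),
      paste(sprintf("beta_%s = %.4g", names(x$betas), x$betas),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_spread_model Region-timepoint table of observed,
#'   predicted and residual log10 pathology with usability flags.
#' @param x A `diffusion_fit`.
#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  x$detail
}

#' @describeIn fit_spread_model One-row summary: model, coefficients, time
#'   constants, standardized weights, pooled and per-timepoint Pearson r.
#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  grab <- function(v, kk) if (kk %in% names(v)) unname(v[kk]) else NA_real_
  out <- tibble::tibble(
    model = x$model,
    beta0 = x$beta0,
    beta_a = grab(x$betas, "a"), beta_r = grab(x$betas, "r"),
    beta_e = grab(x$betas, "e"),
    c_a = grab(x$rates, "a"), c_r = grab(x$rates, "r"),
    c_e = grab(x$rates, "e"),
    std_beta_a = grab(x$std_betas, "a"),
    std_beta_r = grab(x$std_betas, "r"),
    r_pooled = x$r_pooled,
    n_used = sum(x$n_used)
  )
  for (tt in names(x$r_by_timepoint)) {
    out[[paste0("r_t", tt)]] <- unname(x$r_by_timepoint[tt])
  }
  out
}
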