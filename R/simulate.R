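# Synthetic study generator: a bilateral directed connectome with region
# metadata, ipsilateral injection seeds, and per-mouse regional pathology
# drawn from the bidirectional diffusion model with known parameters.
# Every downstream stage (fitting, permutation null, cross-validation,
# bootstrap, regional statistics) is testable against this ground truth.

#' Configuration for the synthetic study generator
#'
#' @param n_regions Regions per hemisphere (the connectome has
#'   `2 * n_regions` regions).
#' @param edge_density Probability of a directed edge between two distinct
#'   regions, in (0, 1].
#' @param weight_scale Target mean out-strength (mean row sum) of the
#'   source-size-normalized adjacency. Edge weights are log-normal
#'   (meanlog 0, sdlog 1) — emulating the orders-of-magnitude spread of
#'   tract-tracing projection strengths — and then globally rescaled to
#'   this out-strength. It sets the intrinsic mixing timescale of the
#'   connectome: the default 0.25 makes diffusion over a months-scale
#'   experiment partial rather than instantaneous, as in real
#'   progressive spread, keeping the time constants identifiable.
#' @param n_seeds Number of ipsilateral injection-site regions (default 5,
#'   matching a five-site hippocampal/cortical injection scheme).
#' @param true_params Named numeric vector with entries `beta0`, `beta_a`,
#'   `beta_r` (regression weights) and `c_a`, `c_r` (positive time
#'   constants, per month) of the generating bidirectional model.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   log10 pathology scale, per mouse and region; `>= 0`.
#' @param n_mice_per_group Mice per experimental group at each timepoint.
#' @param timepoints Months post-injection at which cohorts are sampled.
#' @param group_effects Named list/vector mapping each group label
#'   (convention `"GENOTYPE_TREATMENT"`, e.g. `"WT_0"`, `"G2019S_450"`) to
#'   an additive log10 shift: either a single number applied to every
#'   region, or a named vector keyed by region label
#'   (`"<acronym>_<hemisphere>"`) with unnamed regions shifted by 0.
#' @param sex_effect Additive log10 shift applied to male mice (default 0).
#' @param rng_seed Integer seed; the connectome uses `rng_seed` and the
#'   pathology draw uses `rng_seed + 1`, so the pair is jointly
#'   deterministic.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_regions = 100,
                              edge_density = 0.2,
                              weight_scale = 0.25,
                              n_seeds = 5,
                              true_params = c(beta0 = -1, beta_a = 1,
                                              beta_r = 0.5, c_a = 0.5,
                                              c_r = 2),
                              noise_sd = 0.05,
                              n_mice_per_group = 8,
                              timepoints = c(3, 6),
                              group_effects = list(WT_0 = 0),
                              sex_effect = 0,
                              rng_seed = 1L) {
  stop_if_not_count(n_regions, "n_regions")
  stop_if_not_scalar_number(edge_density, "edge_density")
  if (edge_density <= 0 || edge_density > 1) {
    abort("`edge_density` must lie in (0, 1].")
  }
  stop_if_not_scalar_number(weight_scale, "weight_scale", positive = TRUE)
  stop_if_not_count(n_seeds, "n_seeds")
  need <- c("beta0", "beta_a", "beta_r", "c_a", "c_r")
  if (!all(need %in% names(true_params))) {
    abort(paste0("`true_params` must name: ", paste(need, collapse = ", ")))
  }
  if (true_params[["c_a"]] <= 0 || true_params[["c_r"]] <= 0) {
    abort("`true_params[c_a]` and `true_params[c_r]` must be > 0.")
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stop_if_not_count(n_mice_per_group, "n_mice_per_group")
  if (length(timepoints) < 1 || any(timepoints <= 0)) {
    abort("`timepoints` must be positive months.")
  }
  if (is.null(names(group_effects)) || any(names(group_effects) == "")) {
    abort("`group_effects` must be a named list of group labels.")
  }
  stop_if_not_scalar_number(sex_effect, "sex_effect")
  stop_if_not_count(rng_seed, "rng_seed", min = 0L)
  structure(
    list(n_regions = as.integer(n_regions), edge_density = edge_density,
         weight_scale = weight_scale, n_seeds = as.integer(n_seeds),
         true_params = true_params[need], noise_sd = noise_sd,
         n_mice_per_group = as.integer(n_mice_per_group),
         timepoints = sort(unique(timepoints)),
         group_effects = as.list(group_effects), sex_effect = sex_effect,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

# Strong connectivity via boolean reachability (repeated squaring of the
# adjacency-plus-identity indicator); self-contained so the test suite can
# use an independent graph-library oracle.
is_strongly_connected <- function(A) {
  M <- (A > 0) | diag(nrow(A)) > 0
  steps <- ceiling(log2(max(2, nrow(A))))
  for (i in seq_len(steps)) {
    M <- (M %*% M) > 0
    if (all(M)) return(TRUE)
  }
  all(M)
}

#' Generate a bilateral synthetic connectome
#'
#' Draws a strongly connected directed graph over `2 * n_regions` regions
#' (ipsi and contra hemispheres): edges are independent Bernoulli draws at
#' `edge_density`, weights log-normal (meanlog 0, sdlog 1) scaled by
#' `weight_scale`. Region centroids are uniform in a 10 x 10 x 10 mm box
#' in the ipsilateral hemisphere and mirrored across the midline for the
#' contralateral one; sizes are log-normal and mirrored bilaterally.
#' Generation is rejection-resampled until the graph is strongly
#' connected. `n_seeds` ipsilateral regions are sampled as the injection
#' sites and stored on the connectome.
#'
#' @param config A [simulation_config()].
#' @param max_attempts Resampling attempts before giving up.
#' @return A [connectome] with a `seeds` element.
#' @export
generate_connectome <- function(config, max_attempts = 50) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_seeds > config$n_regions) {
    abort("`n_seeds` cannot exceed `n_regions` (seeds are ipsilateral).")
  }
  set.seed(config$rng_seed)
  n <- config$n_regions
  N <- 2L * n
  acr <- sprintf("R%03d", seq_len(n))
  hemi <- rep(c("ipsi", "contra"), each = n)
  size <- rep(exp(rnorm(n, 0, 0.3)), 2)
  cen_ipsi <- matrix(runif(3 * n, 0, 10), n, 3)
  cen <- rbind(cen_ipsi, cen_ipsi * cbind(rep(-1, n), 1, 1))
  parent <- rep(sprintf("P%02d", ceiling(seq_len(n) / 5)), 2)
  n_dau <- rep(rpois(n, 2), 2)
  regions <- tibble::tibble(
    acronym = rep(acr, 2), hemisphere = hemi, size = size,
    x = cen[, 1], y = cen[, 2], z = cen[, 3],
    parent_acronym = parent, n_daughters = n_dau
  )
  A <- NULL
  for (attempt in seq_len(max_attempts)) {
    edges <- matrix(rbinom(N * N, 1, config$edge_density), N, N)
    diag(edges) <- 0
    W <- matrix(0, N, N)
    ne <- sum(edges)
    W[edges == 1] <- exp(rnorm(ne, 0, 1))
    # rescale so the size-normalized connectome has the configured mean
    # out-strength (sets the mixing timescale; see `weight_scale`)
    W <- W * config$weight_scale / mean(rowSums(W / size))
    if (is_strongly_connected(W)) {
      A <- W
      break
    }
  }
  if (is.null(A)) {
    abort(sprintf(
      "Could not draw a strongly connected graph in %d attempts; increase `edge_density` or `n_regions`.",
      max_attempts))
  }
  seeds <- sort(sample(acr, config$n_seeds))
  connectome(A, regions, seeds = seeds)
}

parse_group_label <- function(label) {
  if (grepl("_", label)) {
    genotype <- sub("_[^_]*$", "", label)
    treatment <- suppressWarnings(as.numeric(sub("^.*_", "", label)))
    if (is.na(treatment)) {
      genotype <- label
      treatment <- 0
    }
  } else {
    genotype <- label
    treatment <- 0
  }
  list(genotype = genotype, treatment = treatment)
}

#' Simulate per-mouse regional pathology from the bidirectional model
#'
#' For every group, timepoint and mouse, regional percent area occupied is
#' `10^(yhat + group effect + sex effect + N(0, noise_sd))`, where `yhat`
#' is the noiseless bidirectional model prediction at the configured true
#' parameters (connectome normalized by source-region size, as in the
#' fitting pipeline). Regions whose diffusion value is exactly zero for a
#' required direction receive pathology 0. Mice are cross-sectional: each
#' mouse is measured at a single timepoint, with sexes alternating M/F
#' within each cohort.
#'
#' @param connectome A [connectome] carrying seeds (from
#'   [generate_connectome()] or with `seeds` set).
#' @param config The [simulation_config()] used to generate it.
#' @param groups Character vector of group labels to simulate; defaults to
#'   `names(config$group_effects)`. Each label must have an entry in
#'   `group_effects`.
#' @return A region table: tibble with columns `mouse_id`, `genotype`,
#'   `treatment`, `sex`, `mpi`, `hemisphere`, `region`, `n_daughters`,
#'   `pct_area`.
#' @export
simulate_pathology <- function(connectome, config,
                               groups = names(config$group_effects)) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(config, "simulation_config"))
  missing_eff <- setdiff(groups, names(config$group_effects))
  if (length(missing_eff) > 0) {
    abort(paste0("No group effect entry for group(s): ",
                 paste(missing_eff, collapse = ", ")))
  }
  set.seed(config$rng_seed + 1L)
  x0 <- make_seed_vector(connectome)
  props <- build_props(connectome, "bidirectional", normalize = TRUE)
  comps <- comps_for(props, "bidirectional", x0)
  tp <- config$timepoints
  pars <- config$true_params
  labels <- rownames(connectome$adjacency)
  N <- length(labels)

  D_a <- prop_apply(comps$a$prop, comps$a$w, pars[["c_a"]] * tp)
  D_r <- prop_apply(comps$r$prop, comps$r$w, pars[["c_r"]] * tp)
  # noiseless log10 prediction; a region is expressible only where every
  # direction with non-zero weight has positive diffusion mass
  usable <- matrix(TRUE, N, length(tp))
  if (pars[["beta_a"]] != 0) usable <- usable & (D_a > 0)
  if (pars[["beta_r"]] != 0) usable <- usable & (D_r > 0)
  yhat <- matrix(pars[["beta0"]], N, length(tp))
  if (pars[["beta_a"]] != 0) yhat <- yhat + pars[["beta_a"]] * log10(pmax(D_a, .zero_tol))
  if (pars[["beta_r"]] != 0) yhat <- yhat + pars[["beta_r"]] * log10(pmax(D_r, .zero_tol))
  yhat[!usable] <- NA_real_

  region_shift <- function(eff) {
    if (length(eff) == 1 && is.null(names(eff))) {
      rep(as.numeric(eff), N)
    } else {
      out <- setNames(numeric(N), labels)
      known <- intersect(names(eff), labels)
      bad <- setdiff(names(eff), labels)
      if (length(bad) > 0) {
        abort(paste0("Group effect names not in the connectome: ",
                     paste(head(bad, 5), collapse = ", ")))
      }
      out[known] <- as.numeric(eff[known])
      unname(out)
    }
  }

  rows <- list()
  mouse_counter <- 0L
  for (g in groups) {
    gl <- parse_group_label(g)
    shift <- region_shift(config$group_effects[[g]])
    for (k in seq_along(tp)) {
      for (m in seq_len(config$n_mice_per_group)) {
        mouse_counter <- mouse_counter + 1L
        sex <- if (m %% 2 == 1) "F" else "M"
        eps <- if (config$noise_sd > 0) rnorm(N, 0, config$noise_sd) else numeric(N)
        logv <- yhat[, k] + shift + config$sex_effect * (sex == "M") + eps
        pct <- ifelse(is.na(logv), 0, 10^logv)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mouse_id = sprintf("m%04d", mouse_counter),
          genotype = gl$genotype,
          treatment = gl$treatment,
          sex = sex,
          mpi = tp[k],
          hemisphere = connectome$regions$hemisphere,
          region = connectome$regions$acronym,
          n_daughters = connectome$regions$n_daughters,
          pct_area = pct
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
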