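test_that("diffusion matches the closed form on a 2-node symmetric graph", {
  L <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(unname(diffuse(L, 1, 0, c(1, 0))), c(1, 0))
  # eigenvalues 0 and 2: masses (1 + e^(-2ct))/2 and (1 - e^(-2ct))/2
  out <- diffuse(L, 1, log(2) / 2, c(1, 0))
  expect_equal(unname(out), c(0.75, 0.25), tolerance = 1e-10)
  p <- spread_predictor(L, 1, log(2) / 2, c(1, 0))
  expect_equal(p$value[1], log10(0.75), tolerance = 1e-10)
  expect_equal(round(p$value[1], 4), -0.1249)
})

test_that("diffusion agrees with a truncated-series oracle on 5-node graphs", {
  for (s in 1:5) {
    set.seed(s)
    L <- random_laplacian(5)
    x0 <- c(1, 0, 0, 1, 0)
    for (ct in c(0.1, 1, 3)) {
      ours <- diffuse(L, ct, 1, x0)
      oracle <- as.vector(expm_series(-ct * t(L)) %*% x0)
      expect_equal(unname(ours), oracle, tolerance = 1e-8)
    }
  }
})

test_that("diffusion agrees with Matrix::expm on a larger random graph", {
  set.seed(9)
  L <- random_laplacian(30, density = 0.3)
  x0 <- as.numeric(seq_len(30) <= 3)
  ours <- diffuse(L, 0.7, 2.5, x0)
  oracle <- as.numeric(Matrix::expm(-0.7 * 2.5 * t(L)) %*% x0)
  expect_equal(unname(ours), oracle, tolerance = 1e-9)
})

test_that("diffusion conserves mass and stays non-negative", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(5:25, 1)
    L <- random_laplacian(n, density = 0.4)
    x0 <- as.numeric(seq_len(n) %in% sample(n, 3))
    for (tt in c(0, 0.5, 2, 10)) {
      out <- diffuse(L, 1, tt, x0)
      expect_true(all(out >= 0))
      expect_equal(sum(out), sum(x0), tolerance = 1e-8)
    }
  }
})

test_that("diffusion satisfies the semigroup property", {
  set.seed(21)
  L <- random_laplacian(12, density = 0.5)
  x0 <- as.numeric(seq_len(12) <= 2)
  one_shot <- diffuse(L, 1, 1.3 + 0.9, x0)
  two_step <- diffuse(L, 1, 0.9, unname(diffuse(L, 1, 1.3, x0)))
  expect_equal(unname(one_shot), unname(two_step), tolerance = 1e-8)
})

test_that("predictor masks unreachable regions and none on connected graphs", {
  # two disconnected 2-node components: mass cannot reach the second
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  L <- diag(rowSums(A)) - A
  p <- spread_predictor(L, 1, 2, c(1, 0, 0, 0))
  expect_equal(p$usable, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(p$value[3:4])))

  cn <- small_study()$cn
  pair <- build_laplacians(normalize_by_source_size(cn))
  x0 <- make_seed_vector(cn)
  p2 <- spread_predictor(pair$L_a, 0.5, 3, x0)
  expect_true(all(p2$usable))
})

test_that("diffuse validates dimensions and arguments", {
  L <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_error(diffuse(L, 1, 1, c(1, 0, 0)), "length 3")
  expect_error(diffuse(L, -1, 1, c(1, 0)), "> 0")
  expect_error(diffuse(L, 1, -1, c(1, 0)), ">= 0")
})

test_that("linear step recovers exact coefficients from noiseless outcomes", {
  st <- small_study()
  cn <- st$cn
  pair <- build_laplacians(normalize_by_source_size(cn))
  x0 <- make_seed_vector(cn)
  b <- c(beta0 = 0.5, beta_a = 2, beta_r = -1)
  rows <- lapply(c(3, 6), function(tt) {
    pa <- spread_predictor(pair$L_a, 0.4, tt, x0)
    pr <- spread_predictor(pair$L_r, 1.2, tt, x0)
    tibble::tibble(
      mouse_id = paste0("m", tt), genotype = "WT", treatment = 0,
      sex = "F", mpi = tt,
      hemisphere = cn$regions$hemisphere, region = cn$regions$acronym,
      n_daughters = 0L,
      pct_area = 10^(b[1] + b[2] * pa$value + b[3] * pr$value)
    )
  })
  dat <- dplyr::bind_rows(rows)
  fit <- fit_linear_given_constants(dat, cn, c_a = 0.4, c_r = 1.2)
  expect_equal(fit$beta0, unname(b[1]), tolerance = 1e-8)
  expect_equal(fit$beta_a, unname(b[2]), tolerance = 1e-8)
  expect_equal(fit$beta_r, unname(b[3]), tolerance = 1e-8)
  expect_equal(fit$r_pooled, 1, tolerance = 1e-8)
})

test_that("linear step rejects collinear predictors on a symmetric graph", {
  n <- 6
  set.seed(3)
  regs <- tibble::tibble(
    acronym = sprintf("R%02d", 1:n), hemisphere = "ipsi", size = 1,
    x = runif(n, 0, 5), y = runif(n, 0, 5), z = runif(n, 0, 5)
  )
  A <- matrix(runif(n * n), n, n) * 0.1
  A <- (A + t(A)) / 2
  diag(A) <- 0
  cn <- connectome(A, regs, seeds = "R01")
  dat <- tibble::tibble(
    mouse_id = "m1", genotype = "WT", treatment = 0, sex = "F", mpi = 3,
    hemisphere = "ipsi", region = regs$acronym, n_daughters = 0L,
    pct_area = runif(n, 0.1, 1)
  )
  expect_error(fit_linear_given_constants(dat, cn, c_a = 1, c_r = 1),
               "collinear")
})

test_that("pure-noise outcomes yield negligible pooled correlation", {
  st <- small_study(n_regions = 100, edge_density = 0.2, rng_seed = 7)
  cn <- st$cn
  rs <- vapply(1:3, function(s) {
    set.seed(400 + s)
    dat <- tibble::tibble(
      mouse_id = "m1", genotype = "WT", treatment = 0, sex = "F", mpi = 3,
      hemisphere = cn$regions$hemisphere, region = cn$regions$acronym,
      n_daughters = 0L,
      pct_area = 10^rnorm(nrow(cn$regions))
    )
    fit_linear_given_constants(dat, cn, c_a = 0.5, c_r = 2)$r_pooled
  }, numeric(1))
  expect_true(all(abs(rs) < 0.2))
})

test_that("bidirectional fit recovers generating parameters", {
  st <- small_study(n_regions = 100, edge_density = 0.2, rng_seed = 7)
  fit <- fit_bidirectional(st$dat, st$cn)
  truth <- st$cfg$true_params
  expect_lt(abs(fit$rates["a"] - truth["c_a"]) / truth["c_a"], 0.10)
  expect_lt(abs(fit$rates["r"] - truth["c_r"]) / truth["c_r"], 0.10)
  expect_equal(unname(fit$betas["a"]), unname(truth["beta_a"]),
               tolerance = 0.1)
  expect_equal(unname(fit$betas["r"]), unname(truth["beta_r"]),
               tolerance = 0.1)
  expect_gt(fit$r_pooled, 0.99)
  expect_true(all(fit$rates > 0))
  expect_true(all(abs(fit$r_by_timepoint) <= 1))
})

test_that("noiseless data are fitted essentially perfectly", {
  st <- small_study(noise_sd = 0)
  fit <- fit_bidirectional(st$dat, st$cn)
  expect_gte(fit$r_pooled, 1 - 1e-6)
})

test_that("pure-anterograde truth yields a null retrograde weight", {
  st <- small_study(
    n_regions = 50, edge_density = 0.25, rng_seed = 13,
    true_params = c(beta0 = -1, beta_a = 1, beta_r = 0, c_a = 0.5,
                    c_r = 2),
    noise_sd = 0.05
  )
  fit <- fit_bidirectional(st$dat, st$cn)
  expect_lt(abs(standardized_betas(fit)["r"]), 0.05)
  expect_gt(standardized_betas(fit)["a"], 0.9)
})

test_that("fit is invariant to region ordering", {
  st <- small_study()
  fit <- fit_bidirectional(st$dat, st$cn)
  set.seed(5)
  shuffled <- st$dat[sample(nrow(st$dat)), ]
  fit2 <- fit_bidirectional(shuffled, st$cn)
  expect_equal(fit$r_pooled, fit2$r_pooled, tolerance = 1e-6)
  expect_equal(fit$rates, fit2$rates, tolerance = 1e-4)
})

test_that("optimum dominates a 20 x 20 log-spaced rate grid", {
  st <- small_study()
  cn <- st$cn
  fit <- fit_bidirectional(st$dat, cn)
  g <- 10^seq(-3, 2, length.out = 20)
  best_grid <- -Inf
  for (ca in g) {
    for (cr in g) {
      r <- tryCatch(
        fit_linear_given_constants(st$dat, cn, c_a = ca, c_r = cr)$r_pooled,
        error = function(e) -Inf
      )
      best_grid <- max(best_grid, r)
    }
  }
  expect_gte(fit$r_pooled + 1e-8, best_grid)
})

test_that("standardized betas are exact for single-predictor outcomes", {
  st <- small_study()
  cn <- st$cn
  pair <- build_laplacians(normalize_by_source_size(cn))
  x0 <- make_seed_vector(cn)
  pa <- spread_predictor(pair$L_a, 0.5, 3, x0)
  dat <- tibble::tibble(
    mouse_id = "m1", genotype = "WT", treatment = 0, sex = "F", mpi = 3,
    hemisphere = cn$regions$hemisphere, region = cn$regions$acronym,
    n_daughters = 0L,
    pct_area = 10^(2 * pa$value - 1)
  )
  fit <- fit_spread_model(dat, cn, timepoints = 3)
  sb <- standardized_betas(fit)
  expect_equal(unname(sb["a"]), 1, tolerance = 0.02)
  expect_equal(unname(sb["r"]), 0, tolerance = 0.02)

  # scale invariance: multiplying the outcome by 10 shifts log10 by +1
  dat10 <- dat
  dat10$pct_area <- dat$pct_area * 10
  fit10 <- fit_spread_model(dat10, cn, timepoints = 3)
  expect_equal(standardized_betas(fit10), sb, tolerance = 1e-4)
})
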