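make_stratum <- function(n_per_group = 8, shift = 0, seed = 1,
                         sexes = TRUE) {
  set.seed(seed)
  n <- 2 * n_per_group
  tibble::tibble(
    mouse_id = sprintf("m%02d", 1:n),
    genotype = rep(c("WT", "G2019S"), each = n_per_group),
    treatment = 0,
    sex = if (sexes) rep(c("M", "F"), n_per_group) else "F",
    mpi = 6,
    hemisphere = "ipsi",
    region = "XX",
    n_daughters = 0L,
    pct_area = c(rnorm(n_per_group, 1, 0.2),
                 rnorm(n_per_group, 1 + shift, 0.2))
  )
}

test_that("section-level values average into one value per region", {
  secs <- tibble::tibble(
    mouse_id = "m1", genotype = "WT", treatment = 0, sex = "F", mpi = 3,
    section_id = c(1, 2, 3, 1),
    hemisphere = "ipsi",
    region = c("A", "A", "A", "B"),
    pct_area = c(1, 2, 3, 7)
  )
  out <- aggregate_sections(secs)
  expect_equal(out$pct_area[out$region == "A"], 2)
  expect_equal(out$pct_area[out$region == "B"], 7)

  dup <- dplyr::bind_rows(secs, secs[1, ])
  expect_error(aggregate_sections(dup), "Duplicate")
})

test_that("section aggregation matches a brute-force oracle", {
  set.seed(19)
  grid <- expand.grid(mouse_id = c("m1", "m2"), section_id = 1:12,
                      region = sprintf("R%02d", 1:50),
                      stringsAsFactors = FALSE)
  # each region appears in a random subset of sections
  grid <- grid[runif(nrow(grid)) < 0.4, ]
  grid$hemisphere <- "ipsi"
  grid$pct_area <- runif(nrow(grid))
  out <- aggregate_sections(grid)
  oracle <- c(tapply(grid$pct_area,
                     paste(grid$mouse_id, grid$region), mean))
  got <- setNames(out$pct_area, paste(out$mouse_id, out$region))
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
})

test_that("zero-variance strata are filtered with an exact count", {
  base <- make_stratum()
  zero <- base
  zero$region <- "Z0"
  zero$pct_area <- 0
  nearzero <- base
  nearzero$region <- "NZ"
  nearzero$pct_area <- c(rep(0, 15), 0.1)
  dat <- dplyr::bind_rows(base, zero, nearzero)
  out <- suppressMessages(filter_zero_variance(dat))
  expect_false("Z0" %in% out$region)
  expect_true("NZ" %in% out$region)
  expect_equal(attr(out, "n_filtered"), 1)

  # fixture with exactly 7 constant strata
  strata <- lapply(1:10, function(i) {
    s <- make_stratum(seed = i)
    s$region <- sprintf("S%02d", i)
    if (i <= 7) s$pct_area <- i / 10
    s
  })
  out7 <- suppressMessages(filter_zero_variance(dplyr::bind_rows(strata)))
  expect_equal(attr(out7, "n_filtered"), 7)
  expect_equal(dplyr::n_distinct(out7$region), 3)
})

test_that("rank transform uses midranks and conserves the rank sum", {
  expect_equal(rank_transform(c(3, 1, 1, 5)), c(3, 1.5, 1.5, 4))
  expect_equal(rank_transform(c(2, 5, 9)), c(1, 2, 3))
  set.seed(8)
  for (i in 1:5) {
    x <- sample(round(rnorm(20), 1), 20, replace = TRUE)
    expect_equal(sum(rank_transform(x)), 20 * 21 / 2)
  }
})

test_that("robust fit matches the OLS contrast on clean balanced data", {
  # interleaved groups: every rank residual stays inside the Huber corner
  # (|r| < 1.345 * MAD scale), so IRLS keeps unit weights and reduces to
  # ordinary least squares exactly
  dat <- tibble::tibble(
    mouse_id = sprintf("m%02d", 1:8),
    genotype = rep(c("WT", "G2019S"), each = 4),
    treatment = 0, sex = "F", mpi = 6, hemisphere = "ipsi",
    region = "XX", n_daughters = 0L,
    pct_area = c(0.1, 0.4, 0.5, 0.8, 0.2, 0.3, 0.6, 0.7)
  )
  res <- robust_region_fit(dat, "genotype", adjust_sex = FALSE)
  rk <- rank_transform(dat$pct_area)
  ols <- lm(rk ~ factor(dat$genotype))
  # lm's coefficient is WT minus the G2019S baseline; the emmeans pairwise
  # contrast is G2019S - WT, so the signs are opposite
  ols_effect <- unname(coef(ols)[2])
  expect_equal(res$effect, -ols_effect, tolerance = 1e-6)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)
})

test_that("the Huber fit resists a gross outlier better than OLS", {
  dat <- make_stratum(shift = 0.4, seed = 3, n_per_group = 10)
  eff0 <- robust_region_fit(dat, "genotype", adjust_sex = FALSE)$effect
  rk0 <- rank_transform(dat$pct_area)
  ols0 <- unname(coef(lm(rk0 ~ factor(dat$genotype)))[2])
  contaminated <- dat
  contaminated$pct_area[4] <- contaminated$pct_area[4] + 1000
  eff1 <- robust_region_fit(contaminated, "genotype",
                            adjust_sex = FALSE)$effect
  rk1 <- rank_transform(contaminated$pct_area)
  ols1 <- unname(coef(lm(rk1 ~ factor(contaminated$genotype)))[2])
  expect_lte(abs(eff1 - eff0), abs(ols1 - ols0) + 1e-8)
})

test_that("identical groups give a null effect with a covering interval", {
  dat <- make_stratum(shift = 0, seed = 4)
  res <- robust_region_fit(dat, "genotype")
  expect_lt(abs(res$effect), 2)
  expect_true(res$ci_low <= 0 && 0 <= res$ci_high)
})

test_that("robust fit enforces level structure and counts", {
  dat <- make_stratum()
  dat$genotype <- "WT"
  expect_error(robust_region_fit(dat, "genotype"), "2 levels")
  dat2 <- make_stratum(n_per_group = 2)
  expect_error(robust_region_fit(dat2, "genotype"), ">= 3")
})

test_that("second-generation P-values match the tabulated interval cases", {
  expect_equal(second_generation_p(10, 20, -5, 5), 0)
  expect_equal(second_generation_p(-5, 5, -5, 5), 1)
  expect_equal(second_generation_p(0, 10, -5, 5), 0.5)
  expect_equal(second_generation_p(-20, 20, -5, 5), 0.5)
})

test_that("second-generation P-values obey conventions and invariances", {
  # degenerate point interval
  expect_equal(second_generation_p(2, 2, -5, 5), 1)
  expect_equal(second_generation_p(7, 7, -5, 5), 0)
  # infinite interval -> inconclusive
  expect_equal(second_generation_p(-Inf, 3, -5, 5), 0.5)
  # inverted intervals raise
  expect_error(second_generation_p(3, 1, -5, 5), "<=")
  expect_error(second_generation_p(1, 3, 5, -5), "<")
  # monotone non-increasing as the estimate slides away from the null
  shifts <- seq(0, 15, by = 0.5)
  ps <- vapply(shifts,
               function(s) second_generation_p(-2 + s, 2 + s, -5, 5),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # joint shift/scale invariance
  p1 <- second_generation_p(1, 9, -5, 5)
  p2 <- second_generation_p(1 * 3 + 2, 9 * 3 + 2, -5 * 3 + 2, 5 * 3 + 2)
  expect_equal(p1, p2)
})

test_that("regional comparison flags shifted regions and few false positives", {
  # aggregate over simulation seeds: individual draws can by chance
  # contain real rank separations in unshifted regions
  shifted <- sprintf("R%03d_ipsi", 1:10)
  n_fp <- 0
  n_rest <- 0
  for (s in 1:5) {
    st <- small_study(
      n_regions = 25, edge_density = 0.3, rng_seed = 50 + s,
      n_mice_per_group = 8, timepoints = 6,
      group_effects = list(
        WT_0 = 0,
        G2019S_0 = setNames(rep(2, 10), shifted)
      )
    )
    dat <- suppressMessages(filter_zero_variance(st$dat))
    res <- suppressWarnings(regional_comparison(dat, "genotype"))
    hits <- res[res$significant %in% TRUE, ]
    hit_labels <- paste0(hits$region, "_", hits$hemisphere)
    expect_true(all(shifted %in% hit_labels))
    n_fp <- n_fp + length(setdiff(hit_labels, shifted))
    n_rest <- n_rest + sum(!is.na(res$significant)) - length(shifted)
  }
  expect_lte(n_fp / n_rest, 0.05)
})

test_that("regional comparison is calibrated on null tables", {
  n_sig <- 0
  n_tested <- 0
  for (s in 1:3) {
    st <- small_study(
      n_regions = 25, edge_density = 0.3, rng_seed = 150 + s,
      n_mice_per_group = 8, timepoints = 6,
      group_effects = list(WT_0 = 0, G2019S_0 = 0)
    )
    dat <- suppressMessages(filter_zero_variance(st$dat))
    res <- suppressWarnings(regional_comparison(dat, "genotype"))
    n_sig <- n_sig + sum(res$significant, na.rm = TRUE)
    n_tested <- n_tested + sum(!is.na(res$significant))
  }
  expect_lte(n_sig / n_tested, 0.05)
})

test_that("unanalyzable strata come back reason-coded, none lost", {
  st <- small_study(n_regions = 10, edge_density = 0.4, rng_seed = 3,
                    n_mice_per_group = 4, timepoints = 6,
                    group_effects = list(WT_0 = 0, G2019S_0 = 0))
  dat <- st$dat
  # leave 2 mice in one arm for a single region stratum
  drop_rows <- dat$genotype == "G2019S" & dat$region == "R001" &
    dat$hemisphere == "ipsi" & dat$mouse_id %in% unique(
      dat$mouse_id[dat$genotype == "G2019S"])[1:2]
  dat <- dat[!drop_rows, ]
  res <- regional_comparison(dat, "genotype")
  n_strata <- dplyr::n_distinct(
    paste(dat$hemisphere, dat$region, dat$mpi, dat$treatment))
  expect_equal(nrow(res), n_strata)
  bad <- res[res$region == "R001" & res$hemisphere == "ipsi", ]
  expect_equal(bad$reason, "too_few_per_level")
  expect_true(is.na(bad$effect))

  # more than two levels of the tested variable require `levels`
  st3 <- small_study(n_regions = 10, edge_density = 0.4, rng_seed = 3,
                     n_mice_per_group = 4, timepoints = 6,
                     group_effects = list(WT_0 = 0, WT_75 = 0,
                                          WT_450 = 0))
  expect_error(regional_comparison(st3$dat, "treatment"), "levels")
  res3 <- regional_comparison(st3$dat, "treatment", levels = c(0, 450))
  expect_true(all(res3$n > 0))
})

test_that("rank-based analysis is invariant to monotone transforms", {
  dat <- make_stratum(shift = 0.5, seed = 6)
  r1 <- robust_region_fit(dat, "genotype")
  trans <- dat
  trans$pct_area <- exp(dat$pct_area * 2)
  r2 <- robust_region_fit(trans, "genotype")
  expect_equal(r1$effect, r2$effect, tolerance = 1e-10)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-8)
})
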