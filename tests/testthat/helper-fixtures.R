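# Fixtures built in code: a tiny hand-specified connectome and a compact
# simulated study used across test files.

# 4-region connectome (2 per hemisphere) with hand-picked weights,
# sizes and centroids.
tiny_connectome <- function() {
  regs <- tibble::tibble(
    acronym = c("AA", "BB", "AA", "BB"),
    hemisphere = c("ipsi", "ipsi", "contra", "contra"),
    size = c(2, 4, 2, 4),
    x = c(1, 4, -1, -4), y = c(0, 0, 0, 0), z = c(2, 2, 2, 2)
  )
  A <- matrix(c(
    0, 2, 1, 0,
    1, 0, 0, 1,
    2, 0, 0, 2,
    0, 1, 1, 0
  ), 4, 4, byrow = TRUE)
  connectome(A, regs, seeds = "AA")
}

# Small simulated study; memoised per parameter set to keep the suite fast.
.sim_cache <- new.env(parent = emptyenv())
small_study <- function(n_regions = 20, edge_density = 0.3, rng_seed = 7,
                        ...) {
  key <- paste(n_regions, edge_density, rng_seed,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- simulation_config(n_regions = n_regions,
                           edge_density = edge_density,
                           rng_seed = rng_seed, ...)
  cn <- generate_connectome(cfg)
  dat <- simulate_pathology(cn, cfg)
  out <- list(cfg = cfg, cn = cn, dat = dat)
  .sim_cache[[key]] <- out
  out
}

# Independent truncated-Taylor-series matrix exponential (oracle).
expm_series <- function(M, order = 60) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(order)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

random_laplacian <- function(n, density = 0.5) {
  A <- matrix(0, n, n)
  off <- which(row(A) != col(A))
  on <- off[runif(length(off)) < density]
  A[on] <- exp(rnorm(length(on), 0, 1)) * 0.3
  diag(rowSums(A), n) - A
}
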