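# netspread

Network diffusion modelling of seeded protein pathology spread on a
directed brain connectome.

When misfolded tau (or α-synuclein) is injected into a handful of brain
regions, pathology appears months later in distant areas. **netspread**
asks whether that progression follows the brain's wiring diagram — and
in which direction along axons — rather than mere spatial proximity. It
is written for systems-neuroscience and quantitative-pathology groups
working with region-by-region percent-area measurements (e.g. from an
atlas-registration pipeline) and a tract-tracing connectome.

## The model

With adjacency $A$ (source → target projection strengths, rows divided
by source-region size), out-degree Laplacians
$L_a = D_{\mathrm{out}} - A$ and $L_r$ built from $A^\top$, and $x_0$
the 0/1 indicator of the injected seed regions, predicted log pathology
at $t$ months post-injection is

$$
\hat y(t) = \beta_0
  + \beta_a \log_{10}\!\left(e^{-c_a L_a t} x_0\right)
  + \beta_r \log_{10}\!\left(e^{-c_r L_r t} x_0\right)
  + \varepsilon(t)
$$

— bidirectional linear diffusion with anterograde and retrograde rate
constants $c_a, c_r$ (per month) and weights $\beta_a, \beta_r$. The
rate constants are optimized (multi-start Nelder–Mead on the log scale)
with the linear weights re-solved by least squares at every candidate,
maximizing the pooled Pearson correlation between predicted and
observed group-mean log pathology.

Around the core fit, the package provides:

- `seed_specificity_test()` — permutation null from 500 random seed
  sets matched on mean pairwise centroid distance (±10%), full refit
  per set, add-one empirical p-value;
- `crossval_compare()` — 500 random half-splits of the mice comparing
  held-out correlation of the bidirectional, anterograde-only,
  retrograde-only and Euclidean-distance models;
- `bootstrap_group()` / `compare_groups()` — 500 bootstrap resamples
  per experimental group giving distributions of $r$, $c_a$, $c_r$ and
  standardized weights;
- `regional_comparison()` — per-region ranked robust regression (Huber
  M-estimation, sex- and daughter-region-adjusted) with
  second-generation P-values against a ±5% null band; significance
  requires SGPV = 0;
- `generate_connectome()` / `simulate_pathology()` — a synthetic study
  generator with known ground truth;
- readers/writers for delimited connectome and pathology tables, and
  `tidy()` / `glance()` / `autoplot()` methods for every result type.

## Worked example

```r
library(netspread)

cfg <- simulation_config(n_regions = 50, edge_density = 0.25, rng_seed = 42)
cn  <- generate_connectome(cfg)     # bilateral, strongly connected
dat <- simulate_pathology(cn, cfg)  # per-mouse region table

fit <- fit_bidirectional(dat, cn)
fit
#> <diffusion_fit> bidirectional model, 2 timepoint(s)
#>   pooled Pearson r = 0.9996
#>   rates (/month): c_a = 0.501, c_r = 2.046
#>   weights: beta0 = -0.9799 beta_a = 1.004, beta_r = 0.5088
```

The generating truth was $c_a = 0.5$, $c_r = 2$, $\beta_a = 1$,
$\beta_r = 0.5$, $\beta_0 = -1$ with noise SD 0.05 on the log10 scale:
both time constants and all three weights are recovered to within a few
percent, and the pooled correlation between predicted and observed log
pathology is 0.9996. A quick specificity check against 99
distance-matched random seed sets:

```r
seed_specificity_test(dat, cn, n_null = 99, rng_seed = 1)
#> <seed_null> observed r = 0.9996 vs 99 distance-matched null sets
#>   matched mean pairwise distance: 7.52 mm (band 6.77-8.28)
#>   empirical p = 0.01 (minimum attainable 0.01)
```

The true seeds beat every matched null set, so the empirical p-value
sits at its floor $1/(1+n_{\mathrm{null}})$. `autoplot()` on any result
object (fit, null distribution, model comparison, bootstrap) draws the
corresponding diagnostic figure, and `tidy()`/`glance()` return tibbles
for downstream work.

See `vignettes/netspread-methods.Rmd` for the model conventions
(operator orientation, masking rules, optimizer settings), the
synthetic generator's assumptions, and known limitations.

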