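---
title: "Modelling seeded pathology spread on a directed connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seeded pathology spread on a directed connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netspread)
```

## The scientific problem

Misfolded proteins such as hyperphosphorylated tau propagate through the
brain in a prion-like fashion: pathology seeded at an injection site
appears, months later, in anatomically connected regions far from the
site. A long-standing question is whether that progression is better
explained by the wiring diagram of the brain — the directed, weighted
connectome measured by viral tract tracing — than by mere spatial
proximity, and whether spread follows axonal projections forward
(anterograde), backward (retrograde), or both.

netspread implements the full analysis chain for this question:

1. a **bidirectional linear diffusion model** on the connectome,
2. **validation** by distance-matched seed permutations and held-out
   model comparison,
3. **group characterization** by bootstrap distributions of fit
   statistics, and
4. **region-wise group comparison** by ranked robust regression with
   second-generation P-values (SGPVs).

A synthetic-data generator with known ground truth makes every stage
testable end to end.

## The spread model

Let $A$ be the $n \times n$ adjacency of projection strengths (source
row $i$ to target column $j$), normalized by dividing each row by the
size of its source region so that large regions do not dominate by
volume. The anterograde out-degree graph Laplacian is
$L_a = D_{\mathrm{out}} - A$ with $D_{\mathrm{out}} =
\mathrm{diag}(A\mathbf{1})$; the retrograde Laplacian applies the same
construction to $A^\top$. With $x_0$ the 0/1 indicator of the injected
seed regions, predicted log pathology at time $t$ (months
post-injection) is

$$
\hat y(t) = \beta_0
  + \beta_a \log_{10}\!\left(e^{-c_a L_a t} x_0\right)
  + \beta_r \log_{10}\!\left(e^{-c_r L_r t} x_0\right)
  + \varepsilon(t),
$$

where $c_a, c_r > 0$ are global rate constants (per month) and
$\beta_a, \beta_r$ weigh the importance of each direction.

**Orientation of the operator.** Writing the semigroup as
$e^{-cLt}x_0$ leaves the orientation of $L$ ambiguous. netspread
applies the *transposed* Laplacian, $e^{-c t L^\top} x_0$: with the
out-degree convention, $-L^\top$ has non-negative off-diagonals and
zero column sums, so it generates a positivity-preserving,
mass-conserving semigroup — pathology mass flows along (or, for $L_r$,
against) projections without being created or destroyed. This is the
physically sensible reading of "spread along connections", and the
package's property tests (non-negativity, conservation of
$\sum_i x_i$, the semigroup identity) all assert it.

**Fitting.** Both hemispheres live in a single matrix; there is no
special-casing of ipsi vs contra beyond reporting masks. The observed
outcome is the group-mean percent area occupied per region, averaged
across the group's mice and then $\log_{10}$-transformed; fitting is at
the group level, pooling region–timepoint observations across all
available timepoints into one objective. (Whether to pool timepoints or
average per-timepoint correlations was an open choice; pooling uses all
data in a single objective and is what the package
does. Groups measured at a single timepoint are simply fitted on that
timepoint.) The rate constants are optimized by derivative-free search
on $(\log c_a, \log c_r)$ — positivity enforced by parameterization —
with the linear weights re-solved by ordinary least squares at every
candidate, maximizing the pooled Pearson correlation between fitted and
observed values. The optimizer evaluates a $7 \times 7$ log-spaced grid
spanning $[10^{-3}, 10^2]$ per month and polishes the 5 best cells by
Nelder–Mead (relative tolerance $10^{-6}$); a single-rate model
(unidirectional or Euclidean variants) uses golden-section search on
the same interval. A fit dominance test against a $20 \times 20$ grid
guards against gross local optima.

**Masking.** $\log_{10} 0$ is undefined, so a region–timepoint
observation enters the fit only when (a) the observed group mean is
positive, (b) every required diffusion predictor is positive, and (c)
the region exists in the connectome (regions measured histologically
but absent from the tract-tracing data are dropped with a reported
count). Diffusion values below $10^{-12}$ are treated as exactly zero:
that threshold is the numerical noise floor of the propagator and, on a
strongly connected graph at $t > 0$, genuine masses sit far above it.

**Numerics.** Resampling-based validation refits the model hundreds of
times, so the matrix exponential is applied through a one-off
eigendecomposition $L^\top = V \Lambda V^{-1}$, giving
$e^{-sL^\top}x_0 = V e^{-s\Lambda} V^{-1} x_0$ at $O(n^2)$ per
candidate rate instead of a fresh $O(n^3)$ exponential. Complex
eigenpairs are handled in complex arithmetic and the (real) result
re-realized. If the eigenbasis reconstruction error exceeds
$10^{-8}$ (a defective or severely ill-conditioned Laplacian), the
propagator falls back to `Matrix::expm()`. The test suite checks the
fast path against two independent oracles: a truncated Taylor series
and `Matrix::expm()`.

## Validation

**Seed specificity.** Is the good fit specific to the true injection
sites, or would any spatially similar seed set do? The permutation null
re-fits the full model (both rate constants re-optimized) for 500
random seed sets of the same cardinality whose mean pairwise centroid
distance lies within ±10% of the true seeds' — matching the spatial
spread of the set while randomizing its topological position. The
add-one empirical p-value
$p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\}) / (1 + n_{\text{null}})$
can never be exactly zero; with 500 nulls its floor is $1/501 < 0.002$.
By default null sets are drawn from all connectome regions; a
`hemisphere` filter restricts the pool, which matters for calibration
when the tested seed set is itself single-hemisphere — unilateral
seeding induces a strong ipsi/contra asymmetry that any all-ipsilateral
candidate set captures, so an unrestricted pool makes the test
anti-conservative *under the null of wrong-but-ipsilateral seeds* while
leaving the positive control untouched.

**Model comparison.** Four model variants — Euclidean (inverse-distance
proximity graph, one rate), anterograde-only, retrograde-only, and
bidirectional — are compared out of sample: mice are split at random
into disjoint halves (stratified by timepoint so both halves retain
every timepoint), group-mean vectors are recomputed per half, each
model is fitted on the training half and scored by Pearson correlation
of its predictions on the held-out half, 500 times. Superiority is
summarized by paired add-one empirical p-values; no analytic p-value is
claimed. The unidirectional variants run through exactly the same code
path with the other direction absent, keeping the comparison honest.
The Euclidean model's functional form is not canonical; netspread uses
inverse-distance proximity $P_{ij} = 1/d_{ij}$ (documented choice; an
exponential-decay kernel is a plausible alternative and would need its
own length-scale parameter).

## Group comparison

**Bootstrap.** Within a group, mice are resampled with replacement
(same count, within each timepoint), the group-mean vectors recomputed,
and the model refitted; 500 resamples give distributions of the pooled
Pearson $r$, both rate constants, and both standardized weights
(slopes after z-scoring predictors and outcome over the pooled usable
observations — scale-free and therefore comparable across groups).
Intervals are percentile (2.5%, 97.5%); no BCa or studentized
refinement. Two groups are compared descriptively by difference of
medians and by the fraction of index-paired draws in which one lies
below the other — each resample index is an independent replicate, so
pairing is a natural coupling, but no formal test is attached.

**Regional statistics.** Per-mouse, per-region percent-area values
(section-level quantifications averaged within mouse and region first)
are compared between genotypes or treatments per stratum — hemisphere ×
region × timepoint, conditioned on each level of the non-tested
variable. Zero-variance strata are removed up front. Within a stratum
the outcome is midrank-transformed and fitted by Huber M-estimation
(`MASS::rlm`, tuning constant 1.345 for 95% Gaussian efficiency,
at most 50 IRLS iterations, coefficient tolerance $10^{-8}$), adjusted
for sex when both sexes are present, and for the daughter-region count
when it reaches 2 — entered as a numeric covariate, though within a
single-region stratum the count is constant and then carries no
information, in which case it is omitted to keep the design full rank.
The effect is the marginal contrast between the two compared levels
averaged over covariate levels (via emmeans), with a 95% interval using
a t quantile at the residual degrees of freedom — the asymptotic normal
interval visibly undercovers at 6–10 mice per arm.

**SGPV.** The second-generation P-value is the fraction of the interval
estimate $I$ overlapping the null interval $N$,
$p = |I \cap N| / |I|$, with the wide-interval correction
$p = \tfrac12 |I \cap N| / |N|$ when $|I| > 2|N|$; a point interval
gives 1 or 0 by membership, an infinite interval the inconclusive 0.5.
A region is called significant **only when its SGPV equals 0**, i.e.
its entire 95% interval is incompatible with the null band. The null
band is "±5% difference"; on a ranked outcome that phrase has no
canonical scale, and netspread operationalizes it as ±5% of the
stratum's rank range (max rank − min rank). This is an interpretive
choice, stated prominently: any other reading (e.g. ±5% of the raw
percent-area scale) changes which intervals touch the band.

Unanalyzable strata (a missing comparison level, fewer than 3 mice per
level, a failed or degenerate fit) are returned with a reason code, not
dropped, so the output row count always equals the stratum count.

## The synthetic-data generator

`generate_connectome()` draws a bilateral directed graph: per
hemisphere, `n_regions` regions with centroids uniform in a
10 × 10 × 10 mm box, mirrored across the midline (x → −x) for the
contralateral hemisphere; log-normal region sizes mirrored bilaterally;
directed edges as independent Bernoulli draws at `edge_density` with
log-normal (meanlog 0, sdlog 1) weights, emulating the
orders-of-magnitude spread of tract-tracing projection strengths.
Generation is rejection-resampled until the graph is strongly
connected (checked by boolean reachability, independently of any graph
library).

One generator parameter deserves emphasis: `weight_scale` is the target
mean out-strength (mean row sum) of the *size-normalized* adjacency and
sets the intrinsic mixing timescale of the system. At the default 0.25,
diffusion over a 3–6-month experiment with rate constants near 0.5–2
per month is *partial* — concentration gradients persist, as in real
progressive pathology. Much larger values equilibrate the system almost
immediately, which makes the rate constants unidentifiable (every
sufficiently large $c$ yields the same stationary predictor, a plateau
in the objective) and would defeat both parameter recovery and the
seed-specificity test; this mirrors the empirical situation, where
spread visibly progresses between 3 and 6 months rather than having
converged.

`simulate_pathology()` emits per-mouse tables from the model itself:
percent area $= 10^{\hat y + \delta_g + \delta_s + \epsilon}$ with
$\hat y$ the noiseless bidirectional prediction at the configured true
parameters, $\delta_g$ a per-group (optionally per-region) log10 shift,
$\delta_s$ an additive log10 shift for male mice (default 0, present so
the sex adjustment is exercisable), and
$\epsilon \sim N(0, \sigma)$ additive Gaussian noise on the log10 scale
— an assumption, since the noise model of real regional measurements is
not established; real percent-area data likely have heavier tails and
measurement floors that this generator does not emulate. Mice are
cross-sectional (each measured at one timepoint, as in a sacrifice
design), sexes alternate within cohorts, and group labels follow the
`"GENOTYPE_TREATMENT"` convention. The two RNG streams (connectome:
`rng_seed`; pathology: `rng_seed + 1`) make a configuration jointly
deterministic.

What passing tests on these data do *not* show: robustness to the real
Allen-atlas region ontology (laminar structure, wildly heterogeneous
region sizes), to non-Gaussian measurement noise, to regions measured
but absent from the connectome in large numbers, or to spatial
autocorrelation of histological error across neighbouring regions.

## Default problem sizes

The package's own validation runs use a 100-region-per-hemisphere
connectome (200 regions), 5 ipsilateral seeds, 8 mice per group, and
the standard 500 resamples for the permutation null, the
cross-validation, and the bootstrap; the eigendecomposition propagator
makes a full 500-refit permutation test a matter of a few minutes on
one core. Unit and property tests use 10–50 regions per hemisphere,
which the weight-scale convention above keeps in the same identifiable
regime.

## Known limitations

- Group-level fitting only: the model sees group-mean vectors, not
  per-mouse trajectories; mouse-level variance enters solely through
  resampling.
- Linear dynamics: no aggregation, clearance, or saturation terms, and
  no regional covariates (gene expression, functional connectivity).
- The Euclidean reference model's inverse-distance kernel is one of
  several defensible forms.
- SGPV significance calls inherit the coverage of the robust-fit
  intervals; at very small strata (3–4 mice per level) even t-quantile
  intervals are approximate.
- The distance-matched null draws from all regions by default; for
  single-hemisphere seed sets the `hemisphere` filter is the better
  calibrated choice (see above).
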