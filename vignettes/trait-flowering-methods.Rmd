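---
title: "Methods: trait-based flowering phenology analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based flowering phenology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitbloom)
```

`traitbloom` analyses single-season counts of flowering shoots per
species, plot and observation date in terms of categorical functional
trait states. This vignette is the package's own account of the models it
fits, the parameters that matter, what the synthetic-study generator does
and does not emulate, and the numerical and design choices made where the
problem left them open.

## 1. From shoot counts to trait-state flowering proportions

The raw datum is `n(x,t,i)`, the number of shoots of species `i` in full
bloom in plot `x` at observation time `t`. Within each plot, a species'
counts are normalized by its seasonal total in that plot, never pooled
across plots, giving a per-plot flowering profile that sums to 1 over the
plot's observed times. A species never in bloom in a plot has no profile
there (the 0/0 cell is excluded, not imputed).

For a trait state `j`, the mean flowering proportion is

$$F_{x,t} = \frac{\sum_{i=1}^{S} n_{x,t,i}/n_{tot,i}}{S_{x,t}},$$

with `S(x,t)` the number of *flowering* carrier species at `(x, t)`. Two
readings of `S` are defensible: counting only carriers in bloom at
`(x, t)` (so `F` is the mean intensity among species actually flowering,
and `F = 0` is reserved for cells with no flowering), or counting every
carrier present in the plot (so carriers not in bloom dilute the mean).
The first is the package default — it matches the definition of `S` as the
number of *flowering* species sharing the state — and the second is
available as `build_trait_matrix(..., carriers = "present")`. The choice
matters: under the default, a single flowering carrier yields the same `F`
as ten synchronized ones, which is why the indicator analysis pairs `F`
with an occupancy component (RF below).

Rows of the resulting matrix are relevés (plot x observed time; with the
default design, 35 x 12 + 35 x 12 + 35 x 10 = 1190 rows), columns are
trait states in deterministic (trait, state) lexicographic order.

## 2. Indicator value analysis over time groups

Within one community, candidate "groups" are all subsets of 1–3 observed
times — not only consecutive ones, since a state may flower in disjoint
windows (e.g. a spring bloom and a post-mowing re-bloom). For a group `C`:

- **RA** (relative abundance): the mean `F` over the relevés of `C`
  divided by that mean plus the single-time means of all times outside
  `C`. For a singleton this is the classical relative mean abundance, and
  a size-1 group reduces exactly to the single-time formula; over single
  times RA sums to 1 whenever the state flowers at all. The
  combination rule follows the site-group-combination extension of
  indicator-value analysis: a group competes against the *individual*
  times outside it.
- **RF** (relative frequency): the fraction of `C`'s relevés with
  `F > 0`.
- **IV = RA x RF**, in [0, 1] with the boundary interpretations checked
  in the test suite (1 = all carriers in bloom at the time in every plot;
  0 = no flowering of the state at the time).

The statistic is the maximum IV over all candidate groups; ties are broken
by smallest group size, then lexicographically earliest time set, so
output never depends on enumeration order. Significance comes from
permuting relevé time-labels (default 4999 permutations) and recomputing
the maximum IV each time, with the add-one estimator
`p = (1 + #[IV* >= IV_obs]) / (1 + B)` so p is never 0. Because plots are
measured repeatedly, a restricted mode (`restricted = TRUE`) permutes
labels within plots only; free permutation is the default, as nothing in
the repeated-measures structure enters the statistic itself. Both modes
are exact-testable on small instances (`exact = TRUE` enumerates all
distinct label arrangements), which is how the implementation is checked
against brute-force enumeration.

Retention applies three filters jointly: `p < 0.05`, `RA >= 0.6`,
`RF >= 0.25`. No multiple-testing correction is applied across trait
states; the component filters, not the p-value alone, carry the burden of
selectivity.

## 3. Ordination and variation partitioning

The redundancy analysis is covariance-based: `F` columns are centered but
not standardized, since they share the [0, 1] scale; a correlation-scaled
variant (`scale = TRUE`) exists for users who want rare states weighted
up. Observation time enters as an unordered factor (12 dummy levels, 10
for the community with skipped times); the environmental block holds soil
temperature (°C), soil relative humidity (%) and canopy height (cm). In
the trend models (below) time is instead quantitative — the ordination
asks *whether* times differ, the trend models ask for a monotone seasonal
component.

Explained variance is adjusted with the Ezekiel formula
`1 − (1 − R²)(n − 1)/(n − p − 1)` using the predictor *rank* as `p`
(rank-deficient columns are dropped with a warning). The partition of the
full-model adjusted R² into unique-to-time, unique-to-environment and
shared fractions is computed by differencing full and single-block
adjusted R²; the shared fraction is a derived quantity that may
legitimately be negative and is reported as computed, never truncated.
Only the full model and the two unique fractions are testable; their
permutation tests use the pseudo-F
`(SS_constrained / rank) / (SS_residual / df_residual)`, permuting rows of
the centered response freely for the full model and permuting residuals
under the reduced (conditioning-block) model for partial tests. Partial
fits use the projector identity `P_[ZX] − P_Z`, which makes the
semipartial decomposition `R²(X|Z) = R²([X Z]) − R²(Z)` hold to machine
precision and keeps the three-way partition additive by construction.

## 4. Mixed-effects trend models

Each trait state's `F` series is fitted by maximum likelihood (REML off,
since every reported comparison is a likelihood-ratio test between
fixed-effect structures). Fixed candidates: soil temperature, humidity,
canopy height, quantitative time, and — only in whole-dataset models —
topographic position. The declared random structure is random intercepts
for topographic position and plot with by-plot random slopes for time and
topographic position. A by-plot slope for a plot-constant factor is not
identifiable, so the fitter walks a simplification ladder (drop the
by-plot position slope, then the by-plot time slope, then the position
intercept; the plot intercept is kept to the last) and records the
structure actually used; the ladder is chosen once per response on the
full fixed model and then held constant across all nested comparisons.

Backward elimination refits the model without each remaining fixed effect
and drops the one whose removal gives the largest LRT p-value, provided
p >= 0.05, iterating until every remaining removal is significant. The
rule is deterministic (largest p first) and idempotent. The reported
significance is the final model against the random-effects-only null,
classed \*\*\*/\*\*/\* at 0.001/0.01/0.05, with chi-squared reference and
df equal to the fixed-parameter difference (the boundary problem of
testing random variances does not arise because the random structure is
held fixed). Constant responses are flagged and skipped, and per-model
failures never abort the batch run.

## 5. What the synthetic generator emulates

The generator reproduces the *statistical* structure the analysis assumes:

- the sampling frame — 3 communities x 35 plots x 12 times, the flat
  (mown) community unsampled at times 8–9;
- per-species unimodal flowering: each species has a Gaussian curve over
  observation indices with peak `mu ~ U[1, 12]` and width
  `sigma ~ U[0.45, 0.9]` intervals. With roughly biweekly sampling, a
  bloom lasting two to four weeks concentrates its shoots on one to three
  adjacent times while always giving non-negligible mass to at least two
  indices — curves are never narrower than the sampling resolution;
- overdispersed abundance: per species and plot, a seasonal shoot total is
  negative-binomial (`mu` lognormal with median 15, size 1.5 — clumped,
  with a realistic fraction of plot-level absences), then allocated across
  the plot's observed times by a multinomial on the discretized curve.
  Counts therefore conserve exactly (time counts sum to the drawn total);
- trait-state assignment with geometric positional weights (ratio 0.55):
  the leading state of each trait is the common syndrome, later states are
  progressively rarer specialized guilds. This matters for indicator
  recovery — real indicator states are typically carried by small,
  phenologically coherent guilds, not by a third of the species pool;
- seasonal environment: soil temperature rising to a mid-summer peak
  (south warmest), humidity declining into the summer drought with an
  autumn recovery (flat moistest), canopy growing logistically to a
  community-specific maximum and, in the mown community, reset to a few
  centimetres after the mowing window. Noise is independent per
  (plot, time);
- planted indicators: each carrier of the planted state has its peak
  drawn inside the target time group with probability equal to the
  concentration strength, in which case its width is also redrawn narrow
  (`U[0.25, 0.45]`) — a bloom with a 4-week standard deviation cannot lie
  "inside" a 3-time group, so concentration without synchrony would be
  self-contradictory. Strength 0 reduces exactly (byte-identically) to
  the null generator.

What it does **not** emulate: within-plot spatial structure, grazing
selectivity, inter-annual weather, species interactions, or any coupling
between a species' traits and its phenology beyond planted indicators.
Consequently, passing recovery and calibration tests shows the *inference
machinery* behaves correctly under the design's sampling structure — it
does not validate ecological conclusions drawn from any particular field
data set. Note also that a null (unplanted) study still yields some
retained indicator states: rare states carried by one or two species are
genuinely concentrated in time because species phenology is genuinely
unimodal. That is correct behaviour of the statistic, not a false
positive in the permutation sense.

## 6. Numerical choices, problem sizes, degenerate inputs

- Permutation p-values use the add-one estimator; "significant" means
  `p < alpha` strictly. Comparisons of permuted against observed statistics
  use a `1e-12` slack so exact ties (constant columns) count as >=,
  giving p = 1 for permutation-invariant columns.
- The calibration suite uses reduced problem sizes chosen as the smallest
  that make the distributional claims crisp: p-value uniformity is checked
  with 199-permutation tests pooled over ~240 trait-state draws
  (Kolmogorov–Smirnov) and 200 likelihood-ratio replicates; recovery runs
  50 replicates of the full 35-plot x 12-time design at 499 permutations.
  The headline analyses in `analysis/` use the reference settings (4999
  ISA permutations, 999 RDA permutations).
- Zero-count observation rows are equivalent to absent rows and are
  normalized away on read. Missing environmental records are an error,
  never imputed — every downstream stage assumes complete covariates.
- All-zero trait-state columns get IV 0, a flag, and p 1 without running
  a permutation test; constant responses are refused by the mixed-model
  fitter with a classed error.
- Every stochastic component (generator, both permutation tests, model
  batches) takes an explicit integer seed, and a fixed seed makes the
  entire pipeline byte-identical, which the test suite asserts on written
  output files.

## 7. Known limitations

- The combination rule for multi-time groups is one member of a family
  (groups could instead compete against all other *groups*); the
  implemented rule is the standard site-group-combination extension and
  reduces exactly to the single-time formula.
- The free-permutation null treats relevés as exchangeable across times
  within a community; with strong within-plot autocorrelation the
  restricted mode is the safer null, at some cost in power.
- Backward elimination inherits the usual caveats of stepwise selection;
  it is provided because the reported model table is defined in terms of
  retained-significant terms, not as a recommendation for effect
  estimation.
- With a single season of data, "time" and "seasonal environment" are
  partially confounded by design; the shared variance fraction is exactly
  where that confounding lands, and no causal reading of the unique
  fractions is implied.
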