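---
title: "Variance estimation for effective coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance estimation for effective coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcov)
```

## The estimand and its structure

Effective coverage asks not just whether people in need reach a service but
whether the facilities they reach are ready to deliver it. The package works
from *stratum summaries*: for each (region, facility-type) cell, a crude
coverage count `x_successes / n_x` from an individual-level sample and a
readiness measure from an independent facility sample — either a binary
count `y_successes / n_y` or a bounded score summarised by `y_mean` and
`y_var`. The estimates are

- stratum: `p_rf = p_x,rf × p_y,rf`,
- region: `p_r = Σ_f p_rf` (facility types partition the users of a
  region, so `Σ_f p_x,rf ≤ 1` is enforced, with a `1e-9` tolerance for
  rounded inputs),
- national: `P = Σ_r w_r p_r`, with region weights accepted unnormalized
  and normalized on use.

Two standing assumptions shape everything downstream. First, the two
samples are independent of each other — they come from different survey
instruments. Second, effective-coverage estimates for different strata are
treated as independent when variances are aggregated (covariance zero).
The second assumption is a modelling choice, not a fact: when the same
individual sample is split across facility types the within-region
covariance is typically negative, so ignoring it overstates the aggregate
variance and yields conservative intervals. The package does not attempt
covariance-aware aggregation.

Proportions are always derived from counts. This is deliberate: the delta
method needs both count cells (`n1`, `n0`) to form its logit intercepts,
and accepting pre-rounded decimals would silently break that.

## The three interval methods

**Exact (Goodman).** For independent `Z`, `M`,
`Var(ZM) = (Var Z + (EZ)²)(Var M + (EM)²) − (EZ·EM)²` holds exactly. With
binomial plug-ins this gives
`s² = [p_x(1−p_x)/n_x + p_x²][p_y(1−p_y)/n_y + p_y²] − p²` per stratum; a
continuous score substitutes `y_var/n_y` for the binomial variance and
`y_mean` for the proportion. Regions sum stratum variances; the national
variance is `Σ_r w_r² Σ_f s_rf²`. The interval is the symmetric Wald form
`p ± 1.96 s`. Two pathologies motivate the status taxonomy: at `p ∈ {0, 1}`
the plug-in variance is zero and the interval is **degenerate**; near the
boundary a bound can leave `[0, 1]`, which is impossible for a proportion —
the interval is **invalid**. Bounds are reported *unclipped* so that
invalidity can be counted; `clip = TRUE` truncates for presentation only
and never changes the status. The test suite checks the Goodman identity
against exhaustive enumeration of all binomial outcomes at small sample
sizes, where it must agree to ten significant digits.

**Delta method on the logit scale.** Each arm's sample proportion is
represented by its covariate-free logit-regression intercept
`b = log(n1/n0)`, `s_b = √(1/n0 + 1/n1)`, and the level estimate is
`F = logit(p)` viewed as a function of all the `b`'s. The chain rule
through `dp/db = p(1−p)` gives, at stratum level, the gradients
`(1−p_x)/(1−p)` and `(1−p_y)/(1−p)`; at region and national level a
stratum's coverage-arm gradient is `w·p_x(1−p_x)·p_y / (p_L(1−p_L))` (and
symmetrically for readiness), with `w` the normalized region weight at
national level and 1 otherwise. The interval is Wald on the logit scale,
back-transformed by the antilogit, hence asymmetric and always strictly
inside (0, 1) — it can never be invalid. It is instead **undefined**
whenever a required intercept does not exist: an empty or full count cell,
detected from the integer counts, never by floating-point comparison.
Rather than transcribing gradient formulas, the implementation derives them
and the build is gated on a finite-difference oracle: every level's
variance must match the variance assembled from central finite differences
(step `1e-6`) of the exact level map `b ↦ logit(level estimate)` to
relative tolerance `1e-5` at 100 random tables.

For a continuous readiness score the logit machinery has no count cells to
work with, so the score mean enters the expansion on its natural scale:
`Var(F) = [(1−p_x)/(1−p)]² s_bx² + [p_x/(p(1−p))]² · y_var/n_y`. This
natural-scale expansion is the package's own reconstruction (validated
against the same finite-difference oracle), chosen because a logit
transformation of a mean score has no exact small-sample standard error.
Design-based standard errors from a survey fit can be supplied per stratum
as `s_bx` / `s_by` override columns, which is how complex-survey inputs are
accommodated without survey machinery in the package.

**Parametric bootstrap.** Per stratum only: `B` draws of
`Binomial(n_x, p_x)/n_x` times `B` draws of `Binomial(n_y, p_y)/n_y`, and
the 2.5th/97.5th percentiles of the products. The percentile rule is linear
interpolation between order statistics (`stats::quantile` type 7); no
convention is canonical here, and at `B = 10000` the rule perturbs
endpoints by well under `1e-3`, but the choice is recorded in
`boot_config()` so it is explicit. For a continuous score the readiness
replicates are means of `n_y` draws from a Beta law moment-matched to
(`y_mean`, `y_var`) — Beta because the score lives on `[0, 1]`; the moment
match requires `y_var < y_mean(1−y_mean)` and infeasible moments are
rejected. A non-parametric bootstrap is deliberately absent: for a binary
simple random sample, resampling the data with replacement and redrawing
from the fitted binomial are the same scheme, and the variant is reported
elsewhere to undercover without a mechanism we could implement
unambiguously. Aggregating bootstrap replicates across strata to region or
national level is out of scope.

## The simulation engine

`run_setting()` draws `reps` datasets at true parameters `(P_x, P_y)` with
sample sizes `(n_x, n_y)` under simple random sampling, builds each
method's interval, and estimates the coverage probability over the
iterations that method can use:

- exact and bootstrap drop **degenerate** iterations (`p_rf ∈ {0, 1}`);
- delta drops **undefined** iterations (`p_rf = 0`, or either sample
  proportion equal to 1);
- exact intervals that are invalid but non-degenerate still count toward
  coverage — they exist, they are just impossible — and are tallied
  separately in `n_invalid`. This is the only accounting under which the
  boundary setting can show 100% conditional coverage and 100% invalidity
  at the same time, which is exactly what it does.

Removal is method-specific: one iteration can contribute to one method and
be removed for another. `n_removed + contributing = reps` holds per method
by construction and is asserted in tests.

The default grids are the study conditions: 25 true-proportion values from
0.02 to 0.98 on each axis (denser near the boundaries) and 11 sample-size
pairs from (50, 50) to (500, 500) plus unequal pairs with the facility
sample held at 50; 10000 replicates per setting and 10000 inner bootstrap
resamples are the full-scale defaults. Continuous-readiness simulations
draw scores from `Beta(P_y, 1−P_y)` — mean `P_y`, variance
`0.5·P_y(1−P_y)` — a deliberately dispersed but boundary-free choice,
recorded here because no canonical score distribution exists for this
setting.

Reproducibility under subsetting matters for a 6875-cell grid: each setting
derives its own seed from the master seed via a small integer hash of the
setting's parameters, so re-running any subset of the grid reproduces the
corresponding cells of a full run bit-for-bit. The hash is arithmetic-only
(FNV-style on 16-bit halves) and keeps every derived seed below 2³¹.

## Problem sizes used by the shipped checks

The packaged acceptance run uses the full 10000 replicates for the
single-setting boundary check and for the exact and delta 25×25 grids, and
a reduced 1000 replicates × 1000 resamples for the bootstrap grid, whose
inner loop is the one expensive cell; the reduced scale widens the
Monte-Carlo standard error of a single cell's coverage from about 0.2 to
about 0.8 percentage points, which is why the bootstrap minimum-coverage
check carries a 3-point floor where the others carry 2. Unit tests use a
few hundred to a few thousand replicates, chosen so that a 3-sigma
Monte-Carlo band still separates the behaviours being asserted.

## What the synthetic data does and does not show

`generate_fixture()` emulates the *shape* of a linked household/facility
application — regions crossed with facility types, a no-service remainder,
region weights — with each region's individual sample drawn once as a
multinomial so the partition constraint holds by construction. Passing the
end-to-end recovery test (national estimate within 0.005 of truth at
n = 10⁵) demonstrates that the estimator chain is consistent under the
package's own sampling assumptions. It does not demonstrate robustness to
anything those assumptions exclude: cluster sampling and design effects,
non-response weighting, readiness measured with error, women using multiple
facility types, or correlated strata. Real applications should supply
effective sample sizes (or `s_b` overrides) that encode their design.

## Known limitations

- No covariance between strata; aggregate intervals are conservative when
  the true within-region covariance is negative, anticonservative if it
  were positive.
- The continuous-readiness delta expansion is a reconstruction on the
  natural scale; it is internally validated but has no external reference.
- The bootstrap is stratum-level and assumes simple random sampling in
  both arms.
- `z = 1.96` is hard-coded at the default level for fidelity to the
  conventional formulas; other `conf_level` values use exact normal
  quantiles.
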