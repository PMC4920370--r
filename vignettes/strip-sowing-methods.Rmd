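---
title: "Methods: kill estimation, recovery simulation and cost projection for strip-sown baiting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kill estimation, recovery simulation and cost projection for strip-sown baiting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripsow)
```

`stripsow` analyses replicated field trials that compare two aerial
patterns for delivering toxic carrot bait against European rabbits:
broadcast sowing (complete coverage) and strip-sowing (dense baited bands
with unbaited gaps between flight lines). This vignette explains each
model in the pipeline, the assumptions behind it, the tunable parameters
and their defaults, and what the synthetic-data tests do and do not
demonstrate about real field data.

## Kill estimation from spotlight counts

The observable is a relative abundance index: rabbits counted per 800 m
transect at night under spotlight. Each treatment block carries four
transects surveyed on two consecutive nights before and about two weeks
after control. `replicate_index()` averages counts over nights *within*
each transect first and across transects second; for balanced data this
equals the plain mean of all eight values, but when a night is missing it
keeps every transect equally weighted, which is the robust choice for an
index built from fixed spatial units.

`percent_kill()` is the relative reduction `100(pre − post)/pre`. It is
deliberately computed per replicate and then averaged across replicates
(never from pooled counts), so each block contributes one independent
efficacy estimate regardless of its absolute abundance. The index is a
ratio, so the estimate is invariant to anything that rescales both counts
equally (observer efficiency, spotlight power), which is the core
assumption of before–after count indices; anything that changes
detectability between the pre and post surveys biases the kill estimate,
and the package cannot correct for that.

Group summaries use the Student-t interval
`mean ± t(0.975, n−1) · SD/√n`. At n = 9–10 replicates the t quantile
(2.26–2.31) is materially wider than the normal 1.96 and is required to
reproduce field-reported interval widths. Treatments are compared with a
Welch unequal-variance t-test (`welch_t()`); variances genuinely differ
between treatments when one contains an anomalous low-kill operation, so
the pooled-variance test would be wrong. Two-sided p-values are reported
throughout and no multiple-testing correction is applied, matching
standard practice for a single planned comparison.

`survivor_model()` fits the ANCOVA
`log(post) ~ log(pre) * treatment` by OLS: a positive slope means more
survivors where more rabbits started; a non-zero interaction would mean
one treatment under-delivered bait at high density. Replicates with zero
post-control counts would break the log; they are offset by `0.5 × 1/8`
(half the smallest index a single rabbit seen on one of eight
transect-nights can produce), a value small enough to preserve rank order
and configurable via `zero_offset`. `logit_adjusted()` implements the
logit transform used for proportion-scale modelling, mapping kill
proportions of exactly 1 using the smallest observed non-zero complement
so that perfect kills stay on the scale of the sample rather than at
infinity.

## Bait-deployment geometry

A `sowing_plan()` is a uniform-density band model: bait falls evenly
within a swath of width `w` centred on each flight line spaced `FPS`
apart. Coverage is `w/FPS`, the unbaited gap `FPS − w`, and concentrating
the block-average sowing rate into the covered fraction gives the
within-strip density a foraging animal actually meets. The model does not
simulate lateral bait scatter (aircraft vortex effects that widen real
swaths); the "effective swath" measured on the ground is an input, not a
prediction. Mass conservation — local density × covered fraction equals
the block-average density — holds identically and is verified as a
property test.

Field-collected baits fragment during deployment, so counted bait density
depends on the mass spectrum, not just the sowing rate.
`generate_bait_masses()` models this as intact dices of
`Normal(6, 0.5)` g of which a fraction (default 0.64) shatter, keeping a
`Beta(2, 2)` share of the parent mass. Those defaults were set once by
moment matching to an observed field spectrum of roughly 46% under 4 g,
36% at 4–6 g and 18% above 6 g and are not adjusted thereafter. Note one
structural limit: if fragments cannot exceed their parent, a generator
whose intact masses never exceed 6 g can never populate the >6 g class,
so the intact law must carry mass on both sides of 6 g; consequently,
with fragmentation disabled about half the dices sit marginally above
6 g rather than all falling in the 4–6 g bin.

## Population recovery after control

Long-run cost-effectiveness is set by how soon control must be repeated,
i.e. how fast the residual population regrows. The simulator uses
discrete-time logistic growth

`N(t+dt) = N(t) + r_eff · N(t) · (1 − N(t)/K) · dt`

with density normalised to the pre-control level (`K = 1`). The daily
default step keeps `r·dt ≈ 0.003`, far below the stability bound
`r·dt < 1` that is enforced by validation, and trajectories then stay
within (0, K] (a property test). A detailed demographic model for this
system exists in the literature, but its equations and parameter values
live outside this package's sources; the logistic stand-in is therefore
deliberately minimal, with every growth parameter exposed in
configuration and none hard-coded. An optional breeding-season window
sets `r_eff = 0` outside the window and rescales it inside so the annual
integral still equals `r`; the default is non-seasonal.

Two growth scenarios are run: a pre-epidemic instantaneous rate `r_pre`
(default 1.0/yr, a plausible semi-arid value for rabbits before rabbit
haemorrhagic disease suppressed growth) and exactly half that rate for a
post-epidemic population. Under non-seasonal logistic growth halving `r`
exactly doubles every recovery time — published results from richer
seasonal models show ratios nearer 1.75, which is a known structural
difference of the stand-in, not a bug.

Control efficacy is a `Beta(α, β)` draw fitted by moments
(`beta_from_moments()`) from the mean and variance of the observed
per-replicate kills; the moment map is exact and is verified by sampling
10⁶ draws. Note that the variance matters as much as the mean: the
broadcast group's wider spread (its moment fit has β < 1) puts weight
near 100% kill, where survivors are few and recovery is slow, which is
why the *higher*-mean treatment also has the *longer* mean recovery.

"Recovered to pre-control density" is asymptotically unreachable under
logistic growth, so a threshold is mathematically required:
`q = 0.95` of pre-control density by default, exposed in `sim_config()`.
Results are sensitive to `q` in the tail (the closed form diverges as
`q → 1`), so any reported recovery time should state its `q`. For the
non-seasonal model the closed form

`t = (1/r) · ln[q(1−s) / (s(1−q))]`

(survivor fraction `s`) is the analytic oracle: the simulator with a
degenerate (fixed) kill must agree within twice the time step. Runs not
recovered within `max_horizon` (default 50 yr) are counted and excluded
from the moments with a warning rather than silently truncated. Each
Monte-Carlo batch (default 10,000 runs) uses one seeded generator, and
the four standard scenarios run in a fixed order with per-scenario seeds
derived from the batch seed, so results are bit-reproducible.

## Cost projection

`cost_schedule()` converts a control frequency into costs over a
farm-plan horizon (default 20 yr): operations accrue pro-rata
(`n_ops = horizon/frequency`, fractional), so the per-hectare annual cost
reduces to `cost_per_op / frequency` with the horizon cancelling —
verified both symbolically in code and numerically in tests. Default
per-operation costs are $NZ 100/ha broadcast and 25% less ($NZ 75/ha)
for strip-sowing, reflecting two-thirds less bait and shorter flying
time; both are parameters. Savings are computed from unrounded
intermediates, so they can disagree with figures recomputed from rounded
per-hectare costs by a few tens of dollars per year — output rounding is
display-only. Discounting and secondary follow-up control are explicitly
out of scope.

## The synthetic trial generator

`generate_trial()` emulates the field design: block true densities drawn
log-uniform over 10–155 rabbits/transect, true kills drawn per treatment
from the beta efficacy laws (defaults fitted by moments at means
92.7%/94.0%), latent per-transect abundance negative binomial around the
block density (spatial heterogeneity, size 10), nightly counts negative
binomial around the transect abundance (observation noise, size 32), and
post-control abundance a binomial thinning by the true kill. The night
dispersion was calibrated analytically — `E|X₁−X₂| = √(2·Var)·√(2/π)` —
so that two nights on the same transect differ by about 18 rabbits at a
pre-control mean of 76, an observed feature of real spotlight data that
Poisson noise would badly understate. A contamination option injects one
anomalous low-kill broadcast replicate (e.g. 77%) to emulate an outlier
operation. Setting both dispersions to `Inf` removes all sampling noise
(counts equal their expectations, non-integer allowed), giving the exact
noise-free limit used by oracle tests.

The generator reproduces the *statistical* structure of a trial — it does
not model spatial transect placement, edge effects near unpoisoned land,
detection-distance variation, weather, or immigration. Passing
calibration tests therefore shows the estimators are consistent and
correctly sized under the stated sampling model, not that the field
design is unbiased against those real-world effects.

## Numerical choices and problem sizes

Tests and the acceptance script keep simulation sizes modest by choice:
Monte-Carlo recovery checks use 20–3,000 runs (the full 10,000 only in
the acceptance script), estimator-calibration loops use 200 synthetic
trials, the Welch size check 400, and moment round-trips 10⁶ draws.
Degenerate inputs are defined explicitly: a zero-variance Welch
comparison of equal groups returns t = 0, p = 1; `percent_kill` refuses a
zero pre-control index; `beta_from_moments` rejects variances at or above
`m(1−m)`; boundary bait masses (exactly 4 or 6 g) belong to the middle
size class.

## Known limitations

- The logistic recovery model omits seasonality by default, age
  structure, immigration and disease dynamics; its post-/pre-epidemic
  recovery-time ratio is exactly 2 by construction.
- Recovery times depend on the threshold `q`; report it.
- Kill estimation inherits all biases of count indices (detectability
  shifts between surveys are indistinguishable from kills).
- The cost model is undiscounted and ignores follow-up control.
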