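# stripsow

Strip-sowing deploys aerial toxic bait (0.02% w/w sodium fluoroacetate on
diced carrot) in high-density bands separated by unbaited gaps, instead of
the conventional broadcast pattern that covers a block completely. Because
a rabbit's home range spans several hectares, the hypothesis is that kill
success is driven by bait density *within* the baited bands, not by the
block-wide average — so a strip pattern can cut bait (and toxin) use by
two thirds without losing efficacy. `stripsow` is for pest-control
analysts and ecologists who need to evaluate that trade-off: it turns
replicated before/after spotlight transect counts into kill estimates,
projects population recovery after control, and converts recovery times
into farm-plan costs.

## What it computes

**Kill statistics.** Each ~160 ha block is surveyed on four 800 m
transects over two nights before and after baiting. Counts are averaged
over nights within transects, then across transects, giving one index
per block and period; the percentage kill is the relative reduction

    kill = 100 (pre − post) / pre.

Treatment groups are summarised by mean, SD and a Student-t 95% CI, and
compared with a Welch unequal-variance t-test. An ANCOVA of log survivors
on log initial counts × treatment asks whether either sowing rate was
insufficient at high density.

**Bait geometry.** For a plan with flight-path spacing `FPS`, swath width
`w` and sowing rate `R` (kg/ha), coverage is `w/FPS`, the unbaited gap is
`FPS − w`, and the within-strip density is `(100 R / (w/FPS)) / m` baits
per m² for mean bait mass `m` g.

**Recovery model.** Control on 1 July removes a beta-distributed kill
fraction, with the beta law fitted by moments to the observed group mean
and variance (`α = m(m(1−m)/v − 1)`, `β = (1−m)(m(1−m)/v − 1)`). The
residual population grows back by discrete-time logistic dynamics
`dN = r N (1 − N/K) dt` (daily step, optional breeding-season window)
until it first reaches a threshold `q` (default 0.95) of the pre-control
density; 10,000 Monte-Carlo runs per scenario across the cross of growth
rate (pre-epidemic `r`, and `r/2` after a rabbit haemorrhagic disease
epidemic) and treatment.

**Cost model.** Mean years-to-recovery becomes the control frequency;
with per-operation costs of $NZ 75/ha (strip) and $NZ 100/ha (broadcast),
per-hectare cost per year is `cost_per_op / frequency` (operations accrue
pro-rata), scaled to a farm area for whole-farm savings.

A synthetic trial generator (`generate_trial()`) reproduces the sampling
structure of the field design — log-uniform block densities, negative
binomial transect and night noise, binomial thinning by a beta-drawn true
kill — so the whole pipeline is testable end to end without field data.

## Worked example

A fully synthetic trial (9 strip, 10 broadcast blocks) analysed end to
end:

```r
library(stripsow)

strip <- read_sowing_plan(system.file("extdata", "strip_plan.cfg",
                                      package = "stripsow"))
strip
#> strip sowing plan: 10 kg/ha, FPS 75 m, swath 10 m
#>   coverage 13.3%, gap 65 m
#>   within-swath density 7.5 g/m2 = 1.25 baits/m2 (at 6 g/bait)
#>   toxin loading 2 g/ha

res <- run_full_analysis(cfg = sim_config(n_runs = 10000), seed = 42)
res$summaries$strip
#> strip: n = 9, mean kill = 90.0% (95% CI 85.1; 94.8), SD = 6.30
res$summaries$broadcast
#> broadcast: n = 10, mean kill = 92.6% (95% CI 87.2; 98.1), SD = 7.62
res$welch
#> Welch t = -0.82, df = 16.90, P = 0.42
res$cost_table[c("scenario", "frequency_years", "cost_per_ha_year")]
#>         scenario frequency_years cost_per_ha_year
#> 1      pre_strip            5.37            13.96
#> 2  pre_broadcast            6.15            16.25
#> 3     post_strip           10.71             7.00
#> 4 post_broadcast           12.32             8.12
```

The two treatments do not differ significantly in kill (P = 0.42 here),
and although the strip schedule has to repeat slightly more often
(every 5.4 vs 6.2 years pre-epidemic), its lower per-operation cost makes
it cheaper per hectare per year — about $4,600/yr cheaper on a 2,000 ha
farm in this run (`res$savings$pre$per_year`).

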