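# urbangrad

Urban-gradient location–scale analysis of well-being, social and economic
satisfaction.

## What this package is for

Are people near city centers more or less satisfied than people in the
hinterlands — and is satisfaction more *unequal* there? `urbangrad`
answers such questions with a continuous, boundary-free urbanicity
measure: each participant's distance to the nearest city center divided by
the square root of that city's population,

    d_i = min_c  dist(x_i, c) / sqrt(N_c)      [km per sqrt(person)]

so `d = 0` at any city center and the gradient stretches with city size
(12 km from Reading ≈ 74 km from London). Along this gradient the package
fits **location–scale additive models**: both the mean and the SD of each
z-scored outcome are penalized B-spline smooths of `d`,

    y = mu(d) + sigma(d) * e,   e ~ N(0,1),

with `log sigma(d)` modelled so the SD stays positive (a GAMLSS-type
model; the binary loneliness item gets a penalized logistic fit whose
variance is `p(1-p)` by construction). From the fitted curves it extracts
**optimal distances** — interior maxima of mean curves, minima of SD
curves, found by the method of differences on a dense grid — with effect
sizes in SD units and conversions to physical km per reference city.

It is aimed at epidemiologists and quantitative social scientists working
with large georeferenced cohorts. Because such cohorts are typically
access-restricted, the package ships a seeded synthetic-cohort generator
that emulates the relevant survey structure (6-point Likert items, a
binary loneliness item, five household-income bands, participants
clustered around cities of stated populations, smooth planted
mean/SD gradients), so the entire pipeline is testable and its parameter
recovery can be demonstrated end to end.

## Worked example

```r
library(urbangrad)

cfg <- synthetic_config(seed = 20260929L, n_participants = 20000L)
coh <- generate_cohort(cfg)

rc  <- run_config(coh$gazetteer, coh$participants, seed = 20260929L)
run <- run_analysis(rc)

pk <- run$peaks
pk[pk$curve_kind == "mean", c("item", "d_star", "extremum_kind",
                              "effect_size", "km_Reading", "km_London")]
```

which prints (abridged):

```
                    item d_star extremum_kind effect_size km_Reading km_London
               happiness 0.0198       maximum      0.1027          9        59
         meaningful_life 0.0220       maximum      0.1829         11        65
     family_satisfaction 0.0227       maximum      0.1782         11        67
 friendship_satisfaction 0.0184       maximum      0.1297          9        55
              loneliness 0.0267       minimum      0.0949         13        79
                  income     NA          none      0.5369         NA        NA
  financial_satisfaction 0.0258       maximum      0.1022         12        77
        job_satisfaction     NA          none      0.0734         NA        NA
```

Read: meaningful life peaks at `d* = 0.022` — about 11 km outside a
Reading-sized city, 65 km outside London — and is 0.18 SD higher there
than at city centers (the generator planted a bump of amplitude 0.2 at
`d* = 0.02`, so the pipeline recovers both the location and the size).
Income rises monotonically toward city centers (`none`: its extreme value
sits on the boundary, so no interior optimum exists; the min-to-max swing
of 0.54 SD is reported instead). Each fitted curve, with 95% pointwise
bands for mean and SD, is in `run$curves`; filter counts, convergence
flags and effective degrees of freedom are in `run$log`.

The numbered scripts under `analysis/` run the same study as a workflow —
`01_simulate.R` (cohort), `02_main_analysis.R` (gradients and optima),
`03_robustness.R` (minimum city size 50k–200k, largest-city exclusion,
age+income adjustment, radius normalization, participation weights,
log population density), `04_validation.R` (parameter recovery and band
coverage) — writing tables under `results/`.

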