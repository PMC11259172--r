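---
title: "Modelling well-being gradients along a continuous urbanicity measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling well-being gradients along a continuous urbanicity measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbangrad)
```

## The measure and the model

`urbangrad` studies how survey outcomes — well-being, social satisfaction,
economic satisfaction — vary along a continuous urban–rural gradient.
Instead of drawing urban/rural boundaries or using population density, the
exposure is the *size-adjusted distance to the nearest city center*:

$$ d_i = \min_c \; \frac{\mathrm{dist}(x_i, c)}{\sqrt{N_c}}, $$

where $x_i$ is participant $i$'s home location and $N_c$ the population of
city $c$. The units are km per $\sqrt{\text{person}}$: $d = 0$ at any city
center, and the same $d$ describes a point 12 km from Reading (230,000
inhabitants) or 74 km from London (8.8 million). Assignment happens on the
adjusted scale — someone in the center of Reading, 55 km west of London, is
assigned to Reading with $d = 0$, not to London. Ties (measure zero) break
lexicographically by city name so output is deterministic.

Each standardized outcome $y$ is then modelled with a location–scale
additive model,

$$ y_i = \mu(d_i) + \sigma(d_i)\,\varepsilon_i, \qquad
   \varepsilon_i \sim \mathcal N(0, 1), $$

with both $\mu(\cdot)$ and $\log \sigma(\cdot)$ penalized B-spline (P-spline)
smooths of $d$. Modelling $\log\sigma$ keeps the SD positive and makes the
scale smooth linear on its natural scale. The binary loneliness item uses a
penalized Bernoulli fit on the log-odds scale instead; its variance is
$p(1-p)$ by construction, so no separate SD curve is reported for it.

Ordinal 6-point Likert items are treated as Gaussian on z-scores rather
than by ordinal regression: the object of interest is the SD gradient in
z units, which only a Gaussian location–scale model yields, and effect
sizes then read directly as Cohen's $d$.

## Spline and penalty choices

* **Basis**: cubic B-splines on 20 equally spaced interior knots over the
  estimation range $[0, 0.07]$, using the uniform-knot convention in which
  knots extend beyond the boundary rather than being clamped. With uniform
  knots the order-2 difference penalty's null space is exactly the linear
  functions of $d$, so "infinite" smoothing collapses to a straight-line
  fit — a property several tests exploit. Evaluation outside the knot range
  is an error; the package never extrapolates silently.
* **Penalty**: second-order differences on adjacent coefficients.
* **Degrees of freedom**: the published procedure constrains each smooth to
  "3 degrees of freedom" in the convention of the GAMLSS smoothers it
  used, where the count excludes the constant-and-linear baseline the
  smoother always retains. In the trace-of-hat-matrix convention used
  throughout this package that is a cap of `max_edf = 5` per smooth (2 for
  the null space + 3). The cap binds only from above: smoothness is
  otherwise chosen from the data (below).
* **Smoothness selection**: every working model in the fitting loop is
  scaled to unit dispersion, so the smoothing parameter of each term is
  chosen by UBRE / Mallows' $C_p$ ($\mathrm{RSS}_w + 2\gamma\,\mathrm{edf}$)
  with an inflation factor $\gamma = 1.7$, then recalibrated upward if the
  resulting edf exceeds the cap. The inflation guards against the
  well-known tendency of prediction-error criteria to undersmooth, and
  matches the analysis intent of capturing broad trends rather than small
  fluctuations: with $\gamma = 1$ a pure-noise outcome acquires spurious
  interior optima in roughly one fit in eight, while BIC-strength
  penalization flattens genuine gentle curvature enough to break
  confidence-band coverage. $\gamma = 1.7$ was fixed after checking three
  behaviours jointly in simulation (optimum recovery, band coverage,
  null-case flatness) and is not re-tuned per analysis.

## Fitting algorithm

Fitting alternates two penalized steps until the penalized deviance changes
by less than $10^{-6}$ (relative):

1. **Mean step** — exact penalized weighted least squares for the $\mu$
   coefficients with working weights $w_i / \sigma_i^2$.
2. **Scale step** — one penalized Fisher-scoring update for the
   $\log\sigma$ coefficients, driven by squared standardized residuals
   (working response $\eta_i + (r_i^2/\sigma_i^2 - 1)/2$, working weights
   $2 w_i$), with step-halving so the penalized deviance never increases.

Smoothing parameters are selected during the first two cycles and then
frozen; the recorded deviance trace starts at the freeze and is
nonincreasing. If the alternating scheme has not converged after 40
cycles, it restarts with coefficient jitter of SD 0.1 (an internally
seeded perturbation; up to five attempts in all), and finally falls back
to a simultaneous Newton update over both coefficient blocks with observed
cross-derivatives for up to 60 iterations. A fit that still fails is
returned with `converged = FALSE` — flagged, never silent — and the
pipeline carries on with the remaining items.

Observation weights (participation weights) multiply the likelihood;
weights of one reproduce the unweighted fit exactly, and splitting an
observation into two half-weight copies leaves the fit unchanged — both
properties are tested, and both motivated using the weight *sum* rather
than the row count inside the selection criterion.

**Confidence bands** are pointwise (not simultaneous), built by the delta
method on the linear predictor scale from the Bayesian covariance
$(X'WX + \lambda P)^{-1}$ and transformed to the response scale, so SD
bands are always positive. Under a truth with gentle curvature they cover
at roughly 91–96% of grid points at the 95% level in the package's own
simulations; truths rougher than the edf cap allows will be undercovered,
which is inherent to penalized fits.

**Covariate adjustment** (age, z-scored recoded income) adds centered
smooths to both predictors. Their df is deliberately left uncapped
("unrestricted"), only selected by the same criterion. When a covariate is
(nearly) a deterministic function of $d$ the decomposition is not
identifiable; the fit still returns, and a concurvity diagnostic (the
$R^2$ of the covariate on the urbanicity basis) flags the problem.

## Optimal distances and effect sizes

Fitted curves are reported on a 501-point grid over $[0, 0.05]$
(resolution $10^{-4}$), after estimating on $d < 0.07$ so the curve is
stable at the reporting edge. The *optimal distance* is the grid point
where the first differences of the fitted curve change sign in the
requested sense (maximum of a mean curve — minimum for loneliness, where
lower is healthier — and minimum of an SD curve). A curve that is monotone
over the grid, or whose extreme value sits on the boundary, has no
interior optimum and reports "none": that is how flat-or-monotone items
(happiness SD, income, job satisfaction) are distinguished from genuine
hinterland optima. No uncertainty interval is attached to the optimum;
the method does not support a good one.

The effect size is $|\hat z(0) - \hat z(d^\*)|$ in SD units; with no
interior optimum, the curve's min-to-max swing over the reporting range is
used. For loneliness the probability difference is divided by the binary
item's marginal SD $\sqrt{\bar p(1 - \bar p)}$ so it reads in the same
units. Optimal distances convert to physical km per reference city as
$d^\* \sqrt{N}$, rounded half-up.

## The synthetic cohort

Real cohorts of this kind are access-restricted, so the generator builds a
cohort carrying exactly the structure the method assumes, with every
generating function stored for recovery tests:

* **Geography** — three monocentric cities (Reading 230k, Glasgow 630k,
  London 8.8M) on a planar grid, far enough apart that cross-assignment is
  rare; areas share one density so radius normalization is an exact
  rescaling of sqrt-population normalization (a property the robustness
  suite tests). 80% of participants attach to a city with probability
  proportional to population, at an exponential raw distance whose mean is
  0.012 on the adjusted scale; 20% are uniform over the bounding region.
  This reproduces heavy near-city sampling (about 80% of the cohort inside
  the reporting range; rural-uniform mass falls mostly beyond the
  estimation range and is excluded by the mask).
* **Outcomes** — per item, a latent Gaussian $\mu^*(d) + \sigma^*(d)\,
  \varepsilon$ with bump-shaped truth curves (baseline + Gaussian bump),
  discretized through fixed cutpoints: five cutpoints for 6-point Likert
  items chosen to give the left-skewed histograms typical of satisfaction
  data, four for the income bands. Loneliness is Bernoulli at a log-odds
  curve dipping at $d = 0.024$. Defaults emulate the published shapes:
  satisfaction means peaking near $d \approx 0.02$, income rising sharply
  toward centers with inflated SD there, monotone job satisfaction. The
  meaningful-life bump (location 0.02, amplitude 0.2, width 0.01) is the
  planted signal the validation scripts recover end to end.
* **Demographics** — age $\mathcal N(55, 7.7)$ (untruncated, so the
  moments are exact), 57% female, a 97/0.8/0.9/1.4% ethnicity mix.
  Missing codes everywhere at 0.5%, do-not-know (2%) only on meaningful
  life, jobless (10%) only on job satisfaction.
* **Districts** — grid cells with density decaying away from the centers
  plus a rural baseline, including a few extreme low-density outliers so
  the density variant's outlier handling (quantile cutoff on log-density,
  default 0.1%) is exercised.

What the generator does *not* emulate: real geography, polycentric cities,
spatial autocorrelation of outcomes beyond the planted $d$-dependence,
item wave-subsetting (real per-item sample sizes differ by design),
participation-weight construction, or any ordinal response process other
than a discretized latent Gaussian. Passing recovery tests therefore show
that the pipeline measures what it models — not that real survey data
satisfy the model.

Because discretizing a latent Gaussian to six categories and re-z-scoring
attenuates scale structure slightly, the SD-recovery validation is run on
the stored latent outcome; the mean-optimum validation runs on the fully
discretized pipeline, where location information survives essentially
intact.

## Degenerate inputs and numerical details

* Empty gazetteer after the population filter, all-0/all-1 binary
  outcomes, constant outcomes (zero variance), and negative weights are
  hard errors with explicit messages.
* The normal-equations matrix always carries a relative ridge of $10^{-8}$
  so sparse basis tails (few rural participants near $d = 0.07$) cannot
  make a solve fail.
* Boundary knots are pinned exactly to the range ends so that values equal
  to a range bound evaluate cleanly.
* Under radius normalization the estimation/reporting bounds (0.07/0.05)
  are rescaled by the gazetteer's median $\sqrt{N}/r$ so they describe the
  same physical radii; for the log-density variant the estimation range is
  the central 99% of included log-densities.
* Problem sizes in the validation scripts (20,000-participant cohorts,
  10–20 seeds, 50–100 coverage replicates at $n = 50{,}000$) were chosen
  to put simulation error well below the tolerances being checked while
  keeping a full run in the minutes range.

## Known limitations

* Pointwise bands say nothing simultaneous about the whole curve.
* The edf cap deliberately biases very sharp features toward smoothness;
  optima narrower than the cap allows are attenuated.
* Monocentric cities only; no polycentric modelling.
* The density variant shares the fitting machinery but its axis has
  opposite orientation to $d$ (high density = urban); effect sizes for it
  are reported relative to the low-density end of the grid.
* No imputation: special codes are dropped (with logged counts), never
  filled in.
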