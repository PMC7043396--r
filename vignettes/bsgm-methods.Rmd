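---
title: "Interpolating annual built-settlement extents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating annual built-settlement extents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Remotely-sensed binary built-settlement (BS) extents are typically
available only for a few snapshot years, while applications in population
mapping, epidemiology and development planning need annual series. `bsgm`
interpolates: given BS rasters at observed years $T = \{t_0, \dots, t_1\}$,
annual subnational population totals, annual lights-at-night (LAN)
brightness rasters, and a static covariate stack, it produces a binary BS
extent for every year in between. The model is strictly interpolative — a
pixel can only be converted during a period if the snapshots show it
transitioned within that period, so spatial uncertainty is never worse
than the inputs; what the model adds is the *timing* of each transition.

The framework has two components, run per subnational unit (the zone at
which census population is known):

1. **Demand quantification** — how many pixels of a unit transition from
   non-BS to BS in each year.
2. **Spatial allocation** — which eligible pixels transition in that year.

## Demand quantification

For each unit $i$ and observed year, the BS population $BSPOP_i(t)$ is the
gridded population summed inside the BS extent, the BS count $BSCNT_i(t)$
is the number of BS pixels, and the unit-average BS density is
$BSD_i(t) = BSPOP_i(t)/BSCNT_i(t)$ (all BS pixels of a unit share one
density; finer within-unit structure is unknown).

Between the two endpoints of each period, BS population is interpolated
with a logistic growth curve whose carrying capacity is the unit's *total*
population that year — a dynamic ceiling $K_i(t)$:

$$BSPOP_i(t) = K_i(t)\,\frac{e^{r_i t + C_i}}{1 + e^{r_i t + C_i}}$$

$r_i$ and $C_i$ come from a least-squares line through the
logit-transformed observations $\ln\!\big(BSPOP/(K - BSPOP)\big)$; with
two endpoints per period this is the exact interpolating line, fitted
piecewise per period. The year variable is the offset from the period
start, so re-indexing years changes only $C_i$, never a prediction. BS
density is interpolated with a single natural cubic spline across *all*
observed years (knots $=T$), prioritising exact reproduction of the
observations over any parametric form.

The annual BS pixel count estimate is the ratio
$\widehat{BSCNT}_i(t) = BSPOP_i(t)/BSD_i(t)$, and annual transition
estimates are its first differences, clamped at zero (transitions are
nonnegative by definition). Within each period the estimates are
normalised to weights $w_{ip}$ summing to one, and the period's *observed*
transition total $\Delta BSCNT_{ip}$ is redistributed over the period's
years as $w_{ip}(t)\,\Delta BSCNT_{ip}$, rounded to integers.

### Numerical choices

* **Logit clipping.** The transform is undefined at $BSPOP \in \{0, K\}$;
  observations are clipped to $[\varepsilon K, (1-\varepsilon)K]$ with
  $\varepsilon = 10^{-6}$. A unit with *no* BS at a period endpoint has no
  usable density either; that unit-period falls back to uniform weights.
  The same fallback applies when the density spline is not strictly
  positive inside a period (possible with strongly non-monotone knot
  values) and when every annual estimate is zero.
* **Conservative rounding.** Independent rounding of $w \cdot \Delta$
  breaks the total; reconciliation uses the largest-remainder rule with
  ties broken toward the earlier year. It is deterministic, conserves the
  sum exactly, and (as the test suite verifies by enumeration) minimises
  the total absolute deviation from the real-valued targets.
* **Demand years.** Period weights cover every year from $t_{start}+1$ to
  $t_{end}$ inclusive. The final-year share is what keeps the modelled
  series from exhausting all transitions one year early: conservation then
  implies the allocation provably reproduces the observed snapshot at each
  period end, which the implementation asserts at run time. Transitions
  assigned to $t_{end}$ are realised by that observed snapshot itself.

## Spatial allocation

A single random-forest classifier is trained on the full study span: the
label is whether a pixel transitioned between $t_0$ and $t_1$. Because
transitions are rare, a stratified under-sample is used — 80% of
transition pixels, capped at 50,000, plus an equal number of
non-transition pixels, drawn without replacement from study-area pixels.
The forest (500 trees by default; vote fractions as posterior
probabilities; mean decrease in Gini impurity as importance) predicts one
study-span transition probability $P_{ij}$ per pixel. Predictors are
derived from the $t_0$ extent only — distance to the nearest BS edge
(exact Euclidean distance transform) and the BS proportion within discs
of 1, 5, 10 and 15 pixels — plus any static extras; intermediate modelled
extents never feed back into the covariates, so the probability surface is
fixed for the whole run.

The surface is made year-specific with LAN change. For year $t$ the annual
lag $LAN_t - LAN_{t-1}$ is min-max rescaled *within each unit* to
$w_{LAN} \in [0,1]$ and multiplied onto the forest probability:
$P_{adj} = w_{LAN} \cdot P$. A relatively large brightness jump marks a
pixel as relatively likely to be transitioning around that year. Each
year, within each unit, the $n$ eligible pixels with the highest $P_{adj}$
are converted ($n$ from the demand table), the union with the previous
extent becomes the next year's base, and the loop proceeds period by
period. Periods are independent, so results are identical whether periods
run sequentially or in parallel.

### Design choices made where the design was open

* **Lag-to-year mapping.** The probability for year $t$ uses the lag
  *ending* at $t$ (brightness increase up to $t$ signals transition by
  $t$). The alternative (lag beginning at $t$) shifts the signal one year
  late for step-like brightness changes.
* **Degenerate units.** When a unit's lag is constant, min-max rescaling
  is undefined; the weight is set to 1 everywhere, leaving the forest
  ranking untouched (any positive constant is rank-equivalent; selection
  is rank-based within the unit).
* **Ties.** Exactly tied $P_{adj}$ values are broken by a seeded uniform
  draw, never by scan order, so no spatial artefact aligns with array
  layout.
* **Neighbourhood shape.** The focal windows are circular discs (centre
  included, centre distance $\le$ radius), truncated at the grid border
  with the in-grid disc size as denominator, so proportions stay in
  $[0,1]$ everywhere. Square windows would weight diagonal neighbours
  more at equal radius.
* **Demand shortfall.** If a unit-year demands more pixels than remain
  eligible (impossible under exact conservation, possible with corrupted
  inputs) the demand is capped and a warning names the shortfall — it is
  treated as a data-integrity signal, not silently absorbed.

## Validation machinery

Agreement is evaluated *only on the pixels observed to transition* in each
period: including never-transition pixels would swamp the counts with
trivially correct true negatives. Per interpolated year the package
reports recall, specificity, precision, F1, the quantity disagreement
$|FN - FP|/N$, the allocation disagreement $2\min(FP, FN)/N$, and the
proportion correct; quantity + allocation equals the total disagreement,
one minus the proportion correct, and the identities are property-tested.
Metrics with zero denominators are reported as missing, not zero, so unit
level prevalence artefacts stay visible.

Classifier quality is summarised by ROC and precision-recall curves over
all score thresholds, computed on a sample that excludes training pixels
and preserves the true transition prevalence (100,000 pixels when
available). The skill baseline is a naive timing model that keeps the
transition pixels fixed and assigns each a uniformly random year within
its period, bootstrapped (500 replicates by default) to per-year means and
2.5/97.5 percentiles.

## The synthetic landscape

Because the original country-scale inputs are both huge and proprietary in
combination, the package ships a generator producing complete, seeded
inputs with known annual ground truth: a Voronoi partition into contiguous
units; a water mask from a smooth random field; per-unit logistic
pixel-count trajectories whose annual counts are enforced *exactly* while
placement is random with probability decaying in distance to the current
settlement; population tables and rasters internally consistent with the
configured density trajectories (uniform density inside BS, uniform rural
density outside); LAN brightness with a configurable jump at each pixel's
transition year plus Gaussian noise; and smooth random static covariates.

The generator emulates the *relative-change* structure the model feeds on:
demand recoverable from population alone, timing recoverable from LAN
alone, placement correlated with settlement proximity. It does **not**
emulate sensor artefacts (resolution switches, light blooming,
inter-sensor calibration), within-unit density gradients (available as a
config option only in the uniform sense), non-nested extents
(misclassification noise), or realistic settlement morphology. Passing
tests therefore demonstrate the machinery is correct and self-consistent
under the model's own assumptions — not that those assumptions hold for
any particular satellite product.

Two diagnostic modes separate error sources: `demand_source = "truth"`
replaces the demand table with the true per-year counts (isolating
allocation error), and `lanNoiseSd = 0` makes the LAN signal noiseless, in
which case the unit-rescaled lag identifies each year's true transition
pixels exactly and the pipeline should recover nearly every pixel's true
year — the test suite requires at least 95%.

## Problem sizes and reproducibility

The reference scenario used by the tests and the acceptance script is a
120 × 120 grid with 9 units, snapshots at 2000/2005/2010/2015 (three
five-year periods, 12 interpolated years), about 5% water, and roughly
1,800–2,000 transition pixels; module tests use 60 × 60 landscapes with
two 3-year periods. These sizes exercise every code path — multiple
units, periods, degenerate and non-degenerate LAN units, the training
cap logic — while keeping a full pipeline run in the tens of seconds.

One global seed fans out to fixed per-stage seeds (synthesis, sampling,
forest, tie-breaks, curves, naive bootstrap), so each stage is
independently reproducible and a rerun with the same configuration is
byte-identical, which the tests verify file by file. All randomness flows
through R's RNG; the forest is single-threaded with a fixed seed.

## Known limitations

* The demand model assumes BS population growth is logistic with the
  unit's total population as a moving ceiling and that growth in demand is
  realised instantly; economic drivers, policy, and lagged construction
  are outside the model.
* The unit-average BS density obscures within-unit gradients, which tends
  to delay modelled infill growth relative to edge growth.
* Observed snapshots are assumed nested (settlement never reverts);
  non-nested inputs trigger warnings and the affected pixels are simply
  passed through at observed years.
* Interpolation cannot be better than its inputs: errors in the snapshot
  extents propagate untouched, and the validation measures fidelity to
  the input series, not to ground truth.
* Raster exchange uses the plain-text ASCII grid format; reprojection,
  resampling and multi-band imagery are out of scope.
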