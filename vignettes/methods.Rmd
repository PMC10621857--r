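---
title: "Methods: landscape reconstruction, territory modeling and tactical-movement inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape reconstruction, territory modeling and tactical-movement inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillwatch)
```

`hillwatch` turns minute-resolution GPS focal-follow tracklogs of two
neighbouring territorial groups into three statistical analyses: the
likelihood to stop on peripheral hills, the modulation of activities by
location and elevation, and post-stop decisions to advance toward or
retreat from rivals. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions that were genuinely
open.

## Landscape reconstruction

Forest GPS receivers carried on daily follows re-visit the same ground on
many days. Binning all fixes onto a 10 m lattice (the receivers' accuracy
scale) and taking the **median elevation per cell** averages out
single-day altimetry error; with 3-5 passes per cell the within-cell
spread is on the order of 8-13 m, which motivates both the median and the
+-13 m elevation gate used later for visit detection. The lattice is
anchored at the arithmetic center of all fixes, and each fix joins the
cell with the nearest center; equidistant ties break toward the lower
cell index so assignment is deterministic.

**Peripheral hills** are connected components, under single linkage at
50 m (center to center), of the cells at or above the elevation
threshold; single linkage is the right closure here because ridges
connect supra-threshold cells into one physical hill. The default
threshold, 230 m, is the conventional 99th-percentile preset for the
landscapes this package targets; `elevation_percentile(grid, 99)`
recomputes it for any reconstruction (computed over cells by default —
computing it over raw fixes would over-weight heavily re-visited ground).
A hill's summit is its highest cell; exact elevation ties break to the
smallest y, then smallest x, a purely conventional choice made so results
are reproducible. **Low-elevation rest locations** are rest stops inside
the inter-group overlap band at or below 180 m (mean landscape elevation
minus one SD), merged within 50 m.

Because elevation comes only from tracklogs, cells exist only where
animals walked: an unvisited summit is invisible to the reconstruction.
Tests therefore score hill recovery against summits that the simulated
groups actually visited.

## Territory model

Space use is modeled as a kernel utilization distribution (UD): an
isotropic Gaussian kernel density with smoothing factor `h = 149` m
evaluated on a 25 m lattice with a 3h margin, normalized to unit volume.
The lattice resolution is our choice; halving it to 12.5 m leaves at
least 95% of kernel values within one unit (a tested property). Each location
gets a **kernel value**: the smallest k in 1..99 such that the location
falls inside the k% percent-volume contour — 1 is the most central,
heavily used ground; 75 and above is conventionally "periphery". The
**territory center** is the UD mode (an alternative `center = "mean"` is
available); the yearly territory size is the area of that year's 95%
volume contour, measured as the raster area of the supra-level region.

The **relative distance to the territory center** covariate divides the
Euclidean distance to the center by the *equivalent-circle radius*
`sqrt(area / pi)` of the yearly territory size, not by the area itself:
dividing by radius keeps the covariate dimensionless and linear in
distance, and the two choices differ only through the area-to-radius
nonlinearity across years. The quadratic control term is the square of
the z-transformed value.

The **overlap band** is the interval between the extreme western
location visited by the eastern group and the extreme eastern location
visited by the western group; its north-south extent is the range of
visited y within the band. It is a data-defined construct, so deep
incursions by either group widen it.

## Event extraction

A **visit** to a hill or low location is a maximal run of fixes within
50 m of the summit whose smoothed elevation is within 13 m of the
summit's — the elevation gate distinguishes using a hill top from
walking past its base. Runs separated by under 5 min merge. A **stop**
is a window of consecutive fixes spanning at least 5 min in which every
fix stays within 25 m of the window's first fix; 25 m is below the
combined GPS error and stationary drift, and the anchored-window form
has an exact brute-force oracle against which the implementation is
tested. **Departure** is the first time the party exceeds 50 m from the
location without returning within 5 min.

**Movement direction before arrival** ("toward the border" vs "toward
the center") is classified from the change of a peripherality measure
over the 30 min before arrival, with a dead-band for ambiguous
approaches (e.g. border-parallel travel). Two measures are implemented.
The kernel-value change (dead-band 5 units) is the UD's own
center-border scale, but it has two structural failure modes in exactly
the analysis regime: the kernel scale saturates near 95-99 across the
whole overlap band, so most in-band moves fall inside the dead-band;
and repeated stop-dwells concentrate UD density on summits, so arriving
at a well-used hill *lowers* the kernel value and the classifier can
reverse sign at the very sites the analysis cares about. The
extraction pipeline therefore defaults to the **change in distance to
the own territory center** (dead-band 250 m, about five minutes of
directed travel), which is monotone everywhere; a test checks that it
recovers the simulator's generated direction labels for the
overwhelming majority of matched events. Ambiguous-direction events
are excluded from the stop model, mirroring standard field practice.

**Advance vs retreat** compares the distance to the closest rival
party's position — frozen at the moment of departure — between departure
and the end of a 30-min horizon; changes within a 50 m dead-band are
undetermined and excluded. The endpoint comparison is the simplest
monotone statistic consistent with a binary advance/retreat coding; a
minimum-distance-in-window alternative would label a brief approach
followed by withdrawal as an advance, which is not the decision the
model is after. **Imbalance of power** is own adult party size minus the
rival adults aggregated over a trailing 30-min observation window.
**Intercommunity distance** is the per-minute distance to the closest
rival party, averaged over the location's usage (stop model) or taken at
departure (advance model); the advance model uses its natural logarithm,
taken before z-transformation, because rival detectability plausibly
changes much faster at short range.

## Statistical models

All three analyses are binomial logit mixed models fitted by maximum
likelihood (Laplace approximation, via `lme4`), with random intercepts
for location, date-within-group and focal individual (single-level
factors are dropped). Continuous covariates are z-transformed using the
modeling table's own mean and SD, computed after row exclusions — the
alternative (transforming before exclusions) differs only by an affine
map but would make printed coefficients irreproducible from the table
alone. Inference follows the likelihood-ratio convention: a full-null
test against a model with only controls and random effects, and
per-term p-values from `drop1_lrt()` refits that respect marginality (a
main effect is never dropped under its interaction). Model reduction
removes the least significant nonsignificant interaction first, highest
order first, refitting after each removal. Effect sizes are
Nakagawa-style marginal and conditional R² with the binomial-logit
distribution variance π²/3; collinearity is checked with
VIFs on the fixed-effects linear design; confidence intervals come from
a parametric bootstrap (simulate with freshly drawn random effects,
refit, percentile interval); stability refits the model leaving out each
random-effect level in turn; overdispersion is the Pearson χ²
over residual df.

### Temporal autocorrelation term

Minute-scale behavioural data are serially dependent. Two defenses are
used. First, the activity analysis thins each day to points at least
30 min apart — twice the mean activity-bout length, so consecutive kept
points rarely share a bout. Second, the event-level models add a
**temporal autocorrelation term**: for each row, the Gaussian-weighted
average of all other same-group residuals, with weights
`dnorm(t_i - t_j, sd = sigma)`. Residuals are taken on the response
scale against the *marginal* (fixed-effects-only) fitted probabilities
of the model without the term: conditional residuals would already have
the day-level correlation absorbed by the random intercepts, leaving
the term nothing to measure. The term is z-transformed and enters as a
fixed effect; `sigma` is chosen by maximizing the refit model's
likelihood over a log-spaced grid (default 25 points from 5 min to
24 h) with an optional golden-section refinement. The search is
restricted to candidates whose fitted AC coefficient lies in [0, 3]:
the term models positive serial dependence, and a large or negative
coefficient is the signature of a degenerate regime in which the
leave-one-out average — which at near-flat weights algebraically
contains `-r_i/(n-1)`, an anti-copy of the row's own residual —
lets the likelihood chase a copy of the response. If no candidate
qualifies (very sparse event streams), the base model is returned with
a warning rather than a spurious correction. Residuals come from a
one-shot scheme: base-model residuals, one refit with the term
included; the bandwidth search already refits the model once per
candidate, so a further iteration of the residuals was left out to
keep the estimator simple and deterministic. Weights are computed in log
space with a per-row shift so that very small bandwidths degrade
gracefully to the nearest-in-time residual rather than 0/0. Times are
absolute minutes, so both within-day and across-day lags contribute.
Diagnostics (`ac_diagnostics()`) correlate pairwise absolute residual
differences with time lags and map distances; because all-pairs work is
quadratic, the default pairing unit is the (group, day).

## The simulator

`sim_config()` / `gen_tracklogs()` generate a fully labeled synthetic
study so that every pipeline stage has recoverable ground truth. The
defaults encode the study conditions the package is designed for: a
~190 m lowland with +-16 m relief and 12 in-band inselbergs rising to
240-290 m; two territories whose centers sit 5 km apart with a ~2 km
overlap band; 1 fix/min follows of 600 min; group-specific mean bout
lengths (rest 15.07/11.6, feed 17.66/16.46, travel 7.15/5.61 min for
the western/eastern group); border patrols on 75% of focal days visiting
2-5 hills. Stop decisions follow
`logit p = -1.1 + 1.6 dir - 0.4 z(hills after) + RE` (intercept chosen
so that the marginal stop rates are roughly 25% toward the center and
58% toward the border); post-stop advance decisions follow
`logit p = -0.3 + 0.25 z(imbalance) + 0.2 z(ln d) z(elev) + 0.75 dir +
RE`; random-intercept SDs default to 0.5 (hill) and 0.3 (day, focal).
GPS noise is 5 m in the horizontal and 4 m in elevation, consistent
with handheld receivers under canopy.

Three design points matter for interpreting tests. (1) Each day one
group runs the decision-making focal program while the other serves as a
fully observed rival ranging between its core and the band edge; roles
alternate daily, so rival positions are always defined when decisions
are made and the band is not contaminated with off-model stop events.
(2) The ground-truth direction label of every visit is the *actual*
change in distance to the territory center over the last 30 simulated
minutes — after a retreat response, the next hill genuinely is
approached border-ward, and the label says so. (3) Travel legs detour
around hills they are not meant to visit, because the generator only
makes stop decisions at intended visits; without the detours, incidental
passes would be real non-stop visits that no decision produced,
attenuating recovered coefficients.

What the simulator does *not* emulate: real fission-fusion party
dynamics (party sizes are a per-day draw), vegetation and visibility,
vocal communication, seasonal range shifts, and observer loss of
contact. Passing tests therefore show that the pipeline recovers the
statistical structure it assumes from realistic geometry and noise —
not that real animals satisfy those assumptions.

## Problem sizes and numerical choices

The test suite exercises the oracle-equivalence properties on hundreds
of small random instances (exact to 1e-12 where real-valued), parameter
recovery at the field scale of roughly 700 visits over 100 seeds,
drop1 type-I calibration over 200 null simulations at n = 500, AC-bandwidth
recovery at n = 500 with a 60-min generating timescale, and the
end-to-end truth-agreement check on a 25-day simulated study. The
acceptance script regenerates a 200-day study (about 600-700 labeled
events, 240,000 fixes) and reruns the entire pipeline; the UD for each
group is fitted on every third fix — consecutive 1-min fixes are almost
redundant spatially, and a tested property keeps at least 95% of kernel
values within two units of the full-data UD — which keeps the density
evaluation affordable.
glmer fits use the bobyqa optimizer with derivative checks off;
convergence warnings are recorded on the returned object and refusals
propagate to downstream operations.

## Known limitations

- The landscape is reconstructed only where animals walked; hill
  detection cannot see unvisited summits, and summit positions inherit
  the 10 m bin quantization.
- Kernel values are computed from a single whole-study UD; only yearly
  territory *sizes* are recomputed per year. If space use drifts across
  years, kernel covariates are a study-average description.
- The advance/retreat label freezes the rival position at departure; a
  rival moving during the 30-min horizon can make a geometrically
  faithful "advance" end farther away than it began.
- Percent-volume contour areas are raster areas of the supra-level
  region; polygon exports are for display and may differ slightly at the
  lattice resolution.
- With only two groups, group-level predictors (e.g. the group control)
  rest on two levels and are identified mainly for parity with the
  field analyses.
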