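# hillwatch

Territorial animals that live in low-visibility habitat can use elevated
ground near their borders to listen for rivals and decide whether to
press on or pull back. `hillwatch` is an R package for testing that idea
from minute-resolution GPS focal-follow tracklogs of two neighbouring
groups. It reconstructs the landscape and the territories from the
tracklogs themselves, extracts the behavioural events, and fits the
binomial mixed models that carry the inference:

1. **Stop model** — does the likelihood of stopping (a pause of >= 5 min)
   on a peripheral hill depend on whether the party was travelling
   toward the border or toward the center, and on how many other hills
   it will still pass that day?
2. **Activity models** — are resting, feeding and travelling modulated
   by the interaction of elevation and location (UD kernel value) across
   the territory?
3. **Advance model** — after a stop at a peripheral hill or low
   location, does the decision to advance toward the closest rival party
   follow the imbalance of power and the (log) intercommunity distance,
   and does elevation change that dependence?

The toolkit around those models:

- **Landscape**: median-elevation raster from binned fixes (10 m cells,
  nearest-center assignment), 99th-percentile hill threshold, peripheral
  hills as single-linkage clusters at 50 m, low-elevation rest
  locations (<= 180 m).
- **Territory**: Gaussian-kernel utilization distributions (h = 149 m),
  percent-volume kernel values 1-99, contours and areas, overlap band
  between the groups, core-vs-periphery elevation tests
  (Mann-Whitney), relative distance to the territory center.
- **Events**: hill/low visits with an elevation gate, anchored-window
  stop detection, movement-direction classification with a dead-band,
  departures, advance/retreat vs the rival position at departure,
  aggregated rival party sizes, intercommunity distances.
- **GLMM inference**: ML binomial-logit mixed models (via lme4) with
  full-null and drop1 likelihood-ratio tests, marginality-respecting
  model reduction, Nakagawa R², VIFs, parametric-bootstrap CIs,
  leave-one-level-out stability, overdispersion, and a Gaussian-weighted
  **temporal autocorrelation term** whose bandwidth is chosen by
  maximizing the model likelihood.
- **Simulator**: a seeded two-group fission-fusion ranging generator
  (inselberg landscape, border patrols, scripted stop and
  advance/retreat decisions with configurable logistic coefficients)
  that gives every stage a recoverable ground truth.

## Worked example

Simulate a 60-day study, run the extraction chain, and fit the stop
model:

```r
library(hillwatch)

cfg    <- sim_config(seed = 7, days = 60)
sim    <- gen_tracklogs(cfg)
follows <- unique(sim$minutes[, c("follow_id", "sex_class")])
follows$sex <- ifelse(follows$sex_class == "male", "male", "female")

events <- extract_study_events(sim$fixes, sim$parties, follows = follows)
events
#> <study_events> 13 hills, 21 low locations, 319 visits (116 stops)

stop_res <- run_stop_analysis(events, reduce = FALSE)
dplyr::select(tidy(stop_res$full)[1:6, ], term, estimate, std.error)
#> # A tibble: 6 x 3
#>   term                   estimate std.error
#>   <chr>                     <dbl>     <dbl>
#> 1 (Intercept)            -1.14        0.613
#> 2 directiontoward_border  1.57        0.555
#> 3 n_hills_before_z       -0.132       0.330
#> 4 n_hills_after_z        -0.384       0.277
#> 5 adult_party_size_z      0.00593     0.206
#> 6 intercomm_dist_z       -0.0365      0.197
```

The generator's stop rule used a direction coefficient of 1.6 and a
hills-after coefficient of -0.4 (z scale): the fitted model recovers
1.57 +- 0.56 and -0.38 +- 0.28 from the noisy tracklogs alone. The
intercept of -1.14 corresponds to a ~24% stop rate for center-ward
approaches. `glance(stop_res$full)` adds likelihood, Nakagawa R²
(here marginal 0.14, conditional 0.21) and the dispersion statistic
(1.05, no overdispersion); `truth_agreement(sim$truth$events,
events$visits)` confirms that 100% of the generated events were
re-extracted with the correct stop label.

The advance analysis adds the temporal autocorrelation term:

```r
adv <- run_advance_analysis(events)          # reduction + AC bandwidth fit
adv$ac$sigma                                  # chosen Gaussian SD, minutes
plot_ac_profile(adv$ac)                       # likelihood profile
autoplot(events$grid, hills = events$hills)   # reconstructed landscape
```

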