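# Orchestration: tracklogs -> landscape -> territories -> events ->
# modeling tables -> fitted models. Each runner returns the fitted model
# bundle (full, null, reduced) plus the dataset it was fitted on, so every
# intermediate is inspectable.

#' Extract all analysis units from a two-group tracklog study
#'
#' Runs the full extraction chain: median-elevation grid, per-group
#' kernel UD territories, overlap band, peripheral hills (supra-threshold
#' cells clustered at 50 m inside the band), low-elevation rest locations,
#' hill/low visits with stop detection, movement direction, departure and
#' advance/retreat classification, and all model covariates.
#'
#' @param fixes fix table (`time, x, y, elev, group, follow_id,
#'   focal_id`), two groups.
#' @param parties party observations (`time, group, party_id,
#'   adult_party_size`).
#' @param follows optional tibble `follow_id, sex` (focal sex per follow);
#'   when absent sex is `"unknown"`.
#' @param h UD smoothing factor in meters (default 149).
#' @param bin_size elevation bin size (default 10 m).
#' @param elev_threshold hill threshold in meters, or `"p99"` to use the
#'   99th percentile of the reconstructed elevations (default 230).
#' @param link_dist hill clustering distance (default 50 m).
#' @param radius use radius around summits (default 50 m).
#' @param elev_tol elevation gate for visits (default 13 m).
#' @param low_max_elev low-location threshold (default 180 m).
#' @param ud_thin use every k-th fix for the UD fit (default 3; kernel
#'   values are insensitive to moderate thinning).
#' @param direction_measure peripherality axis for the movement-direction
#'   classifier: `"center_dist"` (default; distance to the own territory
#'   center) or `"kernel"` (see [classify_direction()]).
#' @param dir_deadband direction dead-band, in the measure's units
#'   (default 250 m for `center_dist`, 5 units for `kernel`).
#' @return a `study_events` list: `grid, band, hills, low_locs,
#'   territories, fixes` (annotated), `visits` (with covariates), `stops`
#'   (with advance labels).
#' @export
extract_study_events <- function(fixes, parties, follows = NULL, h = 149,
                                 bin_size = 10, elev_threshold = 230,
                                 link_dist = 50, radius = 50, elev_tol = 13,
                                 low_max_elev = 180, ud_thin = 3,
                                 direction_measure = c("center_dist",
                                                       "kernel"),
                                 dir_deadband = NULL) {
  direction_measure <- match.arg(direction_measure)
  if (is.null(dir_deadband)) {
    dir_deadband <- if (direction_measure == "center_dist") 250 else 5
  }
  fixes <- tibble::as_tibble(fixes)
  stop_if_missing_cols(fixes, c("time", "x", "y", "elev", "group",
                                "follow_id"), "fix table")
  if (!"focal_id" %in% names(fixes)) fixes$focal_id <- fixes$follow_id
  grid <- build_grid(fixes, grid_spec(bin_size = bin_size))
  fixes <- annotate_elevation(fixes, grid)
  groups <- sort(unique(fixes$group))
  if (length(groups) != 2) stop("extract_study_events: need exactly 2 groups")
  mean_x <- vapply(groups, function(g) mean(fixes$x[fixes$group == g]),
                   numeric(1))
  west <- groups[which.min(mean_x)]; east <- groups[which.max(mean_x)]
  band <- overlap_band(fixes[fixes$group == west, ],
                       fixes[fixes$group == east, ])
  if (identical(elev_threshold, "p99")) {
    elev_threshold <- elevation_percentile(grid, 99)
  }
  hills <- detect_hills(grid, elev_threshold, link_dist,
                        mask = band_mask(band))
  territories <- lapply(stats::setNames(groups, groups), function(g) {
    gf <- fixes[fixes$group == g, ]
    territory_model(gf[seq(1, nrow(gf), by = ud_thin), ], h = h)
  })
  fixes$kernel <- NA_integer_
  fixes$center_dist <- NA_real_
  for (g in groups) {
    sel <- fixes$group == g
    fixes$kernel[sel] <- kernel_value(territories[[g]]$ud, fixes$x[sel],
                                      fixes$y[sel])
    ctr <- territories[[g]]$center_xy
    fixes$center_dist[sel] <- sqrt((fixes$x[sel] - ctr[1])^2 +
                                     (fixes$y[sel] - ctr[2])^2)
  }
  # low-elevation rest locations: stationary episodes inside the band, at
  # low smoothed elevation, away from hills, pooled over both groups
  rests <- purrr::map_dfr(groups, function(g) {
    find_rest_stops(fixes[fixes$group == g, ], band,
                    max_elev = low_max_elev, hills = hills,
                    move_thresh = 25, min_dur = 5)
  })
  low_locs <- detect_low_locations(rests, max_elev = low_max_elev,
                                   merge_dist = 50)
  visits <- purrr::map_dfr(groups, function(g) {
    track <- fixes[fixes$group == g, ]
    track <- track[order(time_minutes(track$time)), ]
    vh <- detect_visits(track, hills, radius = radius, elev_tol = elev_tol)
    vl <- if (nrow(low_locs)) {
      detect_visits(track, low_locs, radius = radius, elev_tol = elev_tol)
    } else empty_visits()
    v <- dplyr::bind_rows(vh, vl)
    if (!nrow(v)) return(v)
    own_parties <- parties[parties$group == g, ]
    rival_track <- fixes[fixes$group != g, ]
    rival_parties <- parties[parties$group != g, ]
    v$direction <- vapply(seq_len(nrow(v)), function(i) {
      tr <- track[track$follow_id == v$follow_id[i], ]
      suppressWarnings(classify_direction(tr, v$t_arrive[i],
                                          deadband = dir_deadband,
                                          measure = direction_measure))
    }, character(1))
    v$adult_party_size <- vapply(seq_len(nrow(v)), function(i) {
      rival_party_size(own_parties, v$t_arrive[i])
    }, numeric(1))
    v$intercomm_dist <- vapply(seq_len(nrow(v)), function(i) {
      intercommunity_distance(track, rival_track, v$t_arrive[i],
                              v$t_last_inside[i], mode = "mean_over_use")
    }, numeric(1))
    v$rel_center_dist <- relative_center_distance(v$x, v$y, territories[[g]])
    v$kernel <- kernel_value(territories[[g]]$ud, v$x, v$y)
    v$time_of_day <- (v$t_arrive %% 1440) / 60
    v$focal_id <- track$focal_id[match(v$follow_id, track$follow_id)]
    # departure + advance/retreat for stop events
    v$t_depart <- NA_real_; v$advance <- NA_character_
    v$imbalance <- NA_real_; v$dist_at_depart <- NA_real_
    rtm <- time_minutes(rival_track$time)
    for (i in which(v$stopped)) {
      tr <- track[track$follow_id == v$follow_id[i], ]
      td <- detect_departure(tr, v$x[i], v$y[i], v$t_arrive[i])
      v$t_depart[i] <- td
      if (is.na(td)) next
      j <- which.min(abs(rtm - td))
      if (abs(rtm[j] - td) > 2) next
      rxy <- c(rival_track$x[j], rival_track$y[j])
      v$advance[i] <- classify_advance(tr, td, rxy[1], rxy[2])
      own_i <- which.min(abs(time_minutes(tr$time) - td))
      v$dist_at_depart[i] <- sqrt((tr$x[own_i] - rxy[1])^2 +
                                    (tr$y[own_i] - rxy[2])^2)
      riv_n <- rival_party_size(rival_parties, td)
      v$imbalance[i] <- v$adult_party_size[i] - riv_n
    }
    v
  })
  if (nrow(visits)) {
    visits <- hills_before_after(visits)
    if (!is.null(follows)) {
      visits$sex <- follows$sex[match(visits$follow_id, follows$follow_id)]
    } else visits$sex <- "unknown"
  }
  stops <- visits[visits$stopped %in% TRUE, ]
  structure(list(grid = grid, band = band, hills = hills,
                 low_locs = low_locs, territories = territories,
                 fixes = fixes, visits = visits, stops = stops),
            class = "study_events")
}

#' @export
print.study_events <- function(x, ...) {
  cat("<study_events> ", nrow(x$hills), " hills, ", nrow(x$low_locs),
      " low locations, ", nrow(x$visits), " visits (",
      sum(x$visits$stopped), " stops)\n", sep = "")
  invisible(x)
}

#' Stationary low-elevation episodes inside the overlap band
#'
#' Scans a track for maximal stationary episodes (every fix within
#' `move_thresh` of the episode's first fix, lasting at least `min_dur`
#' minutes) whose centroid lies in the band at a smoothed elevation of at
#' most `max_elev`, excluding episodes within 2x the use radius of a
#' detected hill (those are hill stops).
#'
#' @param track annotated fixes of one group.
#' @param band an [overlap_band()].
#' @param max_elev meters (default 180).
#' @param hills optional hill table for the exclusion buffer.
#' @param min_dur,move_thresh stop rule.
#' @return tibble of rest-stop episodes (`group, follow_id, t_arrive,
#'   t_end, x, y, smoothed_elev`).
#' @export
find_rest_stops <- function(track, band, max_elev = 180, hills = NULL,
                            min_dur = 5, move_thresh = 25) {
  out <- list()
  inband <- band_mask(band)
  for (fid in unique(track$follow_id)) {
    tr <- track[track$follow_id == fid, ]
    tm <- time_minutes(tr$time)
    o <- order(tm); tr <- tr[o, ]; tm <- tm[o]
    n <- nrow(tr); i <- 1
    while (i <= n) {
      d <- sqrt((tr$x[i:n] - tr$x[i])^2 + (tr$y[i:n] - tr$y[i])^2)
      jrel <- which(d > move_thresh)
      j <- if (length(jrel)) i + jrel[1] - 2 else n
      if (tm[j] - tm[i] + 1 >= min_dur) {
        cx <- mean(tr$x[i:j]); cy <- mean(tr$y[i:j])
        el <- stats::median(tr$smoothed_elev[i:j])
        keep <- inband(cx, cy) && el <= max_elev
        if (keep && !is.null(hills) && nrow(hills)) {
          dh <- min(sqrt((hills$summit_x - cx)^2 + (hills$summit_y - cy)^2))
          keep <- dh > 100
        }
        if (keep) {
          out[[length(out) + 1]] <- tibble::tibble(
            group = tr$group[1], follow_id = fid, t_arrive = tm[i],
            t_end = tm[j], x = cx, y = cy, smoothed_elev = el)
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (!length(out)) {
    return(tibble::tibble(group = character(), follow_id = character(),
                          t_arrive = numeric(), t_end = numeric(),
                          x = numeric(), y = numeric(),
                          smoothed_elev = numeric()))
  }
  dplyr::bind_rows(out)
}

stop_controls <- c("rel_center_dist_z", "rel_center_dist_z2", "kernel_z",
                   "elev_z", "time_of_day_z", "sex", "group")
stop_tests <- c("direction", "n_hills_before_z", "n_hills_after_z",
                "adult_party_size_z", "intercomm_dist_z",
                "adult_party_size_z:intercomm_dist_z")
adv_controls <- c("rel_center_dist_z", "rel_center_dist_z2", "kernel_z",
                  "time_of_day_z", "sex", "group")
adv_tests <- c("direction_num_z", "n_hills_before_z", "n_hills_after_z",
               "elev_z", "imbalance_z", "ln_dist_z",
               "elev_z:imbalance_z", "elev_z:ln_dist_z",
               "imbalance_z:ln_dist_z", "elev_z:imbalance_z:ln_dist_z")

drop_constant_terms <- function(terms, data) {
  keep <- vapply(terms, function(tm) {
    cols <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(cols, function(cl) {
      !cl %in% names(data) || length(unique(data[[cl]])) > 1
    }, logical(1)))
  }, logical(1))
  terms[keep]
}

#' Fit the stop model (likelihood to stop at peripheral hills)
#'
#' Full model: movement direction, hills before/after the same day, own
#' adult party size, intercommunity distance and the party-size x
#' distance interaction, plus controls (relative center distance and its
#' quadratic, kernel value, elevation, time of day, sex, group) and
#' random intercepts for hill, date-in-group and focal. The null model
#' keeps only controls and random effects.
#'
#' @param events a `study_events` (or a ready covariate table of hill
#'   visits).
#' @param reduce also compute the interaction-reduced model (default
#'   `TRUE`).
#' @return list `dataset, full, null, reduced, lrt, drop1`.
#' @export
run_stop_analysis <- function(events, reduce = TRUE) {
  v <- if (inherits(events, "study_events")) {
    events$visits[events$visits$location_type == "hill", ]
  } else tibble::as_tibble(events)
  if (!nrow(v)) stop("run_stop_analysis: no hill visits")
  ds <- build_stop_dataset(v)
  if (nrow(ds) < 30) stop("run_stop_analysis: too few usable visits (",
                          nrow(ds), ")")
  tests <- drop_constant_terms(stop_tests, ds)
  controls <- drop_constant_terms(stop_controls, ds)
  rand <- c("hill_id", "date_group", "focal_id")
  full <- hill_glmm(ds, "stopped", c(tests, controls), rand)
  null <- hill_glmm(ds, "stopped", controls, rand)
  out <- list(dataset = ds, full = full, null = null,
              reduced = if (reduce) reduce_model(full) else NULL,
              lrt = lrt_full_null(full, null))
  out$drop1 <- drop1_lrt(if (reduce) out$reduced else full)
  out
}

#' Fit the advance model (likelihood to advance towards rivals)
#'
#' Full model: movement direction (numeric), hills before/after,
#' elevation, imbalance of power, ln intercommunity distance at
#' departure, all two-way and the three-way interaction of the last
#' three, plus controls and random intercepts. After interaction
#' reduction, a Gaussian-weighted temporal autocorrelation term is added
#' with its SD chosen by likelihood maximization.
#'
#' @param events a `study_events` (stop events are taken from it) or a
#'   ready stop-event covariate table.
#' @param ac fit the autocorrelation term (default `TRUE`).
#' @param sigma_grid candidate AC bandwidths (minutes).
#' @return list `dataset, full, null, reduced, lrt, drop1, ac`
#'   (`ac$sigma`, `ac$fit`, `ac$profile`).
#' @export
run_advance_analysis <- function(events, ac = TRUE,
                                 sigma_grid = exp(seq(log(5), log(1440),
                                                      length.out = 15))) {
  st <- if (inherits(events, "study_events")) events$stops else
    tibble::as_tibble(events)
  if (!nrow(st)) stop("run_advance_analysis: no stop events")
  ds <- build_advance_dataset(st)
  if (nrow(ds) < 30) stop("run_advance_analysis: too few advance records (",
                          nrow(ds), ")")
  tests <- drop_constant_terms(adv_tests, ds)
  controls <- drop_constant_terms(adv_controls, ds)
  rand <- c("location_id", "date_group", "focal_id")
  full <- hill_glmm(ds, "advance", c(tests, controls), rand)
  null <- hill_glmm(ds, "advance", controls, rand)
  reduced <- reduce_model(full)
  out <- list(dataset = ds, full = full, null = null, reduced = reduced,
              lrt = lrt_full_null(full, null))
  if (ac) {
    out$ac <- fit_ac_sigma(reduced, times = ds$t_arrive, groups = ds$group,
                           sigma_grid = sigma_grid)
    out$drop1 <- drop1_lrt(out$ac$fit)
  } else {
    out$drop1 <- drop1_lrt(reduced)
  }
  out
}

#' Fit the three activity models (rest, feed, travel)
#'
#' Thins the minute stream to 30-min spacing within day, builds the three
#' binary-response tables, and fits for each activity a binomial GLMM
#' with the kernel-value x elevation interaction as test predictor and
#' the standard controls; the reduced model drops a nonsignificant
#' interaction.
#'
#' @param minutes minute-point table with `activity`, covariates, and
#'   either precomputed `kernel`/`elev` or raw coordinates to annotate
#'   via `events`.
#' @param events optional `study_events` used to annotate kernel and
#'   smoothed elevation from coordinates.
#' @param spacing thinning interval (default 30 min).
#' @return named list (`rest`, `feed`, `travel`) of lists
#'   `dataset, full, null, reduced, lrt`, plus `budgets`.
#' @export
run_activity_analysis <- function(minutes, events = NULL, spacing = 30) {
  minutes <- tibble::as_tibble(minutes)
  if (!is.null(events)) {
    minutes <- annotate_elevation(minutes, events$grid, missing = "nearest")
    minutes$kernel <- NA_integer_
    for (g in names(events$territories)) {
      sel <- minutes$group == g
      minutes$kernel[sel] <- kernel_value(events$territories[[g]]$ud,
                                          minutes$x[sel], minutes$y[sel])
    }
    minutes$elev <- minutes$smoothed_elev
  }
  thinned <- thin_minutes(minutes, spacing = spacing)
  tables <- build_activity_dataset(thinned)
  controls <- c("sex_class", "group", "day_sin", "day_cos", "party_size_z",
                "food_avail_z", "n_oestrus_z")
  res <- lapply(tables, function(d) {
    controls_d <- drop_constant_terms(controls, d)
    tests <- c("kernel_z", "elev_z", "kernel_z:elev_z")
    rand <- c("date_group", "focal_id")
    full <- hill_glmm(d, "response", c(tests, controls_d), rand)
    null <- hill_glmm(d, "response", controls_d, rand)
    inter_p <- drop1_lrt(full, terms = "kernel_z:elev_z")$p_value
    reduced <- if (inter_p >= 0.05) {
      hill_glmm(d, "response", c("kernel_z", "elev_z", controls_d), rand)
    } else full
    list(dataset = d, full = full, null = null, reduced = reduced,
         lrt = lrt_full_null(full, null), interaction_p = inter_p)
  })
  res$budgets <- activity_budgets(minutes, by_group = TRUE)
  res
}

#' Compare extracted events with simulator ground truth
#'
#' Matches each true event (hill visit or low-location rest) to an
#' extracted visit of the same group and day within `max_dist` meters and
#' `max_dt` minutes of arrival, and scores the agreement of the stop
#' label. The residual disagreement quantifies rule/noise sensitivity.
#'
#' @param truth_events the simulator's `truth$events`.
#' @param visits extracted visit table.
#' @param max_dist meters (default 75).
#' @param max_dt minutes (default 15).
#' @return list `match_rate`, `stop_agreement` (among matched),
#'   `label_agreement` (matched AND same stop label, over all truth
#'   events), `n_truth`.
#' @export
truth_agreement <- function(truth_events, visits, max_dist = 75,
                            max_dt = 15) {
  n <- nrow(truth_events)
  matched <- logical(n); same <- logical(n)
  for (i in seq_len(n)) {
    te <- truth_events[i, ]
    cand <- visits[visits$group == te$group &
                     visits$follow_id == te$follow_id, ]
    if (!nrow(cand)) next
    d <- sqrt((cand$x - te$x)^2 + (cand$y - te$y)^2)
    dt <- abs(cand$t_arrive - te$t_arrive)
    ok <- d <= max_dist & dt <= max_dt
    if (!any(ok)) next
    matched[i] <- TRUE
    j <- which(ok)[which.min(dt[ok])]
    same[i] <- cand$stopped[j] == te$stopped
  }
  list(match_rate = mean(matched),
       stop_agreement = if (any(matched)) mean(same[matched]) else NA_real_,
       label_agreement = mean(matched & same),
       n_truth = n)
}

#' Load a study bundle written by [gen_fixture_suite()]
#'
#' @param dir bundle directory.
#' @return list `fixes, parties, minutes, truth`.
#' @export
load_study_bundle <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  list(fixes = rd("fixes.csv"), parties = rd("parties.csv"),
       minutes = rd("minutes.csv"),
       truth = list(hills = rd("truth_hills.csv"),
                    events = rd("truth_events.csv")))
}

#' Load a pre-assembled modeling table with a column mapping
#'
#' For externally supplied per-event model tables (CSV): renames columns
#' according to `mapping` (`c(new = "old", ...)`) and validates that the
#' required variables are present, failing loudly on a mismatch.
#'
#' @param path CSV path.
#' @param mapping named character vector, `new_name = "file_column"`.
#' @param required character vector of required (new) names.
#' @return tibble.
#' @export
load_model_table <- function(path, mapping = character(), required = names(mapping)) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (length(mapping)) {
    miss <- setdiff(unname(mapping), names(d))
    if (length(miss)) stop("load_model_table: file lacks column(s): ",
                           paste(miss, collapse = ", "))
    d <- dplyr::rename(d, !!!rlang::set_names(mapping, names(mapping)))
  }
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("load_model_table: missing required variable(s): ",
                         paste(miss, collapse = ", "))
  tibble::as_tibble(d)
}
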