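# Behavioral event extraction. The analysis units are visits to peripheral
# hills / low locations (any minute within the use radius at a matching
# elevation), stop events (>= 5 min pause), the travel direction before
# arrival (center -> border axis measured on UD kernel values), departures,
# and post-stop advance/retreat decisions relative to the closest rival
# party's position at departure time.

#' Detect visits to hills or low locations on a track
#'
#' A visit is a maximal run of fixes within `radius` of a location's
#' summit/center whose smoothed elevation is within `elev_tol` of the
#' location's elevation (the elevation gate rejects e.g. passing below a
#' cliff). Runs at the same location separated by less than `merge_gap`
#' minutes merge. Stop detection ([detect_stop()]) is applied to each
#' visit's fixes.
#'
#' @param track one group's fixes, with `time, x, y, smoothed_elev, group,
#'   follow_id` (time-ordered within follow).
#' @param locations tibble of hills (`hill_id, summit_x, summit_y,
#'   summit_elev`) or low locations (`loc_id, x, y, elev`).
#' @param radius use radius in meters (default 50).
#' @param elev_tol elevation gate in meters (default 13, the maximum
#'   within-bin elevation variation of the reconstruction).
#' @param merge_gap minutes (default 5).
#' @param min_stop,move_thresh stop rule, see [detect_stop()].
#' @return tibble of visits: `visit_id, location_id, location_type, group,
#'   follow_id, t_arrive, t_last_inside, stopped, stop_minutes, elev, x, y`.
#' @export
detect_visits <- function(track, locations, radius = 50, elev_tol = 13,
                          merge_gap = 5, min_stop = 5, move_thresh = 25) {
  track <- tibble::as_tibble(track)
  stop_if_missing_cols(track, c("time", "x", "y", "smoothed_elev", "group",
                                "follow_id"), "track")
  locations <- normalize_locations(locations)
  if (!nrow(locations) || !nrow(track)) return(empty_visits())
  tm <- time_minutes(track$time)
  out <- list()
  for (li in seq_len(nrow(locations))) {
    loc <- locations[li, ]
    d <- sqrt((track$x - loc$x)^2 + (track$y - loc$y)^2)
    inside <- d <= radius & abs(track$smoothed_elev - loc$elev) <= elev_tol
    for (fid in unique(track$follow_id[inside])) {
      sel <- which(inside & track$follow_id == fid)
      sel <- sel[order(tm[sel])]
      # split into runs: new run when gap between successive inside fixes
      # is >= merge_gap minutes
      run <- cumsum(c(1, diff(tm[sel]) >= merge_gap))
      for (r in split(sel, run)) {
        st <- detect_stop(track[r, ], min_dur = min_stop,
                          move_thresh = move_thresh)
        out[[length(out) + 1]] <- tibble::tibble(
          location_id = loc$id, location_type = loc$type,
          group = track$group[r[1]], follow_id = fid,
          t_arrive = tm[r[1]], t_last_inside = tm[r[length(r)]],
          stopped = st$stopped, stop_minutes = st$stop_minutes,
          elev = loc$elev, x = loc$x, y = loc$y)
      }
    }
  }
  if (!length(out)) return(empty_visits())
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$group, .data$t_arrive) |>
    dplyr::mutate(visit_id = dplyr::row_number(), .before = 1)
}

normalize_locations <- function(locations) {
  locations <- tibble::as_tibble(locations)
  if ("summit_x" %in% names(locations)) {
    tibble::tibble(id = locations$hill_id, type = "hill",
                   x = locations$summit_x, y = locations$summit_y,
                   elev = locations$summit_elev)
  } else {
    stop_if_missing_cols(locations, c("loc_id", "x", "y", "elev"), "locations")
    tibble::tibble(id = locations$loc_id, type = "low",
                   x = locations$x, y = locations$y, elev = locations$elev)
  }
}

empty_visits <- function() {
  tibble::tibble(visit_id = integer(), location_id = integer(),
                 location_type = character(), group = character(),
                 follow_id = character(), t_arrive = numeric(),
                 t_last_inside = numeric(), stopped = logical(),
                 stop_minutes = numeric(), elev = numeric(),
                 x = numeric(), y = numeric())
}

#' Stop detection within a visit
#'
#' A stop is a window of consecutive fixes spanning at least `min_dur`
#' minutes in which every fix stays within `move_thresh` of the window's
#' first fix. With 1-min sampling a window of k fixes counts as k minutes.
#'
#' @param visit_fixes tibble with `time, x, y`.
#' @param min_dur minimum pause length in minutes (default 5).
#' @param move_thresh anchored displacement threshold in meters (default 25).
#' @return list `stopped` (logical), `stop_minutes` (longest qualifying
#'   window, 0 when none).
#' @export
detect_stop <- function(visit_fixes, min_dur = 5, move_thresh = 25) {
  if (!nrow(visit_fixes)) return(list(stopped = FALSE, stop_minutes = 0))
  tm <- time_minutes(visit_fixes$time)
  o <- order(tm)
  x <- visit_fixes$x[o]; y <- visit_fixes$y[o]; tm <- tm[o]
  n <- length(tm)
  best <- 0
  for (i in seq_len(n)) {
    d <- sqrt((x[i:n] - x[i])^2 + (y[i:n] - y[i])^2)
    jrel <- which(d > move_thresh)
    j <- if (length(jrel)) i + jrel[1] - 2 else n
    dur <- tm[j] - tm[i] + 1
    if (dur > best) best <- dur
  }
  stopped <- best >= min_dur
  list(stopped = stopped, stop_minutes = if (stopped) best else 0)
}

#' Classify travel direction before arriving at a location
#'
#' Direction on the center/border axis is measured as the change in a
#' peripherality measure over the `lookback` window before arrival: an
#' increase beyond the dead-band means travel toward the border, a
#' decrease toward the center, anything within the dead-band is ambiguous
#' (such events are excluded from the stop model, as are e.g. purely
#' north-south moves).
#'
#' Two measures are supported: `"kernel"` (UD kernel value, dead-band in
#' kernel units) and `"center_dist"` (distance to the own territory
#' center in meters, dead-band in meters). The kernel axis is the UD's
#' own center/border scale but saturates near the range edge and is bent
#' locally by use-density feedback at heavily used stop sites; the
#' distance axis is monotone everywhere, so the extraction pipeline
#' defaults to it.
#'
#' @param track fixes with `time` and the measure column (`kernel` or
#'   `center_dist`).
#' @param t_arrive arrival time (minutes or POSIXct).
#' @param lookback minutes (default 30).
#' @param deadband dead-band in measure units (default 5 kernel units;
#'   use ~250 m for `center_dist`).
#' @param measure `"kernel"` (default) or `"center_dist"`.
#' @return one of `"toward_border"`, `"toward_center"`, `"ambiguous"`.
#' @export
classify_direction <- function(track, t_arrive, lookback = 30, deadband = 5,
                               measure = c("kernel", "center_dist")) {
  measure <- match.arg(measure)
  tm <- time_minutes(track$time)
  t_arrive <- time_minutes(t_arrive)
  win <- which(tm >= t_arrive - lookback & tm <= t_arrive)
  if (length(win) < 2) {
    warning("classify_direction: insufficient lookback track; ambiguous")
    return("ambiguous")
  }
  v <- track[[measure]]
  k0 <- v[win[which.min(tm[win])]]
  k1 <- v[win[which.max(tm[win])]]
  delta <- k1 - k0
  if (delta > deadband) "toward_border"
  else if (delta < -deadband) "toward_center"
  else "ambiguous"
}

#' Count same-day hill visits before and after each visit
#'
#' Within each (group, follow) day, each visit is annotated with the
#' number of hill visits earlier and later the same day (low-location
#' visits are annotated too but only hill visits are counted).
#'
#' @param visits a [detect_visits()] table.
#' @return `visits` with `n_hills_before`, `n_hills_after` columns.
#' @export
hills_before_after <- function(visits) {
  visits |>
    dplyr::group_by(.data$group, .data$follow_id) |>
    dplyr::mutate(
      n_hills_before = vapply(seq_len(dplyr::n()), function(i) {
        sum(.data$location_type == "hill" & .data$t_arrive < .data$t_arrive[i])
      }, numeric(1)),
      n_hills_after = vapply(seq_len(dplyr::n()), function(i) {
        sum(.data$location_type == "hill" & .data$t_arrive > .data$t_arrive[i])
      }, numeric(1))) |>
    dplyr::ungroup()
}

#' Aggregated rival adult party size in a trailing window
#'
#' Number of adults across distinct rival parties observed in
#' `(t - window, t]`; for each party the latest observation in the window
#' counts.
#'
#' @param rival_obs tibble with `time, party_id, adult_party_size`.
#' @param t reference time.
#' @param window minutes (default 30).
#' @return count, or `NA` when no rival observation falls in the window.
#' @export
rival_party_size <- function(rival_obs, t, window = 30) {
  tm <- time_minutes(rival_obs$time)
  t <- time_minutes(t)
  sel <- rival_obs[tm > t - window & tm <= t, ]
  if (!nrow(sel)) return(NA_real_)
  sel$.t <- time_minutes(sel$time)
  sel |>
    dplyr::group_by(.data$party_id) |>
    dplyr::slice_max(.data$.t, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$adult_party_size) |>
    sum()
}

#' Intercommunity distance to the closest rival party
#'
#' Per-minute distance from the own track to the closest simultaneously
#' followed rival party, either averaged over a location's usage interval
#' or taken at the departure minute.
#'
#' @param own_track fixes with `time, x, y`.
#' @param rival_tracks fixes with `time, x, y` and optionally `party_id`.
#' @param t_from,t_to interval bounds (minutes or POSIXct).
#' @param mode `"mean_over_use"` or `"at_departure"`.
#' @return meters, or `NA` when there is no simultaneous rival fix.
#' @export
intercommunity_distance <- function(own_track, rival_tracks, t_from, t_to,
                                    mode = c("mean_over_use", "at_departure")) {
  mode <- match.arg(mode)
  t_from <- time_minutes(t_from); t_to <- time_minutes(t_to)
  own <- tibble::tibble(minute = round(time_minutes(own_track$time)),
                        x = own_track$x, y = own_track$y)
  if (!"party_id" %in% names(rival_tracks)) rival_tracks$party_id <- "p1"
  riv <- tibble::tibble(minute = round(time_minutes(rival_tracks$time)),
                        x = rival_tracks$x, y = rival_tracks$y,
                        party_id = rival_tracks$party_id)
  mins <- if (mode == "at_departure") round(t_to) else
    seq(ceiling(t_from), floor(t_to))
  dd <- own |>
    dplyr::filter(.data$minute %in% mins) |>
    dplyr::inner_join(riv, by = "minute", suffix = c("", "_riv"),
                      relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((.data$x - .data$x_riv)^2 +
                             (.data$y - .data$y_riv)^2))
  if (!nrow(dd)) return(NA_real_)
  dd <- dd |>
    dplyr::group_by(.data$minute) |>
    dplyr::summarise(d = min(.data$d), .groups = "drop")
  mean(dd$d)
}

#' Departure time from a location
#'
#' First time at or after `t_after` at which the party is farther than
#' `leave_dist` from the location and does not come back inside within
#' `reentry` minutes.
#'
#' @param track fixes with `time, x, y`.
#' @param loc_x,loc_y location (meters).
#' @param t_after earliest admissible departure time.
#' @param leave_dist meters (default 50).
#' @param reentry minutes (default 5).
#' @return departure time in minutes, or `NA` when the track ends inside.
#' @export
detect_departure <- function(track, loc_x, loc_y, t_after, leave_dist = 50,
                             reentry = 5) {
  tm <- time_minutes(track$time)
  o <- order(tm)
  tm <- tm[o]
  d <- sqrt((track$x[o] - loc_x)^2 + (track$y[o] - loc_y)^2)
  cand <- which(tm >= time_minutes(t_after) & d > leave_dist)
  for (i in cand) {
    back <- which(tm > tm[i] & tm <= tm[i] + reentry & d <= leave_dist)
    if (!length(back)) return(tm[i])
  }
  NA_real_
}

#' Advance or retreat relative to rivals after departure
#'
#' Compares the distance to the rival position (fixed at the moment of
#' departure) at departure and at the end of a `horizon`-minute window; a
#' decrease beyond the dead-band is an advance, an increase a retreat,
#' anything else undetermined (excluded from the advance model).
#'
#' @param track own fixes with `time, x, y` extending past departure.
#' @param t_depart departure time.
#' @param rival_x,rival_y closest rival party position at departure.
#' @param horizon minutes (default 30).
#' @param deadband meters (default 50).
#' @param min_post minimum post-departure track length in minutes (default 5).
#' @return one of `"advance"`, `"retreat"`, `"undetermined"`.
#' @export
classify_advance <- function(track, t_depart, rival_x, rival_y, horizon = 30,
                             deadband = 50, min_post = 5) {
  if (is.na(rival_x) || is.na(rival_y) || is.na(t_depart)) return("undetermined")
  tm <- time_minutes(track$time)
  t_depart <- time_minutes(t_depart)
  t_end <- min(t_depart + horizon, max(tm))
  if (t_end - t_depart < min_post) return("undetermined")
  i0 <- which.min(abs(tm - t_depart))
  i1 <- which.min(abs(tm - t_end))
  d0 <- sqrt((track$x[i0] - rival_x)^2 + (track$y[i0] - rival_y)^2)
  d1 <- sqrt((track$x[i1] - rival_x)^2 + (track$y[i1] - rival_y)^2)
  if (d0 - d1 > deadband) "advance"
  else if (d1 - d0 > deadband) "retreat"
  else "undetermined"
}

#' Assemble the stop-model table
#'
#' One row per unambiguous-direction hill visit, with the binary `stopped`
#' response, test predictors (movement direction, hills before/after that
#' day, own adult party size, intercommunity distance over use) and
#' controls. Continuous predictors are z-transformed (`*_z` columns) using
#' the table's own mean/sd after row exclusions; the quadratic
#' center-distance control is the square of the z-transformed distance.
#'
#' @param visits hill-visit table carrying covariate columns:
#'   `stopped, direction, n_hills_before, n_hills_after, adult_party_size,
#'   intercomm_dist, rel_center_dist, kernel, elev, time_of_day, sex,
#'   group, location_id, follow_id, focal_id`.
#' @return modeling tibble; rows with missing covariates are dropped with
#'   a message.
#' @export
build_stop_dataset <- function(visits) {
  visits <- tibble::as_tibble(visits)
  need <- c("stopped", "direction", "n_hills_before", "n_hills_after",
            "adult_party_size", "intercomm_dist", "rel_center_dist",
            "kernel", "elev", "time_of_day", "sex", "group",
            "location_id", "follow_id", "focal_id")
  stop_if_missing_cols(visits, need, "visit table")
  keep <- intersect("t_arrive", names(visits))
  d <- visits[visits$direction %in% c("toward_border", "toward_center"),
              c(need, keep)]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message("build_stop_dataset: dropped ", sum(!cc),
                        " row(s) with missing covariates")
  d <- d[cc, ]
  if (!nrow(d)) return(dplyr::mutate(d, stopped = integer(0)))
  d$stopped <- as.integer(d$stopped)
  d$direction <- factor(d$direction, levels = c("toward_center", "toward_border"))
  d$hill_id <- factor(d$location_id)
  d$date_group <- factor(paste(d$follow_id, d$group, sep = ":"))
  d$focal_id <- factor(d$focal_id)
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d <- z_transform(d, c("n_hills_before", "n_hills_after", "adult_party_size",
                        "intercomm_dist", "rel_center_dist", "kernel", "elev",
                        "time_of_day"), suffix = "_z", on_constant = "zero")
  d$rel_center_dist_z2 <- d$rel_center_dist_z^2
  d
}

#' Assemble the advance-model table
#'
#' One row per determined advance/retreat decision after a stop at a
#' peripheral hill or low location. Test predictors: movement direction
#' (numeric, border = 1), hills before/after, elevation, imbalance of
#' power (own minus rival adults), and the natural log of the
#' intercommunity distance at departure (log taken before z-transform);
#' the three-way interaction elevation x imbalance x ln-distance is formed
#' at modeling time from the z-scores.
#'
#' @param stops stop-event table with `advance` (`"advance"`/`"retreat"`),
#'   `direction`, `n_hills_before`, `n_hills_after`, `elev`, `imbalance`,
#'   `dist_at_depart`, controls as in [build_stop_dataset()].
#' @return modeling tibble with z-transformed columns.
#' @export
build_advance_dataset <- function(stops) {
  stops <- tibble::as_tibble(stops)
  need <- c("advance", "direction", "n_hills_before", "n_hills_after",
            "elev", "imbalance", "dist_at_depart", "rel_center_dist",
            "kernel", "time_of_day", "sex", "group", "location_id",
            "follow_id", "focal_id")
  stop_if_missing_cols(stops, need, "stop-event table")
  keep <- intersect("t_arrive", names(stops))
  d <- stops[stops$advance %in% c("advance", "retreat") &
               stops$direction %in% c("toward_border", "toward_center"),
             c(need, keep)]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message("build_advance_dataset: dropped ", sum(!cc),
                        " row(s) with missing covariates")
  d <- d[cc, ]
  if (!nrow(d)) return(dplyr::mutate(d, advance = integer(0)))
  d$advance <- as.integer(d$advance == "advance")
  d$direction_num <- as.numeric(d$direction == "toward_border")
  d$ln_dist <- log(pmax(d$dist_at_depart, 1))
  d$location_id <- factor(d$location_id)
  d$date_group <- factor(paste(d$follow_id, d$group, sep = ":"))
  d$focal_id <- factor(d$focal_id)
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d <- z_transform(d, c("direction_num", "n_hills_before", "n_hills_after",
                        "elev", "imbalance", "ln_dist", "rel_center_dist",
                        "kernel", "time_of_day"), suffix = "_z",
                   on_constant = "zero")
  d$rel_center_dist_z2 <- d$rel_center_dist_z^2
  d
}
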