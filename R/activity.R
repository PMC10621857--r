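# Minute-point activity analysis: 30-min thinning to break serial
# dependence, activity budgets by territory section, bout-length
# summaries, and assembly of the three binomial modeling tables
# (rest / feed / travel).

#' Thin minute points to a minimum spacing
#'
#' Greedy within-day selection: each day's first point is kept, then the
#' next point at least `spacing` minutes later, and so on. 30 min is twice
#' the average activity bout length, so kept points are near-independent.
#'
#' @param minutes tibble with `time` and a day key (`follow_id`, falling
#'   back to a single day); additional grouping by `group` and `focal_id`
#'   when present.
#' @param spacing minutes (default 30).
#' @return the thinned subset, original row order within day preserved.
#' @export
thin_minutes <- function(minutes, spacing = 30) {
  minutes <- tibble::as_tibble(minutes)
  keys <- intersect(c("group", "focal_id", "follow_id"), names(minutes))
  if (!length(keys)) minutes$.day <- "d" else minutes$.day <-
    do.call(paste, c(minutes[keys], sep = ":"))
  tm <- time_minutes(minutes$time)
  keep <- logical(nrow(minutes))
  for (idx in split(seq_len(nrow(minutes)), minutes$.day)) {
    idx <- idx[order(tm[idx])]
    last <- -Inf
    for (i in idx) {
      if (tm[i] - last >= spacing) {
        keep[i] <- TRUE
        last <- tm[i]
      }
    }
  }
  minutes$.day <- NULL
  minutes[keep, ]
}

#' Activity budgets by territory section
#'
#' Percent of observation time in each activity within four territory
#' sections defined on kernel values: core (< 25), post-core (25-50),
#' pre-periphery (50-75), periphery (>= 75). Percentages are computed
#' within each section; an "other" remainder is implicit.
#'
#' @param minutes tibble with `kernel` and `activity` (character:
#'   `"rest"`, `"feed"`, `"travel"`, anything else counts as other), plus
#'   optionally `group`.
#' @param by_group also split by group (default `FALSE`).
#' @return tibble `section, activity, n, percent` (and `group`).
#' @export
activity_budgets <- function(minutes, by_group = FALSE) {
  minutes <- tibble::as_tibble(minutes)
  stop_if_missing_cols(minutes, c("kernel", "activity"), "minute table")
  minutes$section <- cut(minutes$kernel, breaks = c(0, 25, 50, 75, 100),
                         labels = c("core", "post-core", "pre-periphery",
                                    "periphery"), right = FALSE)
  grp <- if (by_group) c("group", "section") else "section"
  minutes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.n_section = dplyr::n()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "activity")))) |>
    dplyr::summarise(n = dplyr::n(),
                     percent = 100 * dplyr::n() / .data$.n_section[1],
                     .groups = "drop")
}

#' Mean activity-bout lengths
#'
#' Mean length (minutes) of maximal runs of the same activity within each
#' follow, per activity and group. Run on the un-thinned minute stream.
#'
#' @param minutes tibble with `time, group, follow_id, activity`.
#' @return tibble `group, activity, mean_bout, n_bouts`.
#' @export
bout_lengths <- function(minutes) {
  minutes <- tibble::as_tibble(minutes)
  stop_if_missing_cols(minutes, c("time", "group", "follow_id", "activity"),
                       "minute table")
  tm <- time_minutes(minutes$time)
  minutes <- minutes[order(minutes$group, minutes$follow_id, tm), ]
  res <- minutes |>
    dplyr::group_by(.data$group, .data$follow_id) |>
    dplyr::group_map(function(g, key) {
      r <- rle(g$activity)
      tibble::tibble(group = key$group, activity = r$values,
                     len = r$lengths)
    }) |>
    dplyr::bind_rows()
  res |>
    dplyr::group_by(.data$group, .data$activity) |>
    dplyr::summarise(mean_bout = mean(.data$len), n_bouts = dplyr::n(),
                     .groups = "drop")
}

#' Assemble the activity modeling tables
#'
#' From thinned minute points, builds one table per activity with a 0/1
#' response (`rest`, `feed`, `travel`; an "other" minute is 0 in all
#' three), test predictors kernel value (location) and elevation, and the
#' controls: sex class, group, day-of-year sine/cosine, party size,
#' monthly food availability, number of oestrus females. Continuous
#' covariates are z-transformed in place (`*_z`).
#'
#' @param minutes thinned tibble with `activity, kernel, elev (or
#'   smoothed_elev), sex_class, group, follow_id, focal_id, party_size,
#'   food_avail, n_oestrus` and either `day_sin`/`day_cos` or a `date`.
#' @return named list of three tibbles (`rest`, `feed`, `travel`).
#' @export
build_activity_dataset <- function(minutes) {
  minutes <- tibble::as_tibble(minutes)
  if (!"elev" %in% names(minutes) && "smoothed_elev" %in% names(minutes)) {
    minutes$elev <- minutes$smoothed_elev
  }
  if (!all(c("day_sin", "day_cos") %in% names(minutes))) {
    stop_if_missing_cols(minutes, "date", "minute table (for day_sin/day_cos)")
    ang <- day_angle(minutes$date)
    minutes$day_sin <- sin(ang)
    minutes$day_cos <- cos(ang)
  }
  need <- c("activity", "kernel", "elev", "sex_class", "group", "follow_id",
            "focal_id", "party_size", "food_avail", "n_oestrus",
            "day_sin", "day_cos")
  stop_if_missing_cols(minutes, need, "minute table")
  d <- minutes[, need]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message("build_activity_dataset: dropped ", sum(!cc),
                        " row(s) with missing covariates")
  d <- d[cc, ]
  d$sex_class <- factor(d$sex_class)
  d$group <- factor(d$group)
  d$date_group <- factor(paste(d$follow_id, d$group, sep = ":"))
  d$focal_id <- factor(d$focal_id)
  d <- z_transform(d, c("kernel", "elev", "party_size", "food_avail",
                        "n_oestrus"), suffix = "_z", on_constant = "zero")
  lapply(stats::setNames(c("rest", "feed", "travel"),
                         c("rest", "feed", "travel")), function(a) {
    d$response <- as.integer(d$activity == a)
    d
  })
}
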