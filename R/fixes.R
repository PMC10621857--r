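#' Read GPS fixes from CSV
#'
#' Expects minute-resolution focal-follow tracklogs with columns
#' `time, x, y, elev, group, follow_id`. Coordinates must be projected
#' meters (e.g. UTM); lon/lat data should be projected before ingest.
#'
#' @param path path to a CSV file.
#' @return tibble of fixes.
#' @seealso [read_fixes_gpx()], [validate_fixes()]
#' @export
read_fixes_csv <- function(path) {
  fx <- readr::read_csv(path, show_col_types = FALSE)
  stop_if_missing_cols(fx, c("time", "x", "y", "elev"), "fix table")
  if (!"group" %in% names(fx)) fx$group <- "A"
  if (!"follow_id" %in% names(fx)) fx$follow_id <- "f1"
  tibble::as_tibble(fx)
}

#' Read GPS fixes from a GPX 1.1 track file
#'
#' Parses `<trkpt>` elements (lat/lon/ele/time). Coordinates are returned
#' as `lon`/`lat`; project them to meters before landscape/territory work.
#'
#' @param path path to a GPX file.
#' @param group,follow_id labels attached to every point.
#' @return tibble with `time, lon, lat, elev, group, follow_id`.
#' @export
read_fixes_gpx <- function(path, group = "A", follow_id = basename(path)) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (!length(pts)) stop("no <trkpt> elements in ", path)
  tibble::tibble(
    time = as.POSIXct(xml2::xml_text(xml2::xml_find_first(pts, "./time")),
                      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    elev = as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele"))),
    group = group, follow_id = follow_id
  )
}

#' Validate a fix table
#'
#' Checks the tracklog invariants: finite coordinates and elevations,
#' strictly increasing times within each follow, and a plausibility cap on
#' the displacement between consecutive fixes of a follow.
#'
#' @param fixes tibble with `time, x, y, elev, group, follow_id`.
#' @param max_speed maximum plausible displacement in m per minute
#'   (default 1000); a faster jump raises an error naming the fix.
#' @return the validated fixes, invisibly unchanged (as a tibble).
#' @export
validate_fixes <- function(fixes, max_speed = 1000) {
  fixes <- tibble::as_tibble(fixes)
  stop_if_missing_cols(fixes, c("time", "x", "y", "elev", "group", "follow_id"),
                       "fix table")
  bad <- which(!is.finite(fixes$x) | !is.finite(fixes$y) | !is.finite(fixes$elev))
  if (length(bad)) stop("non-finite coordinate/elevation at fix index ", bad[1])
  tm <- time_minutes(fixes$time)
  for (f in split(seq_len(nrow(fixes)), fixes$follow_id)) {
    f <- f[order(tm[f])]
    dt <- diff(tm[f])
    if (any(dt <= 0)) stop("non-increasing times within follow '",
                           fixes$follow_id[f[1]], "'")
    dd <- sqrt(diff(fixes$x[f])^2 + diff(fixes$y[f])^2)
    v <- dd / dt
    if (any(v > max_speed)) {
      stop("implausible displacement (", round(max(v)), " m/min) at fix index ",
           f[which.max(v) + 1])
    }
  }
  fixes
}
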