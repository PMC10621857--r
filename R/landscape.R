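# Landscape reconstruction: a median-elevation raster built by binning the
# accumulated GPS fixes onto a 10 m lattice anchored at the arithmetic
# center of all fixes, from which peripheral hills (clustered supra-threshold
# cells) and low-elevation rest locations are derived.

#' Grid specification for elevation binning
#'
#' The lattice has cell centers at `ref + k * bin_size` for integer `k`;
#' the reference defaults to the arithmetic center (mean x, mean y) of the
#' fixes the grid is built from.
#'
#' @param bin_size cell size in meters (default 10, the GPS accuracy scale).
#' @param ref_x,ref_y lattice anchor in meters; `NA` means "use the
#'   arithmetic center of the fixes".
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(bin_size = 10, ref_x = NA_real_, ref_y = NA_real_) {
  stopifnot(is.numeric(bin_size), bin_size > 0)
  structure(list(bin_size = bin_size, ref_x = ref_x, ref_y = ref_y),
            class = "grid_spec")
}

# nearest-center bin index; ties at half a cell break toward the lower index
bin_index <- function(v, ref, bin_size) {
  as.integer(ceiling((v - ref) / bin_size - 0.5))
}

#' Build a median-elevation grid from GPS fixes
#'
#' Each fix is assigned to the lattice cell whose center is nearest
#' (ties toward the lower index); each occupied cell records the median of
#' the member elevations and the member count. Multiple passes over the
#' same ground on different days thus smooth single-fix GPS elevation error.
#'
#' @param fixes tibble with at least `x, y, elev` (meters).
#' @param spec a [grid_spec()]; reference defaults to the arithmetic center.
#' @return an `elevation_grid` object; its `cells` tibble has
#'   `ix, iy, x_center, y_center, median_elev, n`.
#' @export
#' @examples
#' g <- build_grid(data.frame(x = c(0, 2), y = c(0, 1), elev = c(100, 120)))
#' g$cells
build_grid <- function(fixes, spec = grid_spec()) {
  fixes <- tibble::as_tibble(fixes)
  stop_if_missing_cols(fixes, c("x", "y", "elev"), "fix table")
  if (!nrow(fixes)) stop("build_grid: empty fix table")
  bad <- which(!is.finite(fixes$x) | !is.finite(fixes$y) | !is.finite(fixes$elev))
  if (length(bad)) stop("build_grid: non-finite values at fix index ", bad[1])
  if (is.na(spec$ref_x)) spec$ref_x <- mean(fixes$x)
  if (is.na(spec$ref_y)) spec$ref_y <- mean(fixes$y)
  ix <- bin_index(fixes$x, spec$ref_x, spec$bin_size)
  iy <- bin_index(fixes$y, spec$ref_y, spec$bin_size)
  cells <- tibble::tibble(ix = ix, iy = iy, elev = fixes$elev) |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(median_elev = stats::median(.data$elev),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(x_center = spec$ref_x + .data$ix * spec$bin_size,
                  y_center = spec$ref_y + .data$iy * spec$bin_size) |>
    dplyr::select("ix", "iy", "x_center", "y_center", "median_elev", "n")
  structure(list(spec = spec, cells = cells), class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat("<elevation_grid> ", nrow(x$cells), " cells of ", x$spec$bin_size,
      " m; elevation ", round(min(x$cells$median_elev), 1), "-",
      round(max(x$cells$median_elev), 1), " m\n", sep = "")
  invisible(x)
}

#' @method tidy elevation_grid
#' @export
tidy.elevation_grid <- function(x, ...) x$cells

#' Annotate fixes with the grid's smoothed (median) elevation
#'
#' Looks up each fix's cell in the grid and attaches the cell's median
#' elevation as `smoothed_elev`; the raw `elev` is kept.
#'
#' @param fixes tibble with `x, y`.
#' @param grid an [build_grid()] result.
#' @param missing what to do for a fix whose cell is absent from the grid:
#'   `"error"` (default) or `"nearest"` (use the nearest occupied cell).
#' @return `fixes` with an added `smoothed_elev` column.
#' @export
annotate_elevation <- function(fixes, grid, missing = c("error", "nearest")) {
  missing <- match.arg(missing)
  fixes <- tibble::as_tibble(fixes)
  sp <- grid$spec
  ix <- bin_index(fixes$x, sp$ref_x, sp$bin_size)
  iy <- bin_index(fixes$y, sp$ref_y, sp$bin_size)
  key <- paste(ix, iy)
  gkey <- paste(grid$cells$ix, grid$cells$iy)
  m <- match(key, gkey)
  if (anyNA(m)) {
    if (missing == "error") {
      stop("annotate_elevation: ", sum(is.na(m)),
           " fix(es) fall outside the grid (first at row ", which(is.na(m))[1], ")")
    }
    for (i in which(is.na(m))) {
      d2 <- (grid$cells$x_center - fixes$x[i])^2 +
        (grid$cells$y_center - fixes$y[i])^2
      m[i] <- which.min(d2)
    }
  }
  fixes$smoothed_elev <- grid$cells$median_elev[m]
  fixes
}

#' Percentile of the reconstructed elevation distribution
#'
#' Quantile of the per-cell median elevations (type-7 linear interpolation,
#' R's default). The conventional hill threshold is the 99th percentile.
#'
#' @param grid an `elevation_grid`.
#' @param q percentile in `[0, 100]`.
#' @return elevation in meters.
#' @export
elevation_percentile <- function(grid, q) {
  stopifnot(q >= 0, q <= 100, nrow(grid$cells) > 0)
  unname(stats::quantile(grid$cells$median_elev, q / 100, type = 7))
}

# union-find with path compression; link cells whose centers are <= link_dist
single_linkage_components <- function(x, y, link_dist) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
      for (j in i + which(d2 <= link_dist^2)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Detect peripheral hills on an elevation grid
#'
#' Cells at or above the elevation threshold are partitioned into
#' single-linkage connected components: two supra-threshold cells belong to
#' the same hill whenever a chain of cells each within `link_dist`
#' (center-to-center) connects them, capturing ridge-linked summits. The
#' summit is the highest member cell (ties broken smallest y, then
#' smallest x). Restriction to the overlap band is the caller's job, via
#' `mask`.
#'
#' @param grid an `elevation_grid`.
#' @param elev_threshold meters; default 230 (the 99th-percentile preset).
#' @param link_dist meters; default 50.
#' @param mask optional function `f(x, y) -> logical` (e.g. an
#'   [overlap_band()] predicate) applied to cell centers before clustering.
#' @return tibble with one row per hill: `hill_id, summit_x, summit_y,
#'   summit_elev, n_cells` and a list-column `cells` of member cells.
#' @export
detect_hills <- function(grid, elev_threshold = 230, link_dist = 50,
                         mask = NULL) {
  cc <- grid$cells[grid$cells$median_elev >= elev_threshold, ]
  if (!is.null(mask) && nrow(cc)) {
    cc <- cc[mask(cc$x_center, cc$y_center), ]
  }
  if (!nrow(cc)) {
    return(tibble::tibble(hill_id = integer(), summit_x = numeric(),
                          summit_y = numeric(), summit_elev = numeric(),
                          n_cells = integer(), cells = list()))
  }
  comp <- single_linkage_components(cc$x_center, cc$y_center, link_dist)
  cc$comp <- comp
  cc |>
    dplyr::group_by(.data$comp) |>
    dplyr::group_map(function(g, key) {
      top <- g[g$median_elev == max(g$median_elev), ]
      top <- top[order(top$y_center, top$x_center), ][1, ]
      tibble::tibble(summit_x = top$x_center, summit_y = top$y_center,
                     summit_elev = top$median_elev, n_cells = nrow(g),
                     cells = list(g[, c("ix", "iy", "x_center", "y_center",
                                        "median_elev", "n")]))
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$summit_elev)) |>
    dplyr::mutate(hill_id = dplyr::row_number(), .before = 1)
}

#' Detect low-elevation rest locations
#'
#' From rest-stop events inside the overlap band, keeps stops whose
#' smoothed elevation is at most `max_elev` (mean landscape elevation minus
#' one SD by convention) and merges stops within `merge_dist` of one
#' another (single linkage) into a single location at their centroid.
#'
#' @param rest_stops tibble of stop events with `x, y` and a smoothed
#'   elevation column (`smoothed_elev`, falling back to `elev`).
#' @param max_elev meters, default 180.
#' @param merge_dist meters, default 50.
#' @return tibble `loc_id, x, y, elev, n_stops`.
#' @export
detect_low_locations <- function(rest_stops, max_elev = 180, merge_dist = 50) {
  rest_stops <- tibble::as_tibble(rest_stops)
  ecol <- if ("smoothed_elev" %in% names(rest_stops)) "smoothed_elev" else "elev"
  keep <- rest_stops[rest_stops[[ecol]] <= max_elev, ]
  if (!nrow(keep)) {
    return(tibble::tibble(loc_id = integer(), x = numeric(), y = numeric(),
                          elev = numeric(), n_stops = integer()))
  }
  comp <- single_linkage_components(keep$x, keep$y, merge_dist)
  keep$comp <- comp
  keep |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                     elev = mean(.data[[ecol]]), n_stops = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(loc_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"comp")
}

#' Write an elevation grid to CSV
#'
#' @param grid an `elevation_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  readr::write_csv(grid$cells, path)
  invisible(path)
}

#' Export point locations (hills or low locations) as GeoJSON
#'
#' @param points tibble with `x, y` plus any property columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(points, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for GeoJSON export")
  }
  props <- points[, setdiff(names(points), c("x", "y", "cells")), drop = FALSE]
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
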