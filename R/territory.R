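# Kernel utilization-distribution territory model. The UD is an isotropic
# Gaussian product-kernel density evaluated on a regular lattice; each
# location gets a "kernel value" in 1..99 — the smallest percent-volume
# contour containing it (1 = most central/used, 99 = most peripheral).

#' Fit a kernel utilization distribution
#'
#' Isotropic Gaussian KDE with smoothing factor `h` (the kernel standard
#' deviation in meters), evaluated on a lattice covering the fixes plus a
#' `3 h` margin and normalized to unit volume.
#'
#' @param fixes tibble with `x, y` (projected meters).
#' @param h smoothing factor in meters (default 149).
#' @param cell lattice resolution in meters (default 25).
#' @return a `ud_surface`: lattice vectors `x`, `y`, density matrix `z`
#'   (rows index `x`), `h`, `cell`.
#' @export
fit_ud <- function(fixes, h = 149, cell = 25) {
  fixes <- tibble::as_tibble(fixes)
  stop_if_missing_cols(fixes, c("x", "y"), "fix table")
  if (nrow(fixes) < 2) stop("fit_ud: need at least 2 fixes")
  if (stats::sd(fixes$x) == 0 && stats::sd(fixes$y) == 0) {
    stop("fit_ud: degenerate (all-identical) fixes")
  }
  stopifnot(h > 0, cell > 0)
  gx <- seq(min(fixes$x) - 3 * h, max(fixes$x) + 3 * h, by = cell)
  gy <- seq(min(fixes$y) - 3 * h, max(fixes$y) + 3 * h, by = cell)
  # separable product kernel: z = Kx %*% t(Ky) / n, via BLAS
  kx <- stats::dnorm(outer(gx, fixes$x, "-") / h) / h
  ky <- stats::dnorm(outer(gy, fixes$y, "-") / h) / h
  z <- (kx %*% t(ky)) / nrow(fixes)
  z <- z / (sum(z) * cell^2)   # renormalize discrete volume to exactly 1
  structure(list(x = gx, y = gy, z = z, h = h, cell = cell),
            class = "ud_surface")
}

#' @export
print.ud_surface <- function(x, ...) {
  cat("<ud_surface> ", length(x$x), "x", length(x$y), " lattice at ",
      x$cell, " m, h = ", x$h, " m\n", sep = "")
  invisible(x)
}

ud_density_at <- function(ud, x, y) {
  ix <- pmin(pmax(round((x - ud$x[1]) / ud$cell) + 1, 1), length(ud$x))
  iy <- pmin(pmax(round((y - ud$y[1]) / ud$cell) + 1, 1), length(ud$y))
  ud$z[cbind(ix, iy)]
}

# cumulative volume of the region with density >= d, for each query d
ud_volume_above <- function(ud, d) {
  dens <- sort(as.vector(ud$z), decreasing = TRUE)
  cv <- cumsum(dens) * ud$cell^2
  # number of lattice cells with density >= d
  k <- length(dens) - findInterval(d, rev(dens), left.open = TRUE)
  ifelse(k == 0, 0, cv[pmax(k, 1)] * (k > 0))
}

#' Kernel values (percent-volume contour membership) of locations
#'
#' The kernel value of a location is the smallest k in 1..99 such that the
#' location lies inside the k% volume contour of the UD, computed as
#' `ceiling(100 * volume{density >= density(xy)})` clamped to `[1, 99]`.
#' Small values are central, heavily used ground; values at or above 75
#' are conventionally "periphery".
#'
#' @param ud a [fit_ud()] surface.
#' @param x,y coordinate vectors (meters).
#' @param strict error on points outside the lattice (default `FALSE`:
#'   such points get kernel value 99 with a warning).
#' @return integer vector in 1..99.
#' @export
kernel_value <- function(ud, x, y, strict = FALSE) {
  outside <- x < min(ud$x) | x > max(ud$x) | y < min(ud$y) | y > max(ud$y)
  if (any(outside)) {
    if (strict) stop("kernel_value: ", sum(outside), " point(s) outside lattice")
    warning(sum(outside), " point(s) outside the UD lattice; assigned 99")
  }
  d <- ud_density_at(ud, x, y)
  vol <- ud_volume_above(ud, d)
  kv <- as.integer(pmin(pmax(ceiling(100 * vol), 1L), 99L))
  kv[outside] <- 99L
  kv
}

# iso-density level enclosing p% of UD volume
ud_level <- function(ud, p) {
  dens <- sort(as.vector(ud$z), decreasing = TRUE)
  cv <- cumsum(dens) * ud$cell^2
  dens[which(cv >= p / 100)[1]]
}

#' Percent-volume contour of a UD
#'
#' Returns the iso-density polygon(s) enclosing `p` percent of the UD
#' volume, with the region's raster area (count of lattice cells at or
#' above the iso level times cell area).
#'
#' @param ud a `ud_surface`.
#' @param p percent in (0, 100); 95 is the conventional territory outline.
#' @return a `ud_contour`: list with `p`, `level`, `area` (m^2) and
#'   `polygons` (tibble `piece, x, y`).
#' @export
ud_contour <- function(ud, p = 95) {
  stopifnot(p > 0, p < 100)
  lev <- ud_level(ud, p)
  area <- sum(ud$z >= lev) * ud$cell^2
  cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = lev)
  polys <- purrr::imap(cl, function(cc, i) {
    tibble::tibble(piece = i, x = cc$x, y = cc$y)
  }) |> dplyr::bind_rows()
  structure(list(p = p, level = lev, area = area, polygons = polys),
            class = "ud_contour")
}

#' @export
print.ud_contour <- function(x, ...) {
  cat("<ud_contour> ", x$p, "% volume; area ",
      format(round(x$area / 1e6, 3)), " km^2 in ",
      length(unique(x$polygons$piece)), " piece(s)\n", sep = "")
  invisible(x)
}

#' Territory model: UD, center, and yearly 95% areas
#'
#' Bundles the UD surface with the territory center (the UD mode by
#' default, or the mean of fixes) and the yearly territory sizes (area of
#' each year's 95% volume contour, fitted on that year's fixes).
#'
#' @param fixes tibble with `x, y` and optionally `time` (for yearly areas).
#' @param h,cell passed to [fit_ud()].
#' @param center `"mode"` (default) or `"mean"`.
#' @return a `territory_model`: `ud`, `center_xy`, `area95`,
#'   `yearly_size` (named numeric, m^2 per year).
#' @export
territory_model <- function(fixes, h = 149, cell = 25,
                            center = c("mode", "mean")) {
  center <- match.arg(center)
  fixes <- tibble::as_tibble(fixes)
  ud <- fit_ud(fixes, h = h, cell = cell)
  ctr <- if (center == "mode") {
    i <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
    c(ud$x[i[1]], ud$y[i[2]])
  } else {
    c(mean(fixes$x), mean(fixes$y))
  }
  area95 <- ud_contour(ud, 95)$area
  yearly <- numeric(0)
  if ("time" %in% names(fixes)) {
    yr <- if (inherits(fixes$time, "POSIXt")) {
      format(fixes$time, "%Y")
    } else {
      # numeric minutes: treat 525960 min (365.25 d) blocks as years
      as.character(floor(time_minutes(fixes$time) / 525960))
    }
    yearly <- vapply(split(fixes, yr), function(fy) {
      if (nrow(fy) < 50) return(NA_real_)
      ud_contour(fit_ud(fy, h = h, cell = cell), 95)$area
    }, numeric(1))
    yearly <- yearly[!is.na(yearly)]
  }
  structure(list(ud = ud, center_xy = ctr, area95 = area95,
                 yearly_size = yearly),
            class = "territory_model")
}

#' @export
print.territory_model <- function(x, ...) {
  cat("<territory_model> center (", round(x$center_xy[1]), ", ",
      round(x$center_xy[2]), "); 95% area ",
      format(round(x$area95 / 1e6, 2)), " km^2; ",
      length(x$yearly_size), " yearly size(s)\n", sep = "")
  invisible(x)
}

#' Relative distance to the territory center
#'
#' Distance from a location to the territory center divided by the
#' equivalent-circle radius of the relevant yearly territory size
#' (`sqrt(area / pi)`), so the covariate is dimensionless and monotone in
#' distance. The quadratic control term is the square of the z-transformed
#' value and is added at modeling time.
#'
#' @param x,y location (meters).
#' @param territory a [territory_model()].
#' @param year optional year key into `yearly_size`; default uses the
#'   whole-period 95% area.
#' @return numeric vector.
#' @export
relative_center_distance <- function(x, y, territory, year = NULL) {
  area <- if (is.null(year)) {
    territory$area95
  } else {
    if (!year %in% names(territory$yearly_size)) {
      stop("no yearly territory size for year '", year, "'")
    }
    territory$yearly_size[[year]]
  }
  d <- sqrt((x - territory$center_xy[1])^2 + (y - territory$center_xy[2])^2)
  d / sqrt(area / pi)
}

#' East-West overlap band between two groups' ranges
#'
#' The band between the extreme western location visited by the eastern
#' group and the extreme eastern location visited by the western group;
#' its y-range is the range of visited y within the band.
#'
#' @param fixes_west,fixes_east fix tibbles of the western and eastern
#'   group respectively.
#' @return an `overlap_band`: `x_min, x_max, y_min, y_max, width`, or a
#'   band with `width = 0` and `empty = TRUE` when the ranges do not
#'   overlap.
#' @export
overlap_band <- function(fixes_west, fixes_east) {
  x_min <- min(fixes_east$x)
  x_max <- max(fixes_west$x)
  if (x_min >= x_max) {
    return(structure(list(x_min = x_min, x_max = x_max, y_min = NA_real_,
                          y_max = NA_real_, width = 0, empty = TRUE),
                     class = "overlap_band"))
  }
  yy <- c(fixes_west$y[fixes_west$x >= x_min & fixes_west$x <= x_max],
          fixes_east$y[fixes_east$x >= x_min & fixes_east$x <= x_max])
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = min(yy), y_max = max(yy),
                 width = x_max - x_min, empty = FALSE),
            class = "overlap_band")
}

#' @export
print.overlap_band <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<overlap_band> no overlap\n")
  } else {
    cat("<overlap_band> x ", round(x$x_min), "-", round(x$x_max), " (width ",
        round(x$width), " m), y ", round(x$y_min), "-", round(x$y_max), "\n",
        sep = "")
  }
  invisible(x)
}

#' Predicate for membership in an overlap band
#'
#' @param band an [overlap_band()].
#' @return function `f(x, y) -> logical`, usable as a `mask`.
#' @export
band_mask <- function(band) {
  if (isTRUE(band$empty)) return(function(x, y) rep(FALSE, length(x)))
  function(x, y) x >= band$x_min & x <= band$x_max &
    y >= band$y_min & y <= band$y_max
}

#' Periphery vs. core elevation comparison
#'
#' Computes the mean smoothed elevation per kernel value (1..99) and
#' compares core (kernel value < `split`) against periphery (>= `split`)
#' with a two-sided Mann-Whitney U (Wilcoxon rank-sum) test.
#'
#' @param data tibble with `kernel` (1..99) and an elevation column
#'   (`smoothed_elev` or `elev`).
#' @param split periphery threshold on the kernel value (default 75).
#' @return tibble with `W`, `p_value`, `n_core`, `n_periphery`,
#'   `mean_core`, `mean_periphery`.
#' @export
periphery_core_test <- function(data, split = 75) {
  ecol <- if ("smoothed_elev" %in% names(data)) "smoothed_elev" else "elev"
  per_kv <- tibble::as_tibble(data) |>
    dplyr::group_by(.data$kernel) |>
    dplyr::summarise(mean_elev = mean(.data[[ecol]]), .groups = "drop")
  core <- per_kv$mean_elev[per_kv$kernel < split]
  peri <- per_kv$mean_elev[per_kv$kernel >= split]
  if (length(core) < 2 || length(peri) < 2) {
    stop("periphery_core_test: need at least 2 kernel values per side")
  }
  wt <- suppressWarnings(stats::wilcox.test(core, peri))
  tibble::tibble(W = unname(wt$statistic), p_value = wt$p.value,
                 n_core = length(core), n_periphery = length(peri),
                 mean_core = mean(core), mean_periphery = mean(peri))
}
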