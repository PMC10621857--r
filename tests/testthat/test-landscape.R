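# Elevation-grid reconstruction and hill/low-location detection.

test_that("grid binning matches the nearest-center oracle and the median rule", {
  g1 <- build_grid(make_fixes(0, 0, elev = 200))
  expect_equal(nrow(g1$cells), 1)
  expect_equal(g1$cells$median_elev, 200)
  expect_equal(g1$cells$n, 1)

  # two fixes 2 m apart share a 10 m cell; median of two = midpoint
  g2 <- build_grid(make_fixes(c(0, 2), c(0, 0), elev = c(100, 120)))
  expect_equal(nrow(g2$cells), 1)
  expect_equal(g2$cells$median_elev, 110)

  # 500 random fixes: assignment identical to exhaustive nearest-center search
  set.seed(11)
  fx <- make_fixes(runif(500, 0, 200), runif(500, 0, 200),
                   elev = runif(500, 100, 300))
  g <- build_grid(fx)
  sp <- g$spec
  ks <- -40:40
  for (i in sample(500, 120)) {
    dx <- abs(fx$x[i] - (sp$ref_x + ks * sp$bin_size))
    dy <- abs(fx$y[i] - (sp$ref_y + ks * sp$bin_size))
    best_ix <- ks[which.min(dx)]   # which.min: ties toward the lower index
    best_iy <- ks[which.min(dy)]
    cell <- g$cells[g$cells$ix == best_ix & g$cells$iy == best_iy, ]
    expect_equal(nrow(cell), 1)
    members <- which(abs(fx$x - (sp$ref_x + best_ix * sp$bin_size)) <= 5 &
                       abs(fx$y - (sp$ref_y + best_iy * sp$bin_size)) <= 5)
    expect_true(cell$median_elev >= min(fx$elev[members]) &&
                  cell$median_elev <= max(fx$elev[members]))
  }
  # counts add up to the number of fixes
  expect_equal(sum(g$cells$n), 500)
})

test_that("grid rebuild from cell centers is idempotent", {
  set.seed(3)
  fx <- make_fixes(runif(200, -100, 100), runif(200, -100, 100),
                   elev = runif(200, 150, 250))
  g <- build_grid(fx)
  g2 <- build_grid(tibble::tibble(x = g$cells$x_center, y = g$cells$y_center,
                                  elev = g$cells$median_elev),
                   spec = grid_spec(ref_x = g$spec$ref_x,
                                    ref_y = g$spec$ref_y))
  expect_equal(dplyr::arrange(g2$cells, ix, iy)[, c("ix", "iy", "median_elev")],
               dplyr::arrange(g$cells, ix, iy)[, c("ix", "iy", "median_elev")])
})

test_that("grid errors on empty and non-finite input", {
  expect_error(build_grid(make_fixes(numeric(0), numeric(0))), "empty")
  expect_error(build_grid(make_fixes(c(1, NA), c(0, 0))), "index 2")
})

test_that("elevation annotation equals per-fix lookup", {
  fx <- make_fixes(c(0, 1, 2, 50), c(0, 0, 0, 0),
                   elev = c(100, 120, 140, 300))
  g <- build_grid(fx)
  an <- annotate_elevation(fx, g)
  expect_equal(an$smoothed_elev[1:3], rep(120, 3))  # odd-count median
  expect_equal(an$smoothed_elev[4], 300)            # single-fix cell
  expect_equal(an$elev, fx$elev)                    # raw retained

  set.seed(5)
  fr <- make_fixes(runif(300, 0, 300), runif(300, 0, 300),
                   elev = runif(300, 100, 200))
  gr <- build_grid(fr)
  ar <- annotate_elevation(fr, gr)
  sp <- gr$spec
  for (i in sample(300, 60)) {
    ix <- ceiling((fr$x[i] - sp$ref_x) / sp$bin_size - 0.5)
    iy <- ceiling((fr$y[i] - sp$ref_y) / sp$bin_size - 0.5)
    expect_equal(ar$smoothed_elev[i],
                 gr$cells$median_elev[gr$cells$ix == ix & gr$cells$iy == iy])
  }
  # outside fix errors unless nearest-cell fallback requested
  out <- make_fixes(1e6, 1e6)
  expect_error(annotate_elevation(out, g), "outside")
  expect_silent(annotate_elevation(out, g, missing = "nearest"))
})

test_that("elevation percentile follows the sort-and-interpolate convention", {
  g <- build_grid(make_fixes(rep(0, 3), c(0, 20, 40), elev = 200))
  expect_equal(elevation_percentile(g, 1), 200)
  expect_equal(elevation_percentile(g, 99), 200)

  fx <- make_fixes(seq(0, by = 10, length.out = 100), rep(0, 100),
                   elev = 100:199)
  g2 <- build_grid(fx)
  v <- sort(g2$cells$median_elev)
  for (q in c(0, 25, 50, 99, 100)) {
    h <- (length(v) - 1) * q / 100
    expect_equal(elevation_percentile(g2, q),
                 v[floor(h) + 1] + (h - floor(h)) *
                   (v[min(floor(h) + 2, length(v))] - v[floor(h) + 1]))
  }
})

test_that("hill clustering is single linkage with documented summit tie-break", {
  mk_grid <- function(x, y, elev) {
    build_grid(make_fixes(x, y, elev = elev),
               spec = grid_spec(ref_x = 0, ref_y = 0))
  }
  # nothing above threshold
  expect_equal(nrow(detect_hills(mk_grid(0, 0, 200))), 0)

  # chain 0, 40, 100: first two link (40 <= 50), third is 60 away
  g <- mk_grid(c(0, 40, 100), c(0, 0, 0), elev = c(240, 250, 260))
  h <- detect_hills(g)
  expect_equal(nrow(h), 2)
  expect_setequal(h$summit_elev, c(250, 260))
  expect_equal(sort(h$n_cells), c(1, 2))

  # random supra-threshold cells: components equal the igraph oracle
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    x <- round(runif(n, 0, 40)) * 10
    y <- round(runif(n, 0, 40)) * 10
    keep <- !duplicated(cbind(x, y))
    x <- x[keep]; y <- y[keep]
    g <- mk_grid(x, y, elev = runif(length(x), 230, 280))
    h <- detect_hills(g, link_dist = 50)
    oracle <- oracle_components(g$cells$x_center, g$cells$y_center, 50)
    mine <- integer(length(oracle))
    for (k in seq_len(nrow(h))) {
      cells <- h$cells[[k]]
      idx <- match(paste(cells$x_center, cells$y_center),
                   paste(g$cells$x_center, g$cells$y_center))
      mine[idx] <- k
    }
    expect_true(same_partition(mine, oracle))
    # partition property: every supra-threshold cell in exactly one hill
    expect_equal(sum(h$n_cells), nrow(g$cells))
  }

  # summit tie-break: equal max elevation -> smallest y then smallest x
  g <- mk_grid(c(0, 10, 20), c(10, 0, 0), elev = c(250, 250, 250))
  h <- detect_hills(g)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$summit_x, h$summit_y), c(10, 0))
})

test_that("raising thresholds shrinks hills monotonically", {
  set.seed(8)
  fx <- make_fixes(round(runif(80, 0, 50)) * 10, round(runif(80, 0, 50)) * 10,
                   elev = runif(80, 200, 290))
  g <- build_grid(fx, grid_spec(ref_x = 0, ref_y = 0))
  h230 <- detect_hills(g, 230); h250 <- detect_hills(g, 250)
  expect_lte(sum(h250$n_cells), sum(h230$n_cells))
  h_50 <- detect_hills(g, 230, link_dist = 50)
  h_150 <- detect_hills(g, 230, link_dist = 150)
  expect_lte(nrow(h_150), nrow(h_50))
})

test_that("low locations apply the elevation cutoff and merge rule", {
  mk <- function(x, elev) tibble::tibble(x = x, y = 0, smoothed_elev = elev)
  expect_equal(nrow(detect_low_locations(mk(0, 150))), 1)
  expect_equal(nrow(detect_low_locations(mk(0, 185))), 0)   # above 180
  expect_equal(nrow(detect_low_locations(mk(c(0, 30), c(150, 150)))), 1)
  expect_equal(nrow(detect_low_locations(mk(c(0, 60), c(150, 150)))), 2)
})

test_that("per-cell elevation spread stays within the GPS noise bound", {
  set.seed(14)
  land <- function(x, y) 200 + 20 * sin(x / 300) * cos(y / 300)
  x <- runif(4000, 0, 500); y <- runif(4000, 0, 500)
  fx <- make_fixes(x, y, elev = land(x, y) + rnorm(4000, 0, 4))
  g <- build_grid(fx)
  an <- annotate_elevation(fx, g)
  # smoothed surface deviates from truth by less than the +-13 m bound
  expect_lt(stats::quantile(abs(an$smoothed_elev - land(x, y)), 0.99), 13)
})
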