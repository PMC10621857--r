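# Kernel UD surface, kernel values, contours, band, periphery test.

test_that("UD normalizes to unit volume and finds the data mode", {
  set.seed(31)
  fx <- tibble::tibble(x = rnorm(10000, 500, 300), y = rnorm(10000, -200, 300))
  ud <- fit_ud(fx, h = 149)
  expect_equal(sum(ud$z) * ud$cell^2, 1, tolerance = 1e-6)
  i <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
  expect_lte(abs(ud$x[i[1]] - 500), ud$cell)
  expect_lte(abs(ud$y[i[2]] + 200), ud$cell)

  # smoothing property: doubling h strictly lowers the max density
  ud2 <- fit_ud(fx, h = 298)
  expect_lt(max(ud2$z), max(ud$z))

  expect_error(fit_ud(fx[1, ]), "at least 2")
  expect_error(fit_ud(tibble::tibble(x = rep(1, 5), y = rep(2, 5))),
               "degenerate")
})

test_that("UD agrees with MASS::kde2d under its bandwidth convention", {
  skip_if_not_installed("MASS")
  set.seed(32)
  fx <- tibble::tibble(x = rnorm(400, 0, 500), y = rnorm(400, 0, 500))
  ud <- fit_ud(fx, h = 100, cell = 50)
  # kde2d's h is 4x the Gaussian sd and its lattice is inclusive of lims
  k2 <- MASS::kde2d(fx$x, fx$y, h = 400, n = length(ud$x),
                    lims = c(range(ud$x), range(ud$y)))
  expect_equal(ud$z / sum(ud$z), k2$z / sum(k2$z), tolerance = 1e-6)
})

test_that("kernel values: mode = 1, radial monotonicity, brute-force oracle", {
  set.seed(33)
  # heavy smoothing keeps the UD near-radially-symmetric, as the
  # monotonicity property requires
  fx <- tibble::tibble(x = rnorm(2000, 0, 200), y = rnorm(2000, 0, 200))
  ud <- fit_ud(fx, h = 400)
  i <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
  mode_xy <- c(ud$x[i[1]], ud$y[i[2]])
  expect_equal(kernel_value(ud, mode_xy[1], mode_xy[2]), 1L)

  # non-decreasing in distance from mode along random rays
  for (th in runif(10, 0, 2 * pi)) {
    r <- seq(0, 1400, by = 100)
    kv <- kernel_value(ud, mode_xy[1] + r * cos(th), mode_xy[2] + r * sin(th))
    expect_true(all(diff(kv) >= 0))
  }

  # brute-force oracle: sort all lattice cells by density
  dens <- sort(as.vector(ud$z), decreasing = TRUE)
  cv <- cumsum(dens) * ud$cell^2
  pts <- fx[sample(nrow(fx), 100), ]
  kv <- kernel_value(ud, pts$x, pts$y)
  for (j in seq_len(nrow(pts))) {
    ix <- round((pts$x[j] - ud$x[1]) / ud$cell) + 1
    iy <- round((pts$y[j] - ud$y[1]) / ud$cell) + 1
    d0 <- ud$z[ix, iy]
    k <- sum(as.vector(ud$z) >= d0)
    expect_equal(kv[j], as.integer(max(1, min(99, ceiling(100 * cv[k])))))
  }

  # outside the lattice: 99 with a warning
  expect_warning(out <- kernel_value(ud, 1e6, 1e6), "outside")
  expect_equal(out, 99L)
  expect_error(kernel_value(ud, 1e6, 1e6, strict = TRUE), "outside")
})

test_that("kernel values are invariant under translation of all fixes", {
  set.seed(34)
  fx <- tibble::tibble(x = rnorm(2000, 0, 800), y = rnorm(2000, 0, 800))
  ud <- fit_ud(fx, h = 149)
  ud_t <- fit_ud(dplyr::mutate(fx, x = x + 5000, y = y - 3000), h = 149)
  pts <- fx[1:50, ]
  expect_equal(kernel_value(ud, pts$x, pts$y),
               kernel_value(ud_t, pts$x + 5000, pts$y - 3000))
})

test_that("contours nest, cover the right mass, and match the Gaussian limit", {
  set.seed(35)
  sigma <- 1200
  fx <- tibble::tibble(x = rnorm(10000, 0, sigma), y = rnorm(10000, 0, sigma))
  ud <- fit_ud(fx, h = 149)
  c95 <- ud_contour(ud, 95)
  c50 <- ud_contour(ud, 50)
  expect_lt(c50$area, c95$area)
  expect_gt(c50$level, c95$level)

  # nesting: all points strictly inside the 50% region are inside the 95%
  inside50 <- ud$z >= c50$level
  expect_true(all(ud$z[inside50] >= c95$level))

  # coverage of training fixes by the 95% volume region
  kv <- kernel_value(ud, fx$x, fx$y)
  expect_equal(mean(kv <= 95), 0.95, tolerance = 0.02)

  # closed-form check: for a bivariate normal the 95% region has area
  # 2*pi*sigma_eff^2*ln(20), with sigma_eff^2 = sigma^2 + h^2
  a_true <- 2 * pi * (sigma^2 + 149^2) * log(20)
  expect_equal(c95$area, a_true, tolerance = 0.1)
})

test_that("kernel values are insensitive to lattice halving and track thinning", {
  set.seed(37)
  fx <- tibble::tibble(x = rnorm(4000, 0, 1000), y = rnorm(4000, 0, 1000))
  ud25 <- fit_ud(fx, h = 149, cell = 25)
  ud12 <- fit_ud(fx, h = 149, cell = 12.5)
  k25 <- suppressWarnings(kernel_value(ud25, fx$x, fx$y))
  k12 <- suppressWarnings(kernel_value(ud12, fx$x, fx$y))
  expect_gte(mean(abs(k25 - k12) <= 1), 0.95)

  # serially correlated tracklog fixes: every 3rd fix carries nearly the
  # same spatial information, so the UD (and kernel values) barely move
  tr <- small_sim()$fixes
  tr <- tr[tr$group == tr$group[1], ]
  ud1 <- fit_ud(tr, h = 149)
  ud3 <- fit_ud(tr[seq(1, nrow(tr), 3), ], h = 149)
  k1 <- suppressWarnings(kernel_value(ud1, tr$x, tr$y))
  k3 <- suppressWarnings(kernel_value(ud3, tr$x, tr$y))
  expect_lt(mean(abs(k1 - k3)), 1)
  expect_gte(mean(abs(k1 - k3) <= 2), 0.95)
})

test_that("overlap band construction matches the extreme-visit rule", {
  west <- make_fixes(runif(50, 0, 1000), runif(50, 0, 500), group = "W")
  east <- make_fixes(runif(50, 800, 2000), runif(50, 200, 700), group = "E")
  b <- overlap_band(west, east)
  expect_false(b$empty)
  expect_equal(b$x_min, min(east$x))
  expect_equal(b$x_max, max(west$x))
  expect_lt(b$width, 200 + 1e-9)
  m <- band_mask(b)
  expect_true(all(m(c(b$x_min, b$x_max), c(b$y_min, b$y_min))))
  expect_false(any(m(c(b$x_min - 1, b$x_max + 1), c(b$y_min, b$y_min))))

  # disjoint ranges: explicit no-overlap flag
  b0 <- overlap_band(make_fixes(0:10, 0:10), make_fixes(100:110, 0:10))
  expect_true(b0$empty)
  expect_false(any(band_mask(b0)(c(0, 50, 105), c(0, 5, 5))))
})

test_that("periphery/core comparison equals the rank-sum enumeration", {
  # identical distributions: W = n1 n2 / 2 under symmetric assignment
  d_eq <- tibble::tibble(kernel = rep(c(70:74, 75:79), 2),
                         elev = rep(c(1:5, 1:5), 2))
  r <- periphery_core_test(d_eq)
  expect_equal(r$W, 5 * 5 / 2)
  expect_gt(r$p_value, 0.9)

  # {1,2,3} vs {4,5,6}: exact p from full enumeration of rank assignments
  d <- tibble::tibble(kernel = c(72, 73, 74, 75, 76, 77),
                      elev = c(1, 2, 3, 4, 5, 6))
  r2 <- periphery_core_test(d)
  combos <- utils::combn(6, 3)
  stats <- apply(combos, 2, function(ix) sum(rank(1:6)[ix]) - 6)
  observed <- 0   # core {1,2,3} has the minimal rank sum
  p_exact <- mean(stats <= observed | stats >= max(stats) - observed)
  expect_equal(r2$W, 0)
  expect_equal(r2$p_value, p_exact)
  expect_error(periphery_core_test(tibble::tibble(kernel = c(70, 80),
                                                  elev = c(1, 2))),
               "at least 2")
})

test_that("relative center distance is the equivalent-radius normalization", {
  set.seed(36)
  fx <- tibble::tibble(time = rep(1, 3000),
                       x = rnorm(3000, 0, 900), y = rnorm(3000, 0, 900))
  tm <- territory_model(fx, h = 149)
  expect_equal(relative_center_distance(tm$center_xy[1], tm$center_xy[2], tm), 0)
  r_eq <- sqrt(tm$area95 / pi)
  expect_equal(relative_center_distance(tm$center_xy[1] + r_eq,
                                        tm$center_xy[2], tm), 1)
  d <- relative_center_distance(tm$center_xy[1] + c(100, 500, 2000),
                                tm$center_xy[2], tm)
  expect_true(all(diff(d) > 0))
  expect_error(relative_center_distance(0, 0, tm, year = "1999"),
               "no yearly")
})
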