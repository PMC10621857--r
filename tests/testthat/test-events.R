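# Event-extraction rules: visits, stops, direction, departures,
# advance/retreat, distances, dataset assembly.

hill1 <- tibble::tibble(hill_id = 1L, summit_x = 0, summit_y = 0,
                        summit_elev = 250)

test_that("visit detection applies radius, elevation gate and gap merging", {
  # pass 30 m from the summit at matching elevation for a few minutes
  tr <- make_track(c(-200, 30), c(200, 30), speed = 60)
  tr$smoothed_elev <- 250
  v <- detect_visits(tr, hill1)
  expect_equal(nrow(v), 1)
  expect_false(v$stopped)
  expect_equal(v$location_type, "hill")

  # same horizontal pass but 40 m below the summit elevation (cliff base)
  tr2 <- tr
  tr2$smoothed_elev <- 210
  expect_equal(nrow(detect_visits(tr2, hill1)), 0)

  # milling tightly near the summit for 8 minutes -> stopped visit of 8 min
  # (every fix within the 25 m anchored displacement threshold)
  th <- seq(0, 2 * pi, length.out = 8)
  tr3 <- tibble::tibble(time = 1:8, x = 30 + 12 * cos(th), y = 12 * sin(th),
                        group = "A", follow_id = "f1", smoothed_elev = 250)
  v3 <- detect_visits(tr3, hill1)
  expect_equal(nrow(v3), 1)
  expect_true(v3$stopped)
  expect_equal(v3$stop_minutes, 8)

  # two passes separated by >= 5 min stay distinct visits
  tr4 <- dplyr::bind_rows(
    tibble::tibble(time = 1:2, x = c(-30, 30), y = 0),
    tibble::tibble(time = 10:11, x = c(30, -30), y = 0))
  tr4$group <- "A"; tr4$follow_id <- "f1"; tr4$smoothed_elev <- 250
  expect_equal(nrow(detect_visits(tr4, hill1)), 2)
  # separated by < 5 min they merge
  tr5 <- tr4
  tr5$time <- c(1, 2, 5, 6)
  expect_equal(nrow(detect_visits(tr5, hill1)), 1)
})

test_that("stop rule matches the brute-force all-windows oracle", {
  # stationary 10-min visit
  st <- detect_stop(tibble::tibble(time = 1:10, x = 0, y = 0))
  expect_true(st$stopped)
  expect_equal(st$stop_minutes, 10)

  # steady 60 m/min traverse: no window qualifies
  mv <- detect_stop(tibble::tibble(time = 1:5, x = (1:5) * 60, y = 0))
  expect_false(mv$stopped)
  expect_equal(mv$stop_minutes, 0)

  oracle_stop <- function(fx, min_dur = 5, thr = 25) {
    n <- nrow(fx); best <- 0
    for (i in 1:n) for (j in i:n) {
      win <- fx[i:j, ]
      if (all(sqrt((win$x - win$x[1])^2 + (win$y - win$y[1])^2) <= thr)) {
        best <- max(best, fx$time[j] - fx$time[i] + 1)
      }
    }
    list(stopped = best >= min_dur, stop_minutes = if (best >= min_dur) best else 0)
  }
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    fx <- tibble::tibble(time = 1:n, x = cumsum(rnorm(n, 0, 12)),
                         y = cumsum(rnorm(n, 0, 12)))
    expect_equal(detect_stop(fx), oracle_stop(fx))
  }
})

test_that("direction classification uses kernel change with a dead-band", {
  tr <- tibble::tibble(time = 0:30, kernel = NA)
  tr$kernel <- 40 + (0:30) * 4 / 3   # 40 -> 80 over the lookback
  expect_equal(classify_direction(tr, 30), "toward_border")
  tr$kernel <- 80 - (0:30) * 4 / 3
  expect_equal(classify_direction(tr, 30), "toward_center")
  tr$kernel <- 60 + (0:30) / 15      # 60 -> 62: inside the dead-band
  expect_equal(classify_direction(tr, 30), "ambiguous")
  expect_warning(
    expect_equal(classify_direction(tr[1, ], 0), "ambiguous"),
    "insufficient")
})

test_that("same-day hill counts and order invariance", {
  v <- tibble::tibble(group = "A", follow_id = "d1",
                      location_type = c("hill", "hill", "low", "hill", "hill"),
                      t_arrive = c(10, 50, 70, 90, 130))
  a <- hills_before_after(v)
  expect_equal(a$n_hills_before, c(0, 1, 2, 2, 3))
  expect_equal(a$n_hills_after, c(3, 2, 2, 1, 0))
  # single visit
  a1 <- hills_before_after(v[1, ])
  expect_equal(c(a1$n_hills_before, a1$n_hills_after), c(0, 0))
  # shuffled input gives the same counts after re-sorting
  set.seed(52)
  sh <- v[sample(5), ]
  a2 <- dplyr::arrange(hills_before_after(sh), t_arrive)
  expect_equal(a2$n_hills_before, a$n_hills_before)
  expect_equal(a2$n_hills_after, a$n_hills_after)
})

test_that("rival party size aggregates distinct parties in the window", {
  obs <- tibble::tibble(time = c(100, 110, 115),
                        party_id = c("p1", "p2", "p1"),
                        adult_party_size = c(5, 4, 3))
  expect_equal(rival_party_size(obs[1, ], 120), 5)
  expect_equal(rival_party_size(obs, 120), 3 + 4)  # latest p1 obs counts
  expect_true(is.na(rival_party_size(obs, 300)))
})

test_that("intercommunity distance follows the closest-party rule", {
  own <- tibble::tibble(time = 1:3, x = 0, y = 0)
  r1 <- tibble::tibble(time = 1:3, x = 300, y = 0, party_id = "a")
  r2 <- tibble::tibble(time = 1:3, x = 700, y = 0, party_id = "b")
  both <- dplyr::bind_rows(r1, r2)
  expect_equal(intercommunity_distance(own, both, 1, 3), 300)
  expect_equal(intercommunity_distance(own, own, 1, 3), 0)

  mv <- tibble::tibble(time = 1:3, x = c(100, 200, 300), y = 0)
  expect_equal(intercommunity_distance(own, mv, 1, 3, "mean_over_use"), 200)
  expect_equal(intercommunity_distance(own, mv, 1, 3, "at_departure"), 300)
  # symmetry between groups at matched minutes
  expect_equal(intercommunity_distance(mv, own, 1, 3),
               intercommunity_distance(own, mv, 1, 3))
  expect_true(is.na(intercommunity_distance(own, tibble::tibble(
    time = 50:52, x = 0, y = 0), 1, 3)))
})

test_that("departure requires a definitive exit", {
  # immediate straight-line exit
  tr <- tibble::tibble(time = 0:5, x = c(0, 20, 60, 120, 180, 240), y = 0)
  expect_equal(detect_departure(tr, 0, 0, 0), 2)
  # exit to 60 m then return at minute 3: deferred to the later exit
  tr2 <- tibble::tibble(time = 0:8, x = c(0, 60, 40, 10, 0, 30, 80, 140, 200),
                        y = 0)
  expect_equal(detect_departure(tr2, 0, 0, 0), 6)
  # never leaves
  tr3 <- tibble::tibble(time = 0:5, x = rep(10, 6), y = 0)
  expect_true(is.na(detect_departure(tr3, 0, 0, 0)))
})

test_that("advance/retreat classification and its reflection antisymmetry", {
  mk <- function(x1) tibble::tibble(time = 0:30,
                                    x = seq(0, x1, length.out = 31), y = 0)
  # d0 = 1000, d1 = 400 -> advance; 1300 -> retreat; 980 -> dead-band
  expect_equal(classify_advance(mk(600), 0, 1000, 0), "advance")
  expect_equal(classify_advance(mk(-300), 0, 1000, 0), "retreat")
  expect_equal(classify_advance(mk(20), 0, 1000, 0), "undetermined")
  expect_equal(classify_advance(mk(600), 0, NA, NA), "undetermined")

  # reflecting the post-departure path about the departure point swaps labels
  set.seed(53)
  for (rep in 1:20) {
    # paths along the rival axis, where the reflection argument is exact
    path <- tibble::tibble(time = 0:30,
                           x = cumsum(c(0, rnorm(30, 8, 30))), y = 0)
    refl <- dplyr::mutate(path, x = -x)
    a <- classify_advance(path, 0, 2000, 0)
    b <- classify_advance(refl, 0, 2000, 0)
    expect_equal(b, switch(a, advance = "retreat", retreat = "advance",
                           undetermined = "undetermined"))
  }
})

test_that("stop and advance tables z-transform and filter correctly", {
  set.seed(54)
  n <- 40
  v <- tibble::tibble(
    stopped = rbinom(n, 1, 0.5) == 1,
    direction = sample(c("toward_border", "toward_center", "ambiguous"), n,
                       replace = TRUE),
    n_hills_before = rpois(n, 1), n_hills_after = rpois(n, 1),
    adult_party_size = sample(2:8, n, TRUE),
    intercomm_dist = runif(n, 200, 3000),
    rel_center_dist = runif(n, 0.5, 1.5), kernel = sample(75:99, n, TRUE),
    elev = runif(n, 230, 280), time_of_day = runif(n, 6, 18),
    sex = sample(c("male", "female"), n, TRUE),
    group = sample(c("E", "S"), n, TRUE),
    location_id = sample(1:5, n, TRUE), follow_id = sample(1:10, n, TRUE),
    focal_id = sample(letters[1:6], n, TRUE))
  ds <- build_stop_dataset(v)
  expect_equal(nrow(ds), sum(v$direction != "ambiguous"))
  for (cl in c("n_hills_before_z", "intercomm_dist_z", "elev_z")) {
    expect_equal(mean(ds[[cl]]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(ds[[cl]]), 1, tolerance = 1e-9)
  }
  expect_equal(ds$rel_center_dist_z2, ds$rel_center_dist_z^2)
  expect_true(is.factor(ds$hill_id))

  st <- dplyr::mutate(v[v$stopped, ],
                      advance = sample(c("advance", "retreat", "undetermined"),
                                       sum(v$stopped), TRUE),
                      imbalance = sample(-4:4, sum(v$stopped), TRUE),
                      dist_at_depart = runif(sum(v$stopped), 100, 4000))
  ad <- build_advance_dataset(st)
  expect_equal(nrow(ad), sum(st$advance != "undetermined" &
                               st$direction != "ambiguous"))
  expect_equal(sort(unique(ad$advance)), c(0, 1))
  expect_equal(ad$ln_dist, log(ad$dist_at_depart))
  expect_equal(mean(ad$ln_dist_z), 0, tolerance = 1e-9)
  # empty input keeps headers only
  expect_equal(nrow(build_stop_dataset(v[0, ])), 0)
})

test_that("events form a strict subset chain on the simulated study", {
  ev <- small_events()
  expect_true(all(ev$stops$visit_id %in% ev$visits$visit_id))
  adv <- ev$stops[!is.na(ev$stops$advance) &
                    ev$stops$advance != "undetermined", ]
  expect_true(all(adv$visit_id %in% ev$stops$visit_id))
  expect_true(all(ev$visits$t_last_inside >= ev$visits$t_arrive))
  expect_true(all(ev$stops$stop_minutes >= 5))
  # stopped flag is equivalent to a >= 5 min stop
  expect_true(all(xor(ev$visits$stop_minutes >= 5, !ev$visits$stopped)))
})
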