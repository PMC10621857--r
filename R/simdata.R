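# Synthetic two-group ranging study with known generating parameters.
# The simulator's only job is to realize the statistical structure the
# analysis assumes: an inselberg-studded elevation field, two neighbouring
# territories with an overlap band, minute-resolution focal-follow
# tracklogs with border patrols, hill visits whose stop probability and
# post-stop advance probability follow configurable logistic models, and
# activity streams with group-specific bout lengths. Each day one group is
# the "focal" group (runs the patrol program, makes stop/advance
# decisions); the other is a fully observed background rival, so rival
# positions are always known when decisions are made.

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis is designed for:
#' ~190 m base elevation with +-16 m relief and inselbergs rising to
#' ~240-290 m, a ~2,000 m wide overlap band, 1 fix/min follows of 600 min,
#' group-specific activity bout means (rest 11.6/15.07, feed 16.46/17.66,
#' travel 5.61/7.15 min for the eastern/western group), and logistic
#' event-generating coefficients (direction -> stop 1.6, hills-after ->
#' stop -0.4, imbalance -> advance 0.25, ln-distance x elevation ->
#' advance 0.2, direction -> advance 0.75).
#'
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param days study days (each day both groups are followed).
#' @param minutes_per_day follow length in minutes (default 600).
#' @param groups names, western group first.
#' @param centers_x territory-center x of each group (border at 0).
#' @param n_hills_band,n_hills_outside inselbergs inside / outside the band.
#' @param base_elev,ripple_amp,bump_sd,summit_height landscape shape (m).
#' @param patrol_prob probability a focal day includes a border patrol.
#' @param hills_per_patrol range of hills visited per patrol.
#' @param b0_stop,beta_dir,beta_after stop-model generating logit.
#' @param g0_adv,beta_imb,beta_dist_elev,beta_dir_adv advance-model logit.
#' @param advance_ar_sd,advance_ar_tau SD and timescale (minutes) of the
#'   Ornstein-Uhlenbeck "boldness" process that makes successive advance
#'   decisions of a day serially correlated (the regime the temporal
#'   autocorrelation term is designed for).
#' @param sd_hill,sd_dategroup,sd_focal random-intercept SDs.
#' @param gps_noise_sd,elev_noise_sd GPS noise (m).
#' @param speed travel speed m/min.
#' @param bout_means named list of per-group mean bout minutes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       days = 60,
                       minutes_per_day = 600,
                       groups = c("South", "East"),
                       centers_x = c(-2500, 2500),
                       n_hills_band = 12,
                       n_hills_outside = 4,
                       base_elev = 190,
                       ripple_amp = 16,
                       bump_sd = 60,
                       summit_height = c(52, 95),
                       patrol_prob = 0.75,
                       hills_per_patrol = c(2, 5),
                       b0_stop = -1.1,
                       beta_dir = 1.6,
                       beta_after = -0.4,
                       g0_adv = -0.3,
                       beta_imb = 0.25,
                       beta_dist_elev = 0.2,
                       beta_dir_adv = 0.75,
                       advance_ar_sd = 1.2,
                       advance_ar_tau = 240,
                       sd_hill = 0.5,
                       sd_dategroup = 0.3,
                       sd_focal = 0.3,
                       gps_noise_sd = 5,
                       elev_noise_sd = 4,
                       speed = 55,
                       bout_means = list(rest = c(15.07, 11.6),
                                         feed = c(17.66, 16.46),
                                         travel = c(7.15, 5.61))) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic elevation field and true hills
#'
#' A smooth low-relief base (sinusoidal ripple around `base_elev`) plus
#' Gaussian bumps for inselbergs; bump centers closer than 400 m are
#' re-sampled. Returns the analytic elevation function, the true summit
#' list, and a set of low-elevation spots inside the band used by the
#' track generator for rest stops.
#'
#' @param config a [sim_config()].
#' @return a `sim_landscape`: `elev_fun(x, y)`, `hills` (tibble
#'   `true_hill_id, x, y, elev, in_band`), `low_spots` (tibble `x, y,
#'   elev`).
#' @export
gen_landscape <- function(config) {
  set.seed(config$seed)
  ripple <- function(x, y) {
    config$ripple_amp * sin(x / 450) * cos(y / 700)
  }
  n_total <- config$n_hills_band + config$n_hills_outside
  cx <- numeric(0); cy <- numeric(0)
  draw_center <- function(in_band) {
    if (in_band) c(stats::runif(1, -850, 850), stats::runif(1, -3300, 3300))
    else c(sample(config$centers_x, 1) + stats::runif(1, -1500, 1500),
           stats::runif(1, -2500, 2500))
  }
  in_band_flag <- c(rep(TRUE, config$n_hills_band),
                    rep(FALSE, config$n_hills_outside))
  for (i in seq_len(n_total)) {
    repeat {
      p <- draw_center(in_band_flag[i])
      if (!length(cx) || min(sqrt((cx - p[1])^2 + (cy - p[2])^2)) >= 400) break
    }
    cx <- c(cx, p[1]); cy <- c(cy, p[2])
  }
  h <- stats::runif(n_total, config$summit_height[1], config$summit_height[2])
  elev_fun <- function(x, y) {
    e <- config$base_elev + ripple(x, y)
    for (i in seq_len(n_total)) {
      e <- e + h[i] * exp(-((x - cx[i])^2 + (y - cy[i])^2) /
                            (2 * config$bump_sd^2))
    }
    e
  }
  # re-draw bump heights whose realized summit dips below the hill band
  for (i in seq_len(n_total)) {
    while (elev_fun(cx[i], cy[i]) < 238) h[i] <- h[i] + 5
  }
  hills <- tibble::tibble(true_hill_id = seq_len(n_total), x = cx, y = cy,
                          elev = elev_fun(cx, cy), in_band = in_band_flag)
  low <- tibble::tibble(x = numeric(0), y = numeric(0))
  while (nrow(low) < 40) {
    px <- stats::runif(200, -900, 900); py <- stats::runif(200, -3300, 3300)
    e <- elev_fun(px, py)
    ok <- e <= 177
    low <- dplyr::bind_rows(low, tibble::tibble(x = px[ok], y = py[ok]))
  }
  low <- low[seq_len(40), ]
  low$elev <- elev_fun(low$x, low$y)
  structure(list(elev_fun = elev_fun, hills = hills, low_spots = low,
                 config = config),
            class = "sim_landscape")
}

# ---- path primitives (1 position per minute) -------------------------------

leg_path <- function(from, to, speed, jitter = 8) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1, ceiling(d / speed))
  f <- seq_len(n) / n
  cbind(from[1] + f * (to[1] - from[1]) + c(stats::rnorm(n - 1, 0, jitter), 0),
        from[2] + f * (to[2] - from[2]) + c(stats::rnorm(n - 1, 0, jitter), 0))
}

# leg that detours around hills it is not meant to visit (decisions are
# only generated at intended visits, so incidental passes are avoided)
leg_path_avoid <- function(from, to, speed, avoid, min_clear = 80,
                           depth = 4) {
  if (depth <= 0 || is.null(avoid) || !nrow(avoid)) {
    return(leg_path(from, to, speed))
  }
  ab <- to - from
  len2 <- sum(ab^2)
  if (len2 < 1) return(leg_path(from, to, speed))
  tt <- pmin(pmax(((avoid[, 1] - from[1]) * ab[1] +
                     (avoid[, 2] - from[2]) * ab[2]) / len2, 0), 1)
  fx <- from[1] + tt * ab[1]; fy <- from[2] + tt * ab[2]
  d <- sqrt((fx - avoid[, 1])^2 + (fy - avoid[, 2])^2)
  bad <- which(d < min_clear & tt > 0.03 & tt < 0.97)
  if (!length(bad)) return(leg_path(from, to, speed))
  w <- bad[which.min(d[bad])]
  nrm <- c(-ab[2], ab[1]) / sqrt(len2)
  side <- sign(sum(nrm * (c(fx[w], fy[w]) - avoid[w, ])))
  if (side == 0) side <- 1
  via <- c(fx[w], fy[w]) + side * nrm * (min_clear + 80)
  rbind(leg_path_avoid(from, via, speed, avoid[-w, , drop = FALSE],
                       min_clear, depth - 1),
        leg_path_avoid(via, to, speed, avoid[-w, , drop = FALSE],
                       min_clear, depth - 1))
}

dwell_path <- function(at, n, sd = 3) {
  cbind(at[1] + stats::rnorm(n, 0, sd), at[2] + stats::rnorm(n, 0, sd))
}

wander_path <- function(from, center, n, sd = 28, pull = 0.04) {
  out <- matrix(0, n, 2)
  p <- from
  for (i in seq_len(n)) {
    p <- p + pull * (center - p) + stats::rnorm(2, 0, sd)
    out[i, ] <- p
  }
  out
}

# bout-structured activities for a stretch of n minutes
bout_activities <- function(n, means, weights = c(rest = 0.3, feed = 0.4,
                                                  travel = 0.15, other = 0.15)) {
  acts <- character(0)
  while (length(acts) < n) {
    a <- sample(names(weights), 1, prob = weights)
    m <- if (a == "other") 5 else means[[a]]
    len <- max(1, stats::rpois(1, m))
    acts <- c(acts, rep(a, len))
  }
  acts[seq_len(n)]
}

# ---- day generators --------------------------------------------------------

# background (rival) day: biased wander around a day-center drawn between
# own territory center and the near edge of the band; the rival stays out
# of the band itself (its own hill program runs on its focal days), so
# rival-to-focal distances vary without contaminating the band with
# off-model stop events
background_day <- function(cfg, center, n_min) {
  toward <- -sign(center[1])             # unit direction toward the border
  day_center <- c(center[1] + toward * stats::runif(1, 200, 1300),
                  stats::runif(1, -2000, 2000))
  start <- day_center + stats::rnorm(2, 0, 200)
  pos <- wander_path(start, day_center, n_min)
  list(pos = pos, mode = rep("wander", n_min))
}

# focal day: optional patrol visiting band hills with scripted stop and
# advance/retreat decisions against the (already generated) rival track
focal_day <- function(cfg, land, group_i, center, n_min, t0, rival_pos,
                      re_hill, re_day, re_focal, own_adults, rival_adults) {
  pos <- matrix(NA_real_, 0, 2)
  mode <- character(0)
  events <- list()
  cur <- center + stats::rnorm(2, 0, 150)
  add <- function(p, m) {
    pos <<- rbind(pos, p)
    mode <<- c(mode, rep(m, nrow(p)))
  }
  minutes_left <- function() n_min - nrow(pos)
  ar_state <- list(b = 0, t = -Inf)
  patrol <- stats::runif(1) < cfg$patrol_prob
  add(wander_path(cur, center, min(sample(60:120, 1), n_min)), "wander")
  if (patrol) {
    band_hills <- land$hills[land$hills$in_band, ]
    avoid_all <- as.matrix(band_hills[, c("x", "y")])
    k <- min(sample(seq(cfg$hills_per_patrol[1], cfg$hills_per_patrol[2]), 1),
             nrow(band_hills))
    plan <- band_hills[sample(nrow(band_hills), k), ]
    # outbound hills first (approached from the core: direction is clearly
    # toward the border), then a far point deep in the band, then return
    # hills (approached from the far periphery: direction toward the
    # center). The outbound/return split is uniform over 0..k so that
    # direction and the hills-after count vary independently across days.
    toward <- -sign(center[1])
    n_out <- sample(0:k, 1)
    plan$leg <- rep(c("out", "ret"), c(n_out, k - n_out))
    plan <- plan[order(plan$leg == "ret", toward * plan$x * ifelse(
      plan$leg == "ret", -1, 1)), ]
    visited <- 0
    for (j in seq_len(k)) {
      hill <- plan[j, ]
      cur <- pos[nrow(pos), ]
      if (j == n_out + 1) {
        # far-point excursion between the legs, followed by a walk along
        # the border line: the 30-min lookback at the first return hill
        # then sees descent only, keeping its direction label clean
        far <- c(toward * stats::runif(1, 850, 950),
                 cur[2] + stats::runif(1, -400, 400))
        far2 <- c(far[1] + stats::runif(1, -50, 50),
                  far[2] + sample(c(-1, 1), 1) * stats::runif(1, 800, 1200))
        need_far <- ceiling(sqrt(sum((far - cur)^2)) / cfg$speed) +
          ceiling(sqrt(sum((far2 - far)^2)) / 40)
        if (minutes_left() >= need_far + 180) {
          add(leg_path_avoid(cur, far, cfg$speed, avoid_all), "leg")
          add(leg_path_avoid(far, far2, 40, avoid_all), "leg")
          cur <- pos[nrow(pos), ]
        }
      }
      need <- ceiling(sqrt(sum((c(hill$x, hill$y) - cur)^2)) / cfg$speed)
      if (minutes_left() < need + 90) break
      avoid <- avoid_all[band_hills$true_hill_id != hill$true_hill_id, ,
                         drop = FALSE]
      add(leg_path_avoid(cur, c(hill$x, hill$y), cfg$speed, avoid), "leg")
      visited <- visited + 1
      n_after_planned <- k - j
      # the behavioural ground truth of the approach direction is the
      # actual change in distance to the own territory center over the
      # last 30 min of generated path; the stop decision conditions on it
      n_here <- nrow(pos)
      w0 <- pos[max(1, n_here - 30), ]
      delta <- sqrt(sum((pos[n_here, ] - center)^2)) -
        sqrt(sum((w0 - center)^2))
      dir_num <- as.numeric(delta > 0)
      dir_label <- if (delta > 250) "toward_border"
                   else if (delta < -250) "toward_center" else "ambiguous"
      lp <- cfg$b0_stop + cfg$beta_dir * dir_num +
        cfg$beta_after * (n_after_planned - 1.5) / 1.2 +
        re_hill[hill$true_hill_id] + re_day + re_focal
      stopped <- unname(stats::runif(1) < inv_logit(lp))
      t_arrive <- t0 + nrow(pos) - 1
      ev <- tibble::tibble(location_type = "hill",
                           true_loc_id = hill$true_hill_id,
                           x = hill$x, y = hill$y, elev = hill$elev,
                           t_arrive = t_arrive,
                           direction = dir_label,
                           n_before = j - 1, n_after = n_after_planned,
                           stopped = stopped, advance = NA_character_,
                           own_adults = own_adults,
                           rival_adults = rival_adults,
                           dist_at_depart = NA_real_, t_depart = NA_real_)
      if (stopped) {
        dwell <- 5 + stats::rpois(1, 14)
        dwell <- min(dwell, max(minutes_left() - 60, 6))
        add(dwell_path(c(hill$x, hill$y), dwell), "dwell")
        ev <- advance_move(cfg, ev, pos, mode, t0, rival_pos, n_min,
                           re_day, re_focal, dir_num, center,
                           avoid = avoid_all[band_hills$true_hill_id !=
                                               hill$true_hill_id, ,
                                             drop = FALSE],
                           ar_state = ar_state)
        pos <- ev$pos; mode <- ev$mode; ar_state <- ev$ar_state
        ev <- ev$event
      } else {
        add(dwell_path(c(hill$x, hill$y), 2), "leg")
        ev$t_depart <- t0 + nrow(pos) - 1
      }
      events[[length(events) + 1]] <- ev
    }
    # low-elevation rest stops on the way back
    n_low <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
    for (l in seq_len(n_low)) {
      if (minutes_left() < 120) break
      cur <- pos[nrow(pos), ]
      spot <- land$low_spots[sample(nrow(land$low_spots), 1), ]
      need <- ceiling(sqrt(sum((c(spot$x, spot$y) - cur)^2)) / cfg$speed)
      if (minutes_left() < need + 90) break
      add(leg_path_avoid(cur, c(spot$x, spot$y), cfg$speed, avoid_all), "leg")
      n_here <- nrow(pos)
      w0 <- pos[max(1, n_here - 30), ]
      delta <- sqrt(sum((pos[n_here, ] - center)^2)) -
        sqrt(sum((w0 - center)^2))
      dwell <- 8 + stats::rpois(1, 14)
      add(dwell_path(c(spot$x, spot$y), dwell), "dwell")
      ev <- tibble::tibble(location_type = "low", true_loc_id = NA_integer_,
                           x = spot$x, y = spot$y, elev = spot$elev,
                           t_arrive = t0 + nrow(pos) - dwell,
                           direction = if (delta > 250) "toward_border"
                                       else if (delta < -250) "toward_center"
                                       else "ambiguous",
                           n_before = visited, n_after = 0,
                           stopped = TRUE, advance = NA_character_,
                           own_adults = own_adults,
                           rival_adults = rival_adults,
                           dist_at_depart = NA_real_, t_depart = NA_real_)
      ev <- advance_move(cfg, ev, pos, mode, t0, rival_pos, n_min,
                         re_day, re_focal, as.numeric(delta > 0), center,
                         avoid = avoid_all, ar_state = ar_state)
      pos <- ev$pos; mode <- ev$mode; ar_state <- ev$ar_state
      ev <- ev$event
      events[[length(events) + 1]] <- ev
    }
    cur <- pos[nrow(pos), ]
    if (minutes_left() > 0) {
      home <- leg_path_avoid(cur, center + stats::rnorm(2, 0, 200),
                             cfg$speed, avoid_all)
      home <- home[seq_len(min(nrow(home), minutes_left())), , drop = FALSE]
      add(home, "leg")
    }
  }
  if (minutes_left() > 0) {
    add(wander_path(pos[nrow(pos), ], center, minutes_left()), "wander")
  }
  pos <- pos[seq_len(n_min), , drop = FALSE]
  mode <- mode[seq_len(n_min)]
  list(pos = pos, mode = mode,
       events = if (length(events)) dplyr::bind_rows(events) else NULL)
}

# post-stop advance/retreat: decide from the generating logit and append
# the 30-min response movement
advance_move <- function(cfg, ev, pos, mode, t0, rival_pos, n_min,
                         re_day, re_focal, dir_num, center, avoid = NULL,
                         ar_state = NULL) {
  t_dep <- t0 + nrow(pos)               # first minute after the dwell
  idx <- min(max(t_dep - t0 + 1, 1), nrow(rival_pos))
  rxy <- rival_pos[idx, ]
  cur <- pos[nrow(pos), ]
  d0 <- sqrt(sum((cur - rxy)^2))
  imb <- ev$own_adults - ev$rival_adults
  # Ornstein-Uhlenbeck boldness: exact update at the decision times
  b <- 0
  if (!is.null(ar_state) && cfg$advance_ar_sd > 0) {
    rho <- exp(-(t_dep - ar_state$t) / cfg$advance_ar_tau)
    if (!is.finite(rho)) rho <- 0
    b <- rho * ar_state$b +
      sqrt(max(1 - rho^2, 0)) * stats::rnorm(1, 0, cfg$advance_ar_sd)
    ar_state$b <- b
    ar_state$t <- t_dep
  }
  lp <- cfg$g0_adv + cfg$beta_imb * imb / 3 +
    cfg$beta_dist_elev * ((log(max(d0, 1)) - log(1000)) / 0.8) *
      ((ev$elev - 210) / 35) +
    cfg$beta_dir_adv * dir_num + re_day + re_focal + b
  adv <- unname(stats::runif(1) < inv_logit(lp))
  n_resp <- min(30, n_min - nrow(pos))
  if (n_resp >= 10) {
    u <- (rxy - cur) / max(d0, 1)
    tgt <- if (adv) cur + u * min(0.8 * d0, 35 * n_resp) else
      cur - u * 35 * n_resp
    resp <- if (is.null(avoid)) leg_path(cur, tgt, 35) else
      leg_path_avoid(cur, tgt, 35, avoid)
    resp <- resp[seq_len(min(nrow(resp), n_resp)), , drop = FALSE]
    pos <- rbind(pos, resp)
    mode <- c(mode, rep("leg", nrow(resp)))
    ev$advance <- if (adv) "advance" else "retreat"
  }
  ev$t_depart <- t_dep
  ev$dist_at_depart <- d0
  list(event = ev, pos = pos, mode = mode, ar_state = ar_state)
}

#' Generate two-group tracklogs, observations and truth
#'
#' Runs the day-by-day simulation: each day one group executes the focal
#' program (patrols, scripted stops and advance/retreat responses) while
#' the other provides a fully observed rival track; roles alternate
#' daily. GPS and elevation noise are added to emitted fixes.
#'
#' @param config a [sim_config()].
#' @param landscape a [gen_landscape()] result (regenerated from `config`
#'   when omitted).
#' @return a `sim_study` list: `fixes`, `parties`, `minutes` (activity
#'   stream), `truth` (`hills`, `events`, `config`).
#' @export
gen_tracklogs <- function(config, landscape = NULL) {
  cfg <- config
  if (is.null(landscape)) landscape <- gen_landscape(cfg)
  set.seed(cfg$seed + 1)
  n_min <- cfg$minutes_per_day
  groups <- cfg$groups
  centers <- list(c(cfg$centers_x[1], 0), c(cfg$centers_x[2], 0))
  focals <- lapply(groups, function(g) {
    tibble::tibble(focal_id = paste0(g, "_f", 1:6),
                   sex = rep(c("male", "female"), each = 3))
  })
  re_hill <- stats::rnorm(nrow(landscape$hills), 0, cfg$sd_hill)
  re_focal <- stats::setNames(
    stats::rnorm(12, 0, cfg$sd_focal),
    c(focals[[1]]$focal_id, focals[[2]]$focal_id))
  start_date <- as.Date("2014-01-01")
  food_month <- stats::setNames(
    50 + 25 * sin(2 * pi * (1:36) / 12) + stats::rnorm(36, 0, 5),
    as.character(1:36))
  fixes <- list(); parties <- list(); minutes <- list(); events <- list()
  for (day in seq_len(cfg$days)) {
    date <- start_date + day - 1
    t0 <- (day - 1) * 1440 + 360
    tmin <- t0 + seq_len(n_min) - 1
    focal_i <- if (day %% 2 == 1) 2 else 1     # alternate focal role
    bg_i <- 3 - focal_i
    adults <- c(sample(3:9, 1), sample(3:9, 1))
    bg <- background_day(cfg, centers[[bg_i]], n_min)
    re_day <- stats::rnorm(2, 0, cfg$sd_dategroup)
    day_focal <- vapply(1:2, function(i) sample(focals[[i]]$focal_id, 1),
                        character(1))
    foc <- focal_day(cfg, landscape, focal_i, centers[[focal_i]], n_min, t0,
                     bg$pos, re_hill, re_day[focal_i],
                     re_focal[day_focal[focal_i]],
                     adults[focal_i], adults[bg_i])
    month_key <- as.character((day - 1) %/% 30 + 1)
    for (i in 1:2) {
      dd <- if (i == focal_i) foc else bg
      g <- groups[i]
      fid <- sprintf("%s_d%03d", g, day)
      true_elev <- landscape$elev_fun(dd$pos[, 1], dd$pos[, 2])
      fixes[[length(fixes) + 1]] <- tibble::tibble(
        time = tmin,
        x = dd$pos[, 1] + stats::rnorm(n_min, 0, cfg$gps_noise_sd),
        y = dd$pos[, 2] + stats::rnorm(n_min, 0, cfg$gps_noise_sd),
        elev = true_elev + stats::rnorm(n_min, 0, cfg$elev_noise_sd),
        group = g, follow_id = fid, focal_id = day_focal[i])
      parties[[length(parties) + 1]] <- tibble::tibble(
        time = tmin, group = g, party_id = g,
        adult_party_size = adults[i],
        party_size = adults[i] + stats::rpois(1, adults[i] / 2),
        n_oestrus = stats::rpois(1, 0.6))
      sex <- focals[[i]]$sex[focals[[i]]$focal_id == day_focal[i]]
      sex_class <- if (sex == "female" && stats::runif(1) < 0.15)
        "oestrus_female" else sex
      act <- character(n_min)
      act[dd$mode == "leg"] <- "travel"
      act[dd$mode == "dwell"] <- "rest"
      iw <- which(dd$mode == "wander")
      if (length(iw)) {
        means <- lapply(cfg$bout_means, function(v) v[i])
        act[iw] <- bout_activities(length(iw), means)
      }
      minutes[[length(minutes) + 1]] <- tibble::tibble(
        time = tmin, date = date, group = g, follow_id = fid,
        focal_id = day_focal[i], x = dd$pos[, 1], y = dd$pos[, 2],
        elev = true_elev, activity = act, sex_class = sex_class,
        party_size = adults[i] + stats::rpois(1, adults[i] / 2),
        adult_party_size = adults[i],
        n_oestrus = stats::rpois(1, 0.6),
        food_avail = unname(food_month[month_key]))
    }
    if (!is.null(foc$events)) {
      ev <- foc$events
      ev$group <- groups[focal_i]
      ev$follow_id <- sprintf("%s_d%03d", groups[focal_i], day)
      ev$focal_id <- day_focal[focal_i]
      events[[length(events) + 1]] <- ev
    }
  }
  structure(list(
    fixes = dplyr::bind_rows(fixes),
    parties = dplyr::bind_rows(parties),
    minutes = dplyr::bind_rows(minutes),
    truth = list(hills = landscape$hills,
                 events = dplyr::bind_rows(events),
                 config = cfg),
    landscape = landscape),
    class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", nrow(x$fixes), " fixes, ",
      nrow(x$truth$events), " true events (",
      sum(x$truth$events$stopped), " stops)\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk as a CSV bundle
#'
#' Emits `fixes.csv`, `parties.csv`, `minutes.csv`, `truth_hills.csv`,
#' `truth_events.csv` and a README of generating values — the same
#' formats the pipeline ingests.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param force overwrite an existing directory (default `FALSE`).
#' @return the `sim_study`, invisibly.
#' @export
gen_fixture_suite <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("gen_fixture_suite: ", dir, " exists; use force = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_tracklogs(config)
  readr::write_csv(sim$fixes, file.path(dir, "fixes.csv"))
  readr::write_csv(sim$parties, file.path(dir, "parties.csv"))
  readr::write_csv(sim$minutes, file.path(dir, "minutes.csv"))
  readr::write_csv(sim$truth$hills, file.path(dir, "truth_hills.csv"))
  readr::write_csv(sim$truth$events, file.path(dir, "truth_events.csv"))
  gen <- config[c("seed", "days", "minutes_per_day", "b0_stop", "beta_dir",
                  "beta_after", "g0_adv", "beta_imb", "beta_dist_elev",
                  "beta_dir_adv", "sd_hill", "sd_dategroup", "sd_focal",
                  "gps_noise_sd")]
  writeLines(c("# Synthetic ranging-study bundle",
               "Generating values:",
               paste0("- ", names(gen), " = ",
                      vapply(gen, function(v) paste(v, collapse = ","),
                             character(1)))),
             file.path(dir, "README.md"))
  invisible(sim)
}
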