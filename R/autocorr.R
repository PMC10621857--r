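# Residual autocorrelation. Diagnostics correlate pairwise |residual
# differences| with time lags / map distances; the correction is a
# per-row Gaussian-weighted average of all other same-group residuals
# added to the model as a fixed effect, with the weighting SD chosen by
# maximizing the refit model's likelihood.

#' Temporal and spatial autocorrelation diagnostics
#'
#' Within each pairing unit, computes the Pearson correlation over all
#' point pairs between |r_i - r_j| and the time lag (temporal) or the
#' Euclidean map distance (spatial), and averages the per-unit
#' correlations. All-pairs work is quadratic, so the default pairing unit
#' is the (group, day); pass coarser keys for an all-days check.
#'
#' @param residuals numeric vector (response minus fitted probability).
#' @param times times (minutes or POSIXct).
#' @param x,y coordinates in meters (optional; spatial part skipped when
#'   absent).
#' @param units pairing-unit keys (e.g. `paste(group, follow_id)`).
#' @return list with `mean_temporal`, `mean_spatial`, and a per-unit
#'   tibble `by_unit`.
#' @export
ac_diagnostics <- function(residuals, times, x = NULL, y = NULL, units) {
  tm <- time_minutes(times)
  per <- purrr::map_dfr(split(seq_along(residuals), units), function(idx) {
    if (length(idx) < 3) {
      return(tibble::tibble(unit = units[idx[1]], r_temporal = NA_real_,
                            r_spatial = NA_real_, n = length(idx)))
    }
    pr <- utils::combn(idx, 2)
    dr <- abs(residuals[pr[1, ]] - residuals[pr[2, ]])
    dt <- abs(tm[pr[1, ]] - tm[pr[2, ]])
    rt <- if (stats::sd(dr) == 0 || stats::sd(dt) == 0) NA_real_ else
      stats::cor(dr, dt)
    rs <- NA_real_
    if (!is.null(x)) {
      dd <- sqrt((x[pr[1, ]] - x[pr[2, ]])^2 + (y[pr[1, ]] - y[pr[2, ]])^2)
      rs <- if (stats::sd(dr) == 0 || stats::sd(dd) == 0) NA_real_ else
        stats::cor(dr, dd)
    }
    tibble::tibble(unit = units[idx[1]], r_temporal = rt, r_spatial = rs,
                   n = length(idx))
  })
  list(mean_temporal = mean(per$r_temporal, na.rm = TRUE),
       mean_spatial = mean(per$r_spatial, na.rm = TRUE),
       by_unit = per)
}

#' Gaussian-weighted temporal autocorrelation term
#'
#' For each row i, the weighted average of all other same-group
#' residuals, with weights `dnorm(t_i - t_j, sd = sigma)`; weights
#' normalize within the group, so each value is a convex combination of
#' the other residuals. Rows whose group has no other member get `NA`.
#'
#' @param residuals numeric vector.
#' @param times times (minutes or POSIXct); absolute, so both within-day
#'   and across-day lags contribute.
#' @param groups group keys.
#' @param sigma Gaussian SD in minutes (> 0).
#' @return numeric vector, same length as `residuals`.
#' @export
ac_term <- function(residuals, times, groups, sigma) {
  stopifnot(sigma > 0)
  tm <- time_minutes(times)
  out <- rep(NA_real_, length(residuals))
  for (idx in split(seq_along(residuals), groups)) {
    if (length(idx) < 2) next
    # log-space weights with a per-row shift so tiny sigmas do not
    # underflow to 0/0; the shift cancels in the normalized average
    lw <- -0.5 * (outer(tm[idx], tm[idx], "-") / sigma)^2
    diag(lw) <- -Inf
    w <- exp(lw - apply(lw, 1, max))
    out[idx] <- as.vector(w %*% residuals[idx]) / rowSums(w)
  }
  out
}

#' Choose the autocorrelation-term bandwidth by maximum likelihood
#'
#' From a fitted base model (without the AC term), computes
#' response-scale residuals, and for each candidate sigma builds the
#' Gaussian-weighted AC term, z-transforms it, and refits the model with
#' the term as an additional fixed effect; the sigma maximizing the refit
#' log-likelihood wins. An optional golden-section refinement around the
#' best grid point follows.
#'
#' @param model a converged `hill_glmm` (the base model).
#' @param times,groups per-row times and group keys, aligned with
#'   `model$data`.
#' @param sigma_grid candidate SDs in minutes; default 25 log-spaced
#'   points from 5 minutes to 24 hours.
#' @param refine golden-section refinement (default `TRUE`).
#' @param ac_name column/term name for the AC covariate.
#' @return list with `sigma` (the argmax), `fit` (the refit `hill_glmm`),
#'   and `profile` (tibble `sigma, logLik`).
#' @export
fit_ac_sigma <- function(model, times, groups,
                         sigma_grid = exp(seq(log(5), log(1440),
                                              length.out = 25)),
                         refine = TRUE, ac_name = "ac_term_z") {
  if (!length(sigma_grid)) stop("fit_ac_sigma: empty sigma grid")
  # response-scale residuals against the MARGINAL (fixed-effects-only)
  # fitted probabilities: conditional residuals would already have the
  # day-level correlation absorbed by the random intercepts, leaving the
  # term nothing to measure
  eta <- as.vector(stats::model.matrix(model$fit) %*% lme4::fixef(model$fit))
  resid <- model$data[[model$response]] - stats::plogis(eta)
  eval_sigma <- function(s) {
    v <- ac_term(resid, times, groups, s)
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) return(NULL)
    d <- model$data
    v[is.na(v)] <- mean(v, na.rm = TRUE)   # singleton groups: neutral value
    d[[ac_name]] <- (v - mean(v)) / stats::sd(v)
    tryCatch(
      suppressMessages(hill_glmm(d, model$response,
                                 c(model$fixed, ac_name), model$random)),
      error = function(e) NULL)
  }
  prof <- purrr::map_dfr(sigma_grid, function(s) {
    f <- eval_sigma(s)
    tibble::tibble(sigma = s,
                   logLik = if (is.null(f)) NA_real_ else
                     as.numeric(stats::logLik(f$fit)),
                   ac_coef = if (is.null(f)) NA_real_ else
                     unname(lme4::fixef(f$fit)[ac_name]))
  })
  if (all(is.na(prof$logLik))) stop("fit_ac_sigma: no candidate converged")
  # The term models POSITIVE temporal autocorrelation; a large negative
  # coefficient is the signature of the degenerate flat-weight limit, in
  # which the leave-one-out average mechanically anti-copies the row's
  # own residual and the likelihood chases that copy. Candidates with a
  # negative coefficient are therefore not eligible for the argmax
  # (they stay in the profile for inspection).
  ok <- !is.na(prof$logLik) & prof$ac_coef >= 0 & prof$ac_coef <= 3
  if (!any(ok)) {
    warning("fit_ac_sigma: the autocorrelation term is degenerate at every ",
            "candidate bandwidth (sparse events); returning the base model")
    return(list(sigma = NA_real_, fit = model, profile = prof))
  }
  best <- prof$sigma[ok][which.max(prof$logLik[ok])]
  if (refine && length(sigma_grid) > 2) {
    i <- which(prof$sigma == best)[1]
    lo <- log(prof$sigma[max(i - 1, 1)])
    hi <- log(prof$sigma[min(i + 1, nrow(prof))])
    phi <- (sqrt(5) - 1) / 2
    ll_at <- function(ls) {
      f <- eval_sigma(exp(ls))
      if (is.null(f)) -Inf else as.numeric(stats::logLik(f$fit))
    }
    a <- lo; b <- hi
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- ll_at(c1); f2 <- ll_at(c2)
    for (k in seq_len(8)) {
      if (f1 < f2) {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- ll_at(c2)
      } else {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- ll_at(c1)
      }
    }
    cand <- exp((a + b) / 2)
    f <- eval_sigma(cand)
    cf <- if (is.null(f)) NA_real_ else unname(lme4::fixef(f$fit)[ac_name])
    if (!is.null(f) && !is.na(cf) && cf >= 0 && cf <= 3 &&
        as.numeric(stats::logLik(f$fit)) >
          max(prof$logLik[ok], na.rm = TRUE)) {
      best <- cand
    }
  }
  fit <- eval_sigma(best)
  list(sigma = best, fit = fit, profile = prof)
}
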