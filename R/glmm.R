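# Binomial logit mixed models. Fitting is delegated to lme4::glmer
# (maximum likelihood, Laplace approximation); this module supplies the
# inference surface used throughout: full-null likelihood-ratio tests,
# marginality-respecting drop1 LRTs, stepwise interaction reduction,
# Nakagawa R-squared, VIF on the fixed-effects design, parametric
# bootstrap CIs, leave-one-level-out stability, and overdispersion.

#' Fit a binomial logit mixed model
#'
#' Builds `response ~ fixed... + (1 | random)...` and fits it by maximum
#' likelihood (Laplace). Random factors with fewer than 2 levels are
#' dropped with a message. Complete separation (a constant response, or a
#' saturated unpenalized logistic fit) raises an error.
#'
#' @param data modeling tibble (see [build_stop_dataset()] and friends).
#' @param response name of the 0/1 response column.
#' @param fixed character vector of fixed-effect terms; interactions as
#'   `"a:b"` (main effects must be listed too).
#' @param random character vector of random-intercept factors.
#' @return a `hill_glmm` object.
#' @export
hill_glmm <- function(data, response, fixed, random) {
  data <- tibble::as_tibble(data)
  stop_if_missing_cols(data, response, "model data")
  y <- data[[response]]
  if (length(unique(y)) < 2) {
    stop("complete separation: response '", response, "' is constant")
  }
  random <- random[vapply(random, function(r) {
    ok <- length(unique(data[[r]])) >= 2
    if (!ok) message("dropping random factor '", r, "' (single level)")
    ok
  }, logical(1))]
  if (!length(random)) stop("hill_glmm: need at least one random factor")
  main <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  for (tm in main) {
    v <- data[[tm]]
    if (is.numeric(v) && length(unique(v)) > 1 &&
        (min(v[y == 1]) > max(v[y == 0]) || max(v[y == 1]) < min(v[y == 0]))) {
      stop("complete separation detected: term '", tm,
           "' perfectly separates '", response, "'")
    }
  }
  glm_form <- stats::reformulate(c("1", main), response = response)
  sep <- FALSE
  withCallingHandlers(
    g0 <- stats::glm(glm_form, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep && all(abs(stats::fitted(g0) - y) < 1e-6)) {
    stop("complete separation detected in model for '", response, "'")
  }
  rhs <- c(if (length(fixed)) fixed else "1",
           paste0("(1 | ", random, ")"))
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = data, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  converged <- !any(grepl("failed to converge|unable to evaluate|degenerate",
                          msgs))
  structure(list(fit = fit, data = data, response = response, fixed = fixed,
                 random = random, formula = form, converged = converged,
                 messages = msgs),
            class = "hill_glmm")
}

refit_terms <- function(model, fixed) {
  hill_glmm(model$data, model$response, fixed, model$random)
}

#' @export
print.hill_glmm <- function(x, ...) {
  cat("<hill_glmm> ", deparse(x$formula), "\n  n = ", nrow(x$data),
      "; logLik = ", round(as.numeric(stats::logLik(x$fit)), 2),
      if (!x$converged) "; NOT converged" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fixed-effect table of a hill_glmm
#'
#' Wald z statistics and normal-approximation CIs, one row per fixed
#' coefficient. p-values for individual terms should come from
#' [drop1_lrt()] (likelihood-ratio tests); the Wald column is reported for
#' table parity.
#'
#' @param x a `hill_glmm`.
#' @param conf.level CI level (default 0.95).
#' @param ... unused.
#' @return tibble `term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high`.
#' @method tidy hill_glmm
#' @export
tidy.hill_glmm <- function(x, conf.level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4],
                 conf.low = sm[, 1] - zq * sm[, 2],
                 conf.high = sm[, 1] + zq * sm[, 2])
}

#' One-line model summary
#'
#' @param x a `hill_glmm`.
#' @param ... unused.
#' @return tibble with `nobs`, `logLik`, `AIC`, `r2_marginal`,
#'   `r2_conditional`, `dispersion`, `converged`.
#' @method glance hill_glmm
#' @export
glance.hill_glmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble::tibble(nobs = nrow(x$data),
                 logLik = as.numeric(stats::logLik(x$fit)),
                 AIC = stats::AIC(x$fit),
                 r2_marginal = r2$marginal, r2_conditional = r2$conditional,
                 dispersion = overdispersion(x),
                 converged = x$converged)
}

#' Full-null likelihood-ratio test
#'
#' chi^2 = 2 (logLik_full - logLik_null), df = difference in fixed
#' parameter counts; the null model retains only controls and the random
#' effects. chi^2 is clipped at 0 for boundary noise.
#'
#' @param full,null `hill_glmm` fits on the same data; `null` must be
#'   nested in `full`.
#' @return tibble `chi2, df, p_value`.
#' @export
lrt_full_null <- function(full, null) {
  pf <- length(lme4::fixef(full$fit))
  pn <- length(lme4::fixef(null$fit))
  if (pn >= pf ||
      !all(names(lme4::fixef(null$fit)) %in% names(lme4::fixef(full$fit)))) {
    stop("lrt_full_null: null model is not nested in the full model")
  }
  if (nrow(full$data) != nrow(null$data)) {
    stop("lrt_full_null: models fitted on different row counts")
  }
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                        as.numeric(stats::logLik(null$fit))))
  df <- pf - pn
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# terms droppable under marginality: not contained in a higher-order term
droppable_terms <- function(fixed) {
  comp <- lapply(strsplit(fixed, ":", fixed = TRUE), sort)
  keep <- vapply(seq_along(fixed), function(i) {
    !any(vapply(seq_along(fixed), function(j) {
      j != i && length(comp[[j]]) > length(comp[[i]]) &&
        all(comp[[i]] %in% comp[[j]])
    }, logical(1)))
  }, logical(1))
  fixed[keep]
}

#' Per-term likelihood-ratio tests (drop1)
#'
#' For each droppable fixed term (marginality respected: no main effect is
#' dropped while an interaction containing it stands), refits the model
#' without the term and reports the LRT against the full model.
#'
#' @param model a `hill_glmm`.
#' @param terms optional subset of terms to test; an unknown term errors.
#' @return tibble `term, chi2, df, p_value`.
#' @export
drop1_lrt <- function(model, terms = NULL) {
  drop_set <- droppable_terms(model$fixed)
  if (!is.null(terms)) {
    bad <- setdiff(terms, model$fixed)
    if (length(bad)) stop("drop1_lrt: term(s) not in model: ",
                          paste(bad, collapse = ", "))
    drop_set <- intersect(drop_set, terms)
  }
  ll_full <- as.numeric(stats::logLik(model$fit))
  purrr::map_dfr(drop_set, function(tm) {
    red <- refit_terms(model, setdiff(model$fixed, tm))
    chi2 <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red$fit))))
    df <- length(lme4::fixef(model$fit)) - length(lme4::fixef(red$fit))
    tibble::tibble(term = tm, chi2 = chi2, df = df,
                   p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
  })
}

#' Stepwise removal of nonsignificant interactions
#'
#' Iteratively removes the least significant nonsignificant interaction,
#' highest order first (three-way before two-way), refitting after each
#' removal. Main effects and controls are never removed.
#'
#' @param model a `hill_glmm`.
#' @param alpha significance threshold (default 0.05).
#' @return the reduced `hill_glmm` (possibly identical terms).
#' @export
reduce_model <- function(model, alpha = 0.05) {
  repeat {
    inter <- model$fixed[grepl(":", model$fixed, fixed = TRUE)]
    if (!length(inter)) return(model)
    ord <- vapply(strsplit(inter, ":", fixed = TRUE), length, integer(1))
    cand <- intersect(droppable_terms(model$fixed), inter[ord == max(ord)])
    if (!length(cand)) return(model)
    tests <- drop1_lrt(model, terms = cand)
    ns <- tests[tests$p_value >= alpha, ]
    if (!nrow(ns)) return(model)
    drop_term <- ns$term[which.max(ns$p_value)]
    model <- refit_terms(model, setdiff(model$fixed, drop_term))
  }
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance decomposition for binomial-logit mixed models on the latent
#' scale: marginal = var(X beta) / (var(X beta) + sum(RE variances) +
#' pi^2/3); conditional adds the random-effect variance to the numerator.
#'
#' @param model a `hill_glmm`.
#' @return list `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(model) {
  X <- stats::model.matrix(model$fit)
  vf <- stats::var(as.vector(X %*% lme4::fixef(model$fit)))
  vc <- lme4::VarCorr(model$fit)
  vr <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  tot <- vf + vr + pi^2 / 3
  list(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Variance inflation factors of the main-effects design
#'
#' Computed on a standard linear design lacking the random effects:
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each design column on the
#' others. Exact collinearity is reported as `Inf`.
#'
#' @param data modeling tibble.
#' @param terms character vector of main-effect terms.
#' @return tibble `term, vif`.
#' @export
vif_terms <- function(data, terms) {
  X <- stats::model.matrix(stats::reformulate(terms), data = data)[, -1,
                                                                   drop = FALSE]
  if (ncol(X) < 2) return(tibble::tibble(term = colnames(X), vif = 1))
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = colnames(X), vif = vifs)
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates responses from the fitted model (fixed effects plus freshly
#' sampled random effects), refits, and returns percentile intervals of
#' the fixed coefficients. Reproducible given `seed`.
#'
#' @param model a converged `hill_glmm`.
#' @param nsim number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level CI level (default 0.95).
#' @return tibble `term, estimate, conf.low, conf.high` with attribute
#'   `n_ok` (converged replicates). A warning is raised when more than
#'   10 percent of replicates fail.
#' @export
bootstrap_ci <- function(model, nsim = 1000, seed = 1, level = 0.95) {
  if (nsim <= 0) stop("bootstrap_ci: nsim must be positive")
  set.seed(seed)
  sims <- stats::simulate(model$fit, nsim = nsim, use.u = FALSE)
  est <- lme4::fixef(model$fit)
  draws <- matrix(NA_real_, nsim, length(est),
                  dimnames = list(NULL, names(est)))
  for (b in seq_len(nsim)) {
    fb <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(model$fit, sims[[b]]))),
      error = function(e) NULL)
    if (!is.null(fb)) draws[b, ] <- lme4::fixef(fb)
  }
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.9) {
    warning("bootstrap_ci: only ", sum(ok), "/", nsim,
            " replicates converged")
  }
  a <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        conf.low = qs[1, ], conf.high = qs[2, ])
  attr(out, "n_ok") <- sum(ok)
  out
}

#' Leave-one-level-out stability of fixed estimates
#'
#' Refits the model excluding each level of each random factor in turn
#' and reports the range of every fixed estimate across exclusions.
#'
#' @param model a `hill_glmm`.
#' @return tibble `term, estimate, min, max`.
#' @export
stability <- function(model) {
  lv <- unlist(lapply(model$random, function(r) {
    u <- unique(as.character(model$data[[r]]))
    if (length(u) < 2) stop("stability: random factor '", r,
                            "' has a single level; nothing to exclude")
    paste(r, u, sep = "\r")
  }))
  est <- lme4::fixef(model$fit)
  mat <- matrix(NA_real_, length(lv), length(est),
                dimnames = list(NULL, names(est)))
  for (i in seq_along(lv)) {
    p <- strsplit(lv[i], "\r", fixed = TRUE)[[1]]
    sub <- model$data[as.character(model$data[[p[1]]]) != p[2], ]
    fb <- tryCatch(
      suppressMessages(hill_glmm(sub, model$response, model$fixed,
                                 model$random)),
      error = function(e) NULL)
    if (!is.null(fb)) {
      fe <- lme4::fixef(fb$fit)
      mat[i, names(fe)] <- fe
    }
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 min = apply(mat, 2, min, na.rm = TRUE),
                 max = apply(mat, 2, max, na.rm = TRUE))
}

#' Overdispersion statistic
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom; values near 1 indicate a well-specified binomial model.
#'
#' @param model a `hill_glmm`.
#' @return numeric dispersion statistic.
#' @export
overdispersion <- function(model) {
  if (!nrow(model$data)) stop("overdispersion: empty data")
  rp <- stats::residuals(model$fit, type = "pearson")
  df <- nrow(model$data) - length(lme4::fixef(model$fit)) -
    length(model$random)
  sum(rp^2) / df
}
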