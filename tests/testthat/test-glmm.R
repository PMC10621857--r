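# Mixed-model inference surface.

sim_glmm_data <- function(n = 400, beta = c(-0.5, 1), sd_re = 1,
                          n_groups = 40, seed = 1) {
  set.seed(seed)
  g <- factor(sample(seq_len(n_groups), n, replace = TRUE))
  x <- rnorm(n)
  eta <- beta[1] + beta[2] * x + rnorm(n_groups, 0, sd_re)[g]
  p <- 1 / (1 + exp(-eta))
  tibble::tibble(y = rbinom(n, 1, p), x = x, g = g,
                 g2 = factor(sample(1:10, n, TRUE)))
}

test_that("zero random variance reduces to plain logistic regression", {
  d <- sim_glmm_data(n = 800, sd_re = 0, seed = 71)
  m <- hill_glmm(d, "y", "x", "g")
  g0 <- stats::glm(y ~ x, data = d, family = stats::binomial())
  expect_equal(unname(lme4::fixef(m$fit)), unname(stats::coef(g0)),
               tolerance = 1e-3)
  # conditional R2 collapses to marginal when the RE variance vanishes
  r2 <- r2_nakagawa(m)
  expect_equal(r2$marginal, r2$conditional, tolerance = 1e-4)
})

test_that("full-null LRT equals the deviance difference and nests properly", {
  d <- sim_glmm_data(n = 500, seed = 72)
  full <- hill_glmm(d, "y", c("x"), "g")
  null <- hill_glmm(d, "y", character(0), "g")
  lrt <- lrt_full_null(full, null)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$chi2,
               2 * (as.numeric(logLik(full$fit)) - as.numeric(logLik(null$fit))))
  expect_equal(lrt$p_value, pchisq(lrt$chi2, 1, lower.tail = FALSE))
  # identical models: chi2 clipped at 0 needs df > 0, so compare to itself
  expect_error(lrt_full_null(null, full), "not nested")

  # plain-GLM cross-check of the deviance difference on the same data
  g_full <- glm(y ~ x, data = d, family = binomial())
  g_null <- glm(y ~ 1, data = d, family = binomial())
  expect_equal(anova(g_null, g_full)$Deviance[2],
               2 * (as.numeric(logLik(g_full)) - as.numeric(logLik(g_null))))
})

test_that("drop1 respects marginality and reduce removes top interactions", {
  set.seed(73)
  n <- 400
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      g = factor(sample(1:30, n, TRUE)))
  eta <- -0.2 + 0.8 * d$x1 + 0.6 * d$x2 + 0.9 * d$x1 * d$x2 +
    rnorm(30, 0, 0.4)[d$g]
  d$y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fixed <- c("x1", "x2", "x3", "x1:x2", "x1:x2:x3")
  m <- hill_glmm(d, "y", fixed, "g")
  dr <- drop1_lrt(m)
  # only x3... no: x3 is in the three-way; droppable is the three-way only
  expect_setequal(dr$term, "x1:x2:x3")
  expect_error(drop1_lrt(m, terms = "nope"), "not in model")

  red <- reduce_model(m, alpha = 0.05)
  # true two-way kept, spurious three-way dropped
  expect_true("x1:x2" %in% red$fixed)
  expect_false("x1:x2:x3" %in% red$fixed)
  # main effects never removed
  expect_true(all(c("x1", "x2", "x3") %in% red$fixed))
})

test_that("Nakagawa R2 matches independent arithmetic", {
  d <- sim_glmm_data(n = 600, seed = 74)
  m <- hill_glmm(d, "y", "x", "g")
  X <- model.matrix(~x, d)
  vf <- var(as.vector(X %*% lme4::fixef(m$fit)))
  vr <- as.numeric(lme4::VarCorr(m$fit)$g)
  r2 <- r2_nakagawa(m)
  expect_equal(r2$marginal, vf / (vf + vr + pi^2 / 3))
  expect_equal(r2$conditional, (vf + vr) / (vf + vr + pi^2 / 3))
  expect_gte(r2$conditional, r2$marginal)
  # null model: zero marginal
  m0 <- hill_glmm(d, "y", character(0), "g")
  expect_equal(r2_nakagawa(m0)$marginal, 0)
})

test_that("VIFs equal 1/(1-R2) and agree with the standard implementation", {
  set.seed(75)
  n <- 300
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  d$c <- 0.7 * d$a + 0.5 * rnorm(n)
  d$y <- rnorm(n)
  v <- vif_terms(d, c("a", "b", "c"))
  # orthogonal-ish b has VIF near 1; correlated pair above 1
  expect_gt(v$vif[v$term == "a"], 1.5)
  expect_lt(abs(v$vif[v$term == "b"] - 1), 0.05)

  skip_if_not_installed("car")
  cv <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(v$vif, unname(cv[v$term]), tolerance = 1e-8)

  # exact collinearity flagged as infinite
  d$dup <- d$a
  vdup <- vif_terms(d, c("a", "b", "dup"))
  expect_true(any(!is.finite(vdup$vif)))
})

test_that("parametric bootstrap is seed-reproducible with valid intervals", {
  d <- sim_glmm_data(n = 300, n_groups = 20, seed = 76)
  m <- hill_glmm(d, "y", "x", "g")
  b1 <- bootstrap_ci(m, nsim = 30, seed = 9)
  b2 <- bootstrap_ci(m, nsim = 30, seed = 9)
  expect_equal(b1, b2)
  expect_true(all(b1$conf.low <= b1$estimate & b1$estimate <= b1$conf.high))
  expect_error(bootstrap_ci(m, nsim = 0), "positive")
})

test_that("stability ranges bracket the full-data estimates", {
  d <- sim_glmm_data(n = 400, n_groups = 8, seed = 77)
  m <- hill_glmm(d, "y", "x", "g")
  st <- stability(m)
  expect_true(all(st$min <= st$estimate + 1e-6 &
                    st$estimate - 1e-6 <= st$max))
  # a single-level factor cannot be excluded
  d1 <- dplyr::mutate(d, solo = factor("only"))
  m1 <- hill_glmm(d, "y", "x", "g")
  m1$random <- "solo"
  m1$data$solo <- factor("only")
  expect_error(stability(m1), "single level")
})

test_that("overdispersion is near 1 for a well-specified binary model", {
  d <- sim_glmm_data(n = 1000, seed = 78)
  m <- hill_glmm(d, "y", "x", "g")
  expect_equal(overdispersion(m), 1, tolerance = 0.25)
  expect_gt(overdispersion(m), 0)
})

test_that("degenerate responses raise separation errors", {
  d <- sim_glmm_data(n = 100, seed = 79)
  d$y <- 0
  expect_error(hill_glmm(d, "y", "x", "g"), "separation")
  d2 <- sim_glmm_data(n = 100, seed = 80)
  d2$xsep <- ifelse(d2$y == 1, 1, -1)
  expect_error(hill_glmm(d2, "y", "xsep", "g"), "separation")
})
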