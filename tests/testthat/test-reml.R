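test_that("balanced one-way REML equals the ANOVA closed form", {
  for (seed in c(1, 2, 3, 10, 77)) {
    co <- toy_cohort(n = 12, k = 3, sd_b = 1.5, sd_w = 0.8, seed = seed)
    fit <- fit_oneway_random(co, "y", scale = "raw")
    mom <- anova_components(co)
    if (!fit$singular) {
      expect_equal(fit$components$sigma2_between, unname(mom["sigma2_b"]),
                   tolerance = 1e-8)
      expect_equal(fit$components$sigma2_within, unname(mom["sigma2_w"]),
                   tolerance = 1e-8)
    } else {
      expect_equal(unname(mom["sigma2_b"]), 0)
    }
  }
})

test_that("a negative moment solution is truncated to zero and flagged singular", {
  # within-noise dominates: between-subject MoM component goes negative
  co <- toy_cohort(n = 8, k = 3, sd_b = 0.001, sd_w = 2, seed = 2)
  fit <- fit_oneway_random(co, "y")
  mom <- anova_components(co)
  expect_equal(unname(mom["sigma2_b"]), 0)
  expect_true(fit$singular)
  expect_equal(fit$components$sigma2_between, 0)
  expect_equal(fit$icc, 0)
})

test_that("profile optimum beats a dense-matrix likelihood grid (oracle)", {
  co <- toy_cohort(n = 6, k = 3, sd_b = 1, sd_w = 0.5, seed = 4)
  fit <- fit_oneway_random(co, "y", scale = "raw")
  X <- cbind(rep(1, nrow(co)))
  sid <- as.integer(factor(co$subject))
  coarse <- seq(0.01, 100, by = 0.01)
  obj_c <- vapply(coarse, dense_reml_objective, numeric(1),
                  y = co$y, subject = sid, design = X)
  lam_hat <- fit$lambda
  fine <- seq(max(1e-4, lam_hat - 0.05), lam_hat + 0.05, by = 1e-4)
  obj_f <- vapply(fine, dense_reml_objective, numeric(1),
                  y = co$y, subject = sid, design = X)
  expect_gte(fit$reml_criterion, max(obj_c, obj_f) - 1e-9)
  expect_equal(lam_hat, coarse[which.max(obj_c)], tolerance = 0.02)
  expect_equal(lam_hat, fine[which.max(obj_f)], tolerance = 1e-3)
  # engine variance components agree with the grid argmax within 1e-6 relative
  sol_grid <- fine[which.max(obj_f)]
  expect_equal(lam_hat, sol_grid, tolerance = 1e-6 + 1e-4 / lam_hat)
})

test_that("adjusted model with one covariate matches a dense joint grid oracle", {
  set.seed(21)
  n <- 4; k <- 3
  x <- rnorm(n * k)
  y <- 1 + 0.7 * x + rep(rnorm(n, 0, 1), each = k) + rnorm(n * k, 0, 0.6)
  co <- tibble::tibble(subject = rep(letters[1:n], each = k),
                       visit = rep(1:k, n), y = y, x = x)
  fit <- fit_mixed_covariates(co, "y", covariates = "x", scale = "raw")
  X <- cbind(1, x)
  sid <- as.integer(factor(co$subject))
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 40001))
  obj <- vapply(grid, dense_reml_objective, numeric(1),
                y = y, subject = sid, design = X)
  expect_gte(fit$reml_criterion, max(obj) - 1e-8)
  lam_star <- grid[which.max(obj)]
  expect_equal(fit$lambda, lam_star, tolerance = 1e-3)
  # beta at the optimum agrees with the oracle GLS within 1e-5
  Z <- outer(sid, 1:n, "==") * 1
  V <- diag(n * k) + fit$lambda * tcrossprod(Z)
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_equal(unname(fit$fixed_effects), unname(drop(beta_gls)), tolerance = 1e-5)
})

test_that("REML fits agree with lme4 on crude and adjusted models", {
  skip_if_not_installed("lme4")
  co <- generate_cohort(synthetic_spec(n_subjects = 20, seed = 31))
  d <- data.frame(y = log(co$uric_acid), s = co$subject,
                  bmi = co$bmi, pal = co$pal)

  fit <- fit_oneway_random(co, "uric_acid", scale = "log")
  m <- lme4::lmer(y ~ 1 + (1 | s), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(fit$components$sigma2_between, vc[1], tolerance = 1e-6)
  expect_equal(fit$components$sigma2_within, vc[2], tolerance = 1e-6)

  adj <- fit_mixed_covariates(co, "uric_acid", c("bmi", "pal"), scale = "log")
  m2 <- lme4::lmer(y ~ bmi + pal + (1 | s), d, REML = TRUE)
  vc2 <- as.data.frame(lme4::VarCorr(m2))$vcov
  expect_equal(adj$components$sigma2_between, vc2[1], tolerance = 1e-6)
  expect_equal(adj$components$sigma2_within, vc2[2], tolerance = 1e-6)
  expect_equal(unname(adj$fixed_effects),
               unname(lme4::fixef(m2)), tolerance = 1e-6)
})

test_that("record order never changes the estimates", {
  co <- generate_cohort(synthetic_spec(n_subjects = 15, seed = 9))
  fit1 <- fit_oneway_random(co, "lutein", scale = "log")
  set.seed(1)
  co2 <- co[sample(nrow(co)), ]
  fit2 <- fit_oneway_random(co2, "lutein", scale = "log")
  expect_equal(fit1$components, fit2$components)
  expect_equal(fit1$icc, fit2$icc)
})

test_that("degenerate inputs behave as documented", {
  # repeats identical within subject, means differ: ICC -> 1
  co <- tibble::tibble(subject = rep(letters[1:5], each = 3),
                       visit = rep(1:3, 5),
                       y = rep(c(3, 7, 12, 20, 33), each = 3))
  fit <- fit_oneway_random(co, "y")
  expect_equal(fit$icc, 1)
  expect_equal(fit$components$sigma2_within, 0)

  # all values identical: singular by convention, ICC 0
  co$y <- 5
  fit0 <- fit_oneway_random(co, "y")
  expect_true(fit0$singular)
  expect_equal(fit0$icc, 0)

  # one visit per subject: within variance unidentifiable
  solo <- tibble::tibble(subject = letters[1:6], visit = 1L, y = rnorm(6))
  expect_error(fit_oneway_random(solo, "y"), "unidentifiable")

  expect_error(fit_oneway_random(dplyr::mutate(co, y = NA_real_), "y"),
               "missing")
})

test_that("constant covariates reduce the adjusted fit to the crude fit", {
  co <- generate_cohort(synthetic_spec(n_subjects = 12, seed = 6))
  co$flat <- 3.3
  crude <- fit_oneway_random(co, "retinol", scale = "log")
  adj <- suppressMessages(
    fit_mixed_covariates(co, "retinol", "flat", scale = "log"))
  expect_equal(adj$components$sigma2_between,
               crude$components$sigma2_between, tolerance = 1e-8)
  expect_equal(adj$components$sigma2_within,
               crude$components$sigma2_within, tolerance = 1e-8)
})

test_that("collinear covariates raise an error naming the columns", {
  co <- generate_cohort(synthetic_spec(n_subjects = 10, seed = 14))
  co$bmi2 <- 2 * co$bmi
  expect_error(fit_mixed_covariates(co, "retinol", c("bmi", "bmi2"),
                                    scale = "log"),
               "collinear.*bmi2")
})

test_that("adjusting for a true between-subject covariate effect shrinks sigma2_between", {
  shrunk <- vapply(1:60, function(s) {
    spec <- synthetic_spec(
      biomarkers = tibble::tibble(name = "m", mu = 100, cv_g = 0.25,
                                  cv_t = 0.12, lognormal = TRUE),
      n_subjects = 44,
      covariate_distributions = list(contraceptive = list(p = 0.5)),
      covariate_effects = list(contraceptive = sigma_from_cv(0.25)),
      seed = s)
    co <- generate_cohort(spec)
    crude <- fit_oneway_random(co, "m", scale = "log")
    adj <- fit_mixed_covariates(co, "m", "contraceptive", scale = "log")
    adj$components$sigma2_between < crude$components$sigma2_between
  }, logical(1))
  expect_gte(mean(shrunk), 0.95)
})

test_that("icc_from_components handles boundaries and bad input", {
  expect_equal(icc_from_components(list(sigma2_between = 2, sigma2_within = 2)), 0.5)
  expect_equal(icc_from_components(list(sigma2_between = 3, sigma2_within = 0)), 1)
  expect_equal(icc_from_components(list(sigma2_between = 0, sigma2_within = 0,
                                        singular = TRUE)), 0)
  expect_error(icc_from_components(list(sigma2_between = 0, sigma2_within = 0)),
               "zero")
  expect_error(icc_from_components(list(sigma2_between = -1, sigma2_within = 1)),
               "non-negative")
})

test_that("bootstrap CI is deterministic, clipped, and degenerate-safe", {
  co <- generate_cohort(one_marker_spec(0.3, 0.15, n_subjects = 20, seed = 3))
  b1 <- bootstrap_icc_ci(co, "marker", scale = "log", B = 100, seed = 11)
  b2 <- bootstrap_icc_ci(co, "marker", scale = "log", B = 100, seed = 11)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_equal(b1$ci_high, b2$ci_high)
  expect_true(b1$ci_low >= 0 && b1$ci_high <= 1 && b1$ci_low <= b1$ci_high)

  # identical repeats within subject, distinct means: every replicate ICC = 1
  dg <- tibble::tibble(subject = rep(letters[1:6], each = 3),
                       visit = rep(1:3, 6),
                       y = rep(c(3, 7, 12, 20, 33, 41), each = 3))
  bd <- bootstrap_icc_ci(dg, "y", B = 50, seed = 2)
  expect_equal(c(bd$ci_low, bd$ci_high), c(1, 1))
})

test_that("iterative residual exclusion removes an injected aberrant subject", {
  hits <- vapply(1:200, function(s) {
    co <- generate_cohort(one_marker_spec(0.3, 0.1, n_subjects = 30, seed = s))
    # +6 within-subject SD shift on one visit of subject 5; detection is
    # near-certain but not sure-fire at this shift size
    sw <- sigma_from_cv(0.1)
    i <- which(co$subject == "S005" & co$visit == 2)
    co$marker[i] <- co$marker[i] * exp(6 * sw)
    res <- iterative_residual_exclusion(co, "marker", scale = "log", cutoff = 2)
    "S005" %in% res$report$subject
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("residual exclusion decreases the within-subject variance under injection", {
  co <- generate_cohort(one_marker_spec(0.3, 0.1, n_subjects = 30, seed = 44))
  sw <- sigma_from_cv(0.1)
  i <- which(co$subject == "S010" & co$visit == 3)
  co$marker[i] <- co$marker[i] * exp(6 * sw)
  before <- fit_oneway_random(co, "marker", scale = "log")
  res <- iterative_residual_exclusion(co, "marker", scale = "log", cutoff = 2)
  expect_lt(res$fit$components$sigma2_within, before$components$sigma2_within)
})

test_that("residual exclusion with nothing outlying is a no-op", {
  co <- toy_cohort(n = 10, seed = 2)
  fit <- fit_oneway_random(co, "y")
  capped <- iterative_residual_exclusion(co, "y", cutoff = 1e6)
  expect_equal(nrow(capped$report), 0L)
  expect_equal(capped$fit$components, fit$components)
})

test_that("tidy and glance expose the fit in broom shape", {
  co <- generate_cohort(synthetic_spec(n_subjects = 10, seed = 18))
  fit <- fit_mixed_covariates(co, "lycopene", c("bmi"), scale = "log")
  td <- tidy(fit)
  expect_setequal(td$term[td$effect == "fixed"], c("(Intercept)", "bmi"))
  expect_setequal(td$term[td$effect == "ran_pars"],
                  c("sigma2_between", "sigma2_within"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$icc, fit$icc)
})
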