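test_that("generation is deterministic and substream-isolated", {
  spec <- synthetic_spec(n_subjects = 10, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # dropping biomarkers from the panel leaves the remaining columns untouched
  small <- synthetic_spec(biomarkers = default_panel()[c(2, 8), ],
                          n_subjects = 10, seed = 123)
  c2 <- generate_cohort(small)
  expect_identical(c2$uric_acid, a$uric_acid)
  expect_identical(c2$beta_carotene, a$beta_carotene)
  expect_identical(c2$bmi, a$bmi)
})

test_that("zero within-subject CV gives identical repeats per subject", {
  co <- generate_cohort(one_marker_spec(0.3, 0, n_subjects = 6, seed = 5))
  spread <- tapply(co$marker, co$subject, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("true_params reports the analysis-scale ICC", {
  expect_equal(true_params(one_marker_spec(0.2, 0.2))$icc, 0.5)
  expect_equal(true_params(one_marker_spec(0.3, 0))$icc, 1)
  tp <- true_params(one_marker_spec(0.617, 0.217))
  expect_equal(tp$icc,
               log(1 + 0.617^2) / (log(1 + 0.617^2) + log(1 + 0.217^2)),
               tolerance = 1e-12)
  expect_equal(tp$icc, 0.875, tolerance = 2e-3)
  # normal-scale marker: relative variances
  tpn <- true_params(one_marker_spec(0.3, 0.3, lognormal = FALSE))
  expect_equal(tpn$icc, 0.5)
})

test_that("true ICC strictly decreases as within-subject CV grows", {
  iccs <- vapply(seq(0.05, 0.8, by = 0.05),
                 function(cvt) true_params(one_marker_spec(0.4, cvt))$icc,
                 numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("a large cohort recovers the specified CVs through the estimator", {
  spec <- one_marker_spec(0.617, 0.217, n_subjects = 5000, seed = 2024)
  co <- generate_cohort(spec)
  fit <- fit_oneway_random(co, "marker", scale = "log")
  cv <- cv_from_components(fit$components)
  expect_equal(unname(cv["cv_g"]), 0.617, tolerance = 0.02)
  expect_equal(unname(cv["cv_t"]), 0.217, tolerance = 0.02)
})

test_that("outlier injection changes only the targeted subject", {
  spec <- one_marker_spec(0.3, 0.15, n_subjects = 8, seed = 10,
                          outliers = list(list(subject = 2,
                                               kind = "variance_inflation",
                                               magnitude = 10)))
  clean <- generate_cohort(one_marker_spec(0.3, 0.15, n_subjects = 8, seed = 10))
  dirty <- generate_cohort(spec)
  other <- dirty$subject != "S002"
  expect_identical(dirty$marker[other], clean$marker[other])
  v <- tapply(dirty$marker, dirty$subject, var)
  expect_identical(names(which.max(v)), "S002")

  # empty injection list is the identity
  expect_identical(as.data.frame(inject_outliers(clean, one_marker_spec(0.3, 0.15))),
                   as.data.frame(clean))
  expect_error(inject_outliers(clean, one_marker_spec(
    0.3, 0.15, outliers = list(list(subject = 99, kind = "mean_shift",
                                    magnitude = 2)))),
    "unknown subject")
})

test_that("a mean-shifted subject is flagged by Reed's criterion downstream", {
  spec <- one_marker_spec(0.3, 0.1, n_subjects = 20, seed = 3,
                          outliers = list(list(subject = 4, kind = "mean_shift",
                                               magnitude = 10)))
  co <- generate_cohort(spec)
  means <- tapply(co$marker, co$subject, mean)
  flagged <- reed_outliers(as.numeric(means))
  expect_true("S004" %in% names(means)[flagged])
})

test_that("estimated crude ICC is nearly unbiased at the study scale", {
  # 44 subjects x 3 visits; moderate replicate count per truth keeps the
  # routine suite quick — the acceptance suite runs the full 500
  for (target in c(0.3, 0.7)) {
    cv_t <- 0.2
    vw <- log(1 + cv_t^2)
    vg <- target * vw / (1 - target)
    cv_g <- sqrt(exp(vg) - 1)
    est <- vapply(1:120, function(s) {
      co <- generate_cohort(one_marker_spec(cv_g, cv_t, seed = s))
      fit_oneway_random(co, "marker", scale = "log")$icc
    }, numeric(1))
    expect_lt(abs(mean(est) - target), 0.05)
  }
})

test_that("invalid specs are rejected", {
  expect_error(one_marker_spec(-0.1, 0.2), "cv_g")
  expect_error(synthetic_spec(n_subjects = 1), "n_subjects")
  expect_error(one_marker_spec(0.3, 0.1, outliers = list(
    list(subject = 1, kind = "variance_inflation", magnitude = 0.5))),
    "exceed 1")
  expect_error(one_marker_spec(0.3, 0.1, outliers = list(
    list(subject = 1, kind = "typo", magnitude = 2))), "unknown outlier kind")
})

test_that("YAML spec roundtrip preserves the generating process", {
  spec <- one_marker_spec(0.4, 0.2, n_subjects = 7, seed = 55)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    biomarkers = list(list(name = "marker", mu = 100, cv_g = 0.4,
                           cv_t = 0.2, lognormal = TRUE)),
    n_subjects = 7, n_visits = 3,
    covariate_distributions = list(), seed = 55), path)
  spec2 <- read_synthetic_spec(path)
  expect_identical(as.data.frame(generate_cohort(spec2)),
                   as.data.frame(generate_cohort(spec)))
})
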