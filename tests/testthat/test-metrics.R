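test_that("lognormal CV/sigma conversions are exact inverses", {
  expect_equal(sigma_from_cv(0), 0)
  expect_equal(sigma_from_cv(0.113), sqrt(log(0.113^2 + 1)))
  for (x in seq(0, 2, by = 0.1))
    expect_equal(cv_from_sigma(sigma_from_cv(x)), x, tolerance = 1e-12)
  expect_error(sigma_from_cv(-0.1), "non-negative")
})

test_that("CVs from variance components follow the lognormal and raw rules", {
  log_vc <- list(sigma2_between = 0.01, sigma2_within = 0.01, scale = "log")
  cv <- cv_from_components(log_vc)
  expect_equal(unname(cv["cv_g"]), sqrt(exp(0.01) - 1))
  expect_equal(unname(cv["cv_t"]), sqrt(exp(0.01) - 1))

  singular <- list(sigma2_between = 0, sigma2_within = 0.005, scale = "log")
  expect_equal(unname(cv_from_components(singular)["cv_g"]), 0)

  raw <- list(sigma2_between = 4, sigma2_within = (0.1 * 50)^2,
              scale = "raw", grand_mean = 50)
  expect_equal(unname(cv_from_components(raw)["cv_t"]), 0.1)
  raw$grand_mean <- 0
  expect_error(cv_from_components(raw), "grand mean")
})

test_that("index of individuality reproduces published table cells", {
  expect_equal(round(index_of_individuality(0.217, 0.617)$ii, 3), 0.352)
  # some printed II cells reflect unrounded CVs; agreement to ~2e-3 here
  expect_equal(index_of_individuality(0.266, 0.547)$ii, 0.487, tolerance = 2e-3)
  expect_true(is.na(index_of_individuality(0.07, 0)$ii))
  expect_identical(index_of_individuality(0.07, 0)$class, "undefined")
  expect_equal(index_of_individuality(0.3, 0.3)$ii, 1)
  expect_identical(index_of_individuality(0.2, 0.617)$class, "marked_individuality")
  expect_identical(index_of_individuality(0.3, 0.2)$class, "low_individuality")
})

test_that("reference change values reproduce published table cells", {
  # symmetric: raw-scale biomarkers
  expect_equal(rcv_symmetric(0.161), 44.6, tolerance = 0.05)
  expect_equal(rcv_symmetric(0.062), 17.2, tolerance = 0.05)
  expect_equal(rcv_symmetric(0), 0)
  # asymmetric: lognormal biomarkers
  expect_equal(rcv_asymmetric(0.113), c(up = 36.6, down = -26.8),
               tolerance = 5e-3)
  expect_equal(rcv_asymmetric(0.310), c(up = 131.6, down = -56.8),
               tolerance = 5e-3)
  expect_equal(rcv_asymmetric(0.186), c(up = 66.7, down = -40.0),
               tolerance = 5e-3)
})

test_that("asymmetric RCV dominance and small-CV limit hold", {
  for (cv in c(0.01, 0.05, 0.1, 0.3, 0.8)) {
    r <- rcv_asymmetric(cv)
    expect_gt(r[["up"]], abs(r[["down"]]))
  }
  r <- rcv_asymmetric(0.01)
  s <- rcv_symmetric(0.01)
  # exp(x) - 1 deviates from x by ~x/2 relative: ~1.4% at this CV
  expect_equal(r[["up"]], s, tolerance = 0.015)
  expect_equal(abs(r[["down"]]), s, tolerance = 0.015)
})

test_that("attenuation-limiting measurement counts follow the 0.20 rounding rule", {
  # glutathione ICC 0.098 -> 83 and 37; beta-carotene 0.875 -> 2 and 1
  expect_equal(n_measurements(0.902, 0.098, 0.10), 83L)
  expect_equal(n_measurements(0.902, 0.098, 0.20), 37L)
  expect_equal(n_measurements(0.125, 0.875, 0.10), 2L)
  expect_equal(n_measurements(0.125, 0.875, 0.20), 1L)
  # exact integer: no rounding up
  expect_equal(n_measurements(0.5, 0.5, 0.10), 9L)
  # fractional excess at exactly 0.20 stays down; floor at one measurement
  expect_equal(n_measurements(0.2, 9, 0.10), 1L)
  expect_true(is.na(n_measurements(0.5, 0, 0.10)))
})

test_that("n_measurements decreases in ICC and in allowed attenuation", {
  iccs <- seq(0.05, 0.95, by = 0.05)
  n10 <- vapply(iccs, function(r) n_measurements(1 - r, r, 0.10), integer(1))
  n20 <- vapply(iccs, function(r) n_measurements(1 - r, r, 0.20), integer(1))
  expect_true(all(diff(n10) <= 0))
  expect_true(all(diff(n20) <= 0))
  expect_true(all(n20 <= n10))
})

test_that("ICC reliability bands match the published cutoffs", {
  expect_identical(icc_category(0.875), "very_good")
  expect_identical(icc_category(0.75), "very_good")
  expect_identical(icc_category(0.6), "good")
  expect_identical(icc_category(0.51), "good")
  expect_identical(icc_category(0.40), "fair")
  expect_identical(icc_category(0.098), "poor")
  expect_warning(cls <- icc_category(0.505), "unassigned")
  expect_identical(cls, "fair")
})

test_that("ICC sample-size formula reproduces the published planning numbers", {
  res <- icc_sample_size(rho1 = 0.30, rho0 = 0, k = 3, alpha = 0.05,
                         tails = 2, power = 0.80, dropout = 0.20)
  expect_equal(res$n_required, 36L)
  expect_equal(res$n_raw, 35.46, tolerance = 2e-3)
  expect_equal(res$n_with_dropout, 44L)
  expect_error(icc_sample_size(0.2, 0.3, k = 3), "exceed")
})

test_that("simulated power of the planned design reaches its nominal level", {
  pow <- icc_power_sim(n = 36, k = 3, rho = 0.30, nsim = 2000, seed = 7)
  expect_gte(pow, 0.80)
})
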