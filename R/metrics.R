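#' Lognormal conversion between CVs and log-scale SDs
#'
#' For a lognormally distributed biomarker the coefficient of variation on
#' the original scale and the standard deviation on the natural-log scale
#' are linked by `sigma = sqrt(ln(cv^2 + 1))` and its inverse
#' `cv = sqrt(exp(sigma^2) - 1)`; the two functions are exact inverses.
#'
#' @param cv Coefficient of variation as a fraction (0.113 for 11.3%).
#' @param sigma Standard deviation on the log scale.
#' @return `sigma_from_cv()` the log-scale SD; `cv_from_sigma()` the CV.
#' @export
#' @examples
#' sigma_from_cv(0.113)
#' cv_from_sigma(sigma_from_cv(0.113))
sigma_from_cv <- function(cv) {
  if (any(cv < 0)) abort("`cv` must be non-negative.")
  sqrt(log(cv^2 + 1))
}

#' @rdname sigma_from_cv
#' @export
cv_from_sigma <- function(sigma) {
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  sqrt(exp(sigma^2) - 1)
}

#' Coefficients of variation from variance components
#'
#' Converts fitted between- and within-subject variance components to the
#' inter-individual (`cv_g`) and total intra-individual (`cv_t`) CVs on the
#' original measurement scale. On the log scale each component's SD passes
#' through the lognormal relation `cv = sqrt(exp(sigma^2) - 1)`; on the raw
#' scale `cv = sqrt(component) / grand mean`.
#'
#' @param vc Variance components: a list with `sigma2_between`,
#'   `sigma2_within`, `scale` (`"log"` or `"raw"`) and, for the raw scale,
#'   `grand_mean` (a `biovar_fit$components` works directly).
#' @return Named numeric vector `c(cv_g =, cv_t =)` as fractions.
#' @export
cv_from_components <- function(vc) {
  stopifnot(vc$sigma2_between >= 0, vc$sigma2_within >= 0)
  if (identical(vc$scale, "log")) {
    c(cv_g = cv_from_sigma(sqrt(vc$sigma2_between)),
      cv_t = cv_from_sigma(sqrt(vc$sigma2_within)))
  } else {
    if (is.null(vc$grand_mean) || vc$grand_mean <= 0)
      abort("raw-scale CV needs a positive grand mean.")
    c(cv_g = sqrt(vc$sigma2_between) / vc$grand_mean,
      cv_t = sqrt(vc$sigma2_within) / vc$grand_mean)
  }
}

#' Index of individuality
#'
#' Ratio of the total intra-individual to the inter-individual CV. Values
#' below 0.6 indicate marked individuality — population-based reference
#' intervals are then insensitive to individual change and the reference
#' change value is the better yardstick; values above 1.4 indicate low
#' individuality. Undefined (NA) when `cv_g` is zero.
#'
#' @param cv_t,cv_g Total intra-individual and inter-individual CVs
#'   (fractions).
#' @return List with `ii` (fraction or `NA`) and `class`
#'   (`"marked_individuality"`, `"intermediate"`, `"low_individuality"`, or
#'   `"undefined"`).
#' @export
#' @examples
#' index_of_individuality(0.217, 0.617) # 0.352, marked individuality
index_of_individuality <- function(cv_t, cv_g) {
  if (cv_t < 0 || cv_g < 0) abort("CVs must be non-negative.")
  if (cv_g == 0) return(list(ii = NA_real_, class = "undefined"))
  ii <- cv_t / cv_g
  cls <- if (ii < 0.6) "marked_individuality"
         else if (ii > 1.4) "low_individuality"
         else "intermediate"
  list(ii = ii, class = cls)
}

#' Reference change values
#'
#' The minimal percentage difference between two serial measurements in the
#' same individual that exceeds inherent variation at the probability set by
#' `z` (1.96 for the bidirectional 95% level). On the raw scale the RCV is
#' symmetric, `± z * sqrt(2) * cv_t * 100` percent. Under the lognormal
#' model it is asymmetric: `up = (exp(+z sqrt(2) sigma) - 1) * 100` and
#' `down = (exp(-z sqrt(2) sigma) - 1) * 100` with
#' `sigma = sqrt(ln(cv_t^2 + 1))`.
#'
#' @param cv_t Total intra-individual CV (fraction).
#' @param z Probability multiplier.
#' @return `rcv_symmetric()`: the half-width in percent.
#'   `rcv_asymmetric()`: named vector `c(up =, down =)` in percent (down is
#'   negative).
#' @export
#' @examples
#' rcv_symmetric(0.161)   # ±44.6%
#' rcv_asymmetric(0.113)  # +36.6%, -26.8%
rcv_symmetric <- function(cv_t, z = 1.96) {
  stopifnot(cv_t >= 0, z > 0)
  z * sqrt(2) * cv_t * 100
}

#' @rdname rcv_symmetric
#' @export
rcv_asymmetric <- function(cv_t, z = 1.96) {
  stopifnot(cv_t >= 0, z > 0)
  s <- sigma_from_cv(cv_t)
  c(up = (exp(z * sqrt(2) * s) - 1) * 100,
    down = (exp(-z * sqrt(2) * s) - 1) * 100)
}

#' Measurements needed to limit regression-dilution attenuation
#'
#' Number of repeated measurements per subject required so that the
#' attenuation of a regression coefficient using the biomarker as exposure
#' stays within the chosen fraction:
#' `n = [P / (1 - P)] * (S_w^2 / S_b^2)` with `P = 1 - attenuation`.
#' The raw value is rounded up to the next integer only when it exceeds the
#' lower integer by more than 0.20, and floored at one measurement;
#' undefined (NA) when the between-subject variance is zero.
#'
#' @param s_w2,s_b2 Within- and between-subject variance components (any
#'   common scale; only the ratio matters, so `(1 - ICC)` and `ICC` work).
#' @param attenuation Maximum allowed attenuation as a fraction in (0, 1),
#'   e.g. 0.10 or 0.20.
#' @return Integer count, or `NA` when undefined.
#' @export
#' @examples
#' n_measurements(1 - 0.098, 0.098, 0.10) # 83
#' n_measurements(1 - 0.875, 0.875, 0.10) # 2
n_measurements <- function(s_w2, s_b2, attenuation) {
  stopifnot(s_w2 >= 0, s_b2 >= 0, attenuation > 0, attenuation < 1)
  if (s_b2 == 0) return(NA_integer_)
  p <- 1 - attenuation
  raw <- (p / (1 - p)) * (s_w2 / s_b2)
  base <- floor(raw)
  n <- if (raw - base > 0.20) base + 1 else base
  max(as.integer(n), 1L)
}

#' Qualitative reliability band of an ICC
#'
#' `>= 0.75` very good, `0.51-0.74` good, `0.40-0.50` fair, `< 0.40` poor.
#' The published bands leave (0.50, 0.51) unassigned; such values fall into
#' `fair` with a warning.
#'
#' @param icc ICC in `[0, 1]`.
#' @return One of `"very_good"`, `"good"`, `"fair"`, `"poor"`.
#' @export
icc_category <- function(icc) {
  stopifnot(icc >= 0, icc <= 1)
  if (icc >= 0.75) return("very_good")
  if (icc >= 0.51) return("good")
  if (icc >= 0.40) {
    if (icc > 0.50) warn("ICC in the unassigned band (0.50, 0.51); classified as fair.")
    return("fair")
  }
  "poor"
}

#' Sample size for detecting an ICC
#'
#' Walter–Eliasziw–Donner formula based on the Fisher-type transform of the
#' one-way ICC:
#' `n = 1 + 2k (z_a + z_b)^2 / [(k - 1) (ln C)^2]` with
#' `C = (1 + k theta_1) / (1 + k theta_0)`, `theta = rho / (1 - rho)`,
#' rounded up; an optional dropout rate inflates the result
#' multiplicatively, `ceil(n (1 + dropout))`.
#'
#' @param rho1 ICC to detect, in (0, 1).
#' @param rho0 Null ICC, in `[0, rho1)`.
#' @param k Repeated measurements per subject, at least 2.
#' @param alpha Type-1 error probability.
#' @param tails 1 or 2.
#' @param power Target power in (0, 1).
#' @param dropout Anticipated dropout fraction in `[0, 1)`.
#' @return List with `n_required`, `n_with_dropout` and the unrounded
#'   `n_raw`.
#' @export
#' @examples
#' icc_sample_size(rho1 = 0.30, k = 3, dropout = 0.20) # 36, 44 with dropout
icc_sample_size <- function(rho1, rho0 = 0, k, alpha = 0.05, tails = 2,
                            power = 0.80, dropout = 0) {
  if (rho1 <= rho0) abort("`rho1` must exceed `rho0`.")
  stopifnot(rho1 < 1, rho0 >= 0, k >= 2, alpha > 0, alpha < 1,
            tails %in% c(1, 2), power > 0, power < 1,
            dropout >= 0, dropout < 1)
  theta1 <- rho1 / (1 - rho1)
  theta0 <- rho0 / (1 - rho0)
  cc <- (1 + k * theta1) / (1 + k * theta0)
  za <- qnorm(1 - alpha / tails)
  zb <- qnorm(power)
  n_raw <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(cc)^2)
  n_req <- ceiling(n_raw)
  list(n_required = as.integer(n_req),
       n_with_dropout = as.integer(ceiling(n_req * (1 + dropout))),
       n_raw = n_raw)
}

#' Simulated power of the one-way ANOVA ICC test
#'
#' Monte-Carlo check of the analytic sample-size formula: simulates one-way
#' random-effect cohorts at a true ICC and counts rejections of the
#' `ICC = rho0` one-way F test.
#'
#' @param n Subjects per cohort.
#' @param k Measurements per subject.
#' @param rho True ICC generating the data.
#' @param rho0 Null ICC of the F test.
#' @param alpha Two-sided type-1 error probability (upper-tail test at
#'   `alpha/2` mirrors the two-sided formula).
#' @param nsim Number of simulated cohorts.
#' @param seed Integer seed.
#' @return Estimated power (fraction of rejections).
#' @export
icc_power_sim <- function(n, k, rho, rho0 = 0, alpha = 0.05, nsim = 2000L,
                          seed = 1L) {
  stopifnot(rho > rho0, rho < 1)
  set.seed(seed)
  crit <- qf(1 - alpha / 2, n - 1, n * (k - 1))
  ratio0 <- (1 + k * rho0 / (1 - rho0))
  rej <- 0L
  for (s in seq_len(nsim)) {
    b <- rnorm(n, 0, sqrt(rho))
    y <- rep(b, each = k) + rnorm(n * k, 0, sqrt(1 - rho))
    g <- rep(seq_len(n), each = k)
    m <- tapply(y, g, mean)
    msb <- k * sum((m - mean(y))^2) / (n - 1)
    msw <- sum((y - m[g])^2) / (n * (k - 1))
    if (msb / msw / ratio0 > crit) rej <- rej + 1L
  }
  rej / nsim
}
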