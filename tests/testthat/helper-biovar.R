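# small fixture builders shared across the suite

# single-biomarker spec at chosen CV magnitudes
one_marker_spec <- function(cv_g, cv_t, n_subjects = 44, n_visits = 3,
                            lognormal = TRUE, seed = 1, mu = 100,
                            outliers = list()) {
  synthetic_spec(
    biomarkers = tibble::tibble(name = "marker", mu = mu, cv_g = cv_g,
                                cv_t = cv_t, lognormal = lognormal),
    n_subjects = n_subjects, n_visits = n_visits,
    covariate_distributions = list(), outliers = outliers, seed = seed)
}

# balanced toy cohort straight from normal draws
toy_cohort <- function(n = 6, k = 3, sd_b = 1, sd_w = 0.5, seed = 42,
                       mu = 10) {
  set.seed(seed)
  tibble::tibble(
    subject = rep(sprintf("S%02d", 1:n), each = k),
    visit = rep(1:k, times = n),
    y = mu + rep(rnorm(n, 0, sd_b), each = k) + rnorm(n * k, 0, sd_w))
}

# one-way ANOVA method-of-moments variance components (balanced design)
anova_components <- function(data, value = "y") {
  y <- data[[value]]
  g <- data$subject
  k <- as.integer(table(g))[1]
  m <- tapply(y, g, mean)
  n <- length(m)
  msb <- k * sum((m - mean(y))^2) / (n - 1)
  msw <- sum((y - m[g])^2) / (n * (k - 1))
  c(sigma2_b = max(0, (msb - msw) / k), sigma2_w = msw)
}

# vectorized row maximum (fast path for large Monte-Carlo matrices)
row_max <- function(m) do.call(pmax, as.data.frame(m))

# dense-matrix restricted-likelihood criterion, an independent oracle for the
# profile engine (explicit V, determinants via chol of the full matrices)
dense_reml_objective <- function(lambda, y, subject, design) {
  X <- design
  Z <- outer(subject, sort(unique(subject)), "==") * 1
  V <- diag(length(y)) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rVr <- drop(t(r) %*% Vi %*% r)
  np <- length(y) - ncol(X)
  as.numeric(-0.5 * (np * (log(2 * pi * rVr / np) + 1) +
                       determinant(V)$modulus + determinant(A)$modulus))
}
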