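# ---- profile-REML engine for the random-intercept model ---------------------
#
# y = X beta + Z b + e,  b_i ~ N(0, lambda sigma2_w),  e ~ N(0, sigma2_w I).
# For fixed lambda the covariance is block diagonal V_i = I + lambda J, so
#   V_i^-1 = I - (lambda / (1 + n_i lambda)) J,  log|V_i| = log(1 + n_i lambda),
# and everything reduces to per-subject sums: with S_x = rowsum(X), S_y =
# rowsum(y), c_i = lambda / (1 + n_i lambda),
#   X'V^-1X = X'X - S_x' diag(c) S_x,  X'V^-1y = X'y - S_x' (c S_y),
#   y'V^-1y = y'y - sum(c S_y^2).
# The restricted likelihood is profiled over beta (GLS) and sigma2_w, leaving
# a 1-D criterion in log(lambda) maximized by Brent search; the lambda = 0
# boundary (singular fit) is evaluated exactly and kept when it wins.

reml_objective <- function(loglam, pre) {
  lam <- exp(loglam)
  c_i <- lam / (1 + pre$n_i * lam)
  A <- pre$XtX - crossprod(pre$Sx, pre$Sx * c_i)
  b <- pre$Xty - crossprod(pre$Sx, c_i * pre$Sy)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  yVy <- pre$yty - sum(c_i * pre$Sy^2)
  rVr <- max(yVy - sum(beta * b), 0)
  np <- pre$n - pre$p
  if (rVr <= 0) return(Inf)
  ll <- -0.5 * (np * (log(2 * pi * rVr / np) + 1) +
                  sum(log1p(pre$n_i * lam)) + 2 * sum(log(diag(ch))))
  ll
}

reml_solution <- function(loglam, pre) {
  lam <- exp(loglam)
  c_i <- lam / (1 + pre$n_i * lam)
  A <- pre$XtX - crossprod(pre$Sx, pre$Sx * c_i)
  b <- pre$Xty - crossprod(pre$Sx, c_i * pre$Sy)
  beta <- solve(A, b)
  yVy <- pre$yty - sum(c_i * pre$Sy^2)
  rVr <- max(yVy - sum(beta * b), 0)
  sigma2_w <- rVr / (pre$n - pre$p)
  list(lambda = lam, beta = drop(beta), sigma2_w = sigma2_w,
       sigma2_b = lam * sigma2_w, objective = reml_objective(loglam, pre))
}

# analytic score of the profiled restricted likelihood in lambda; with
# W_i = 1/(1 + n_i lambda), t_i the subject sums of GLS residuals:
#   d(-2 l_R)/d lambda = -(n-p) sum(W^2 t^2)/rVr + sum(n W) - sum(W^2 s'A^-1 s)
reml_score <- function(loglam, pre) {
  lam <- exp(loglam)
  W <- 1 / (1 + pre$n_i * lam)
  c_i <- lam * W
  A <- pre$XtX - crossprod(pre$Sx, pre$Sx * c_i)
  b <- pre$Xty - crossprod(pre$Sx, c_i * pre$Sy)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NA_real_)
  t_i <- pre$Sy - drop(pre$Sx %*% beta)
  rVr <- pre$yty - sum(c_i * pre$Sy^2) - sum(beta * b)
  if (rVr <= 0) return(NA_real_)
  SAS <- rowSums((pre$Sx %*% solve(A)) * pre$Sx)
  g <- -(pre$n - pre$p) * sum(W^2 * t_i^2) / rVr + sum(pre$n_i * W) -
    sum(W^2 * SAS)
  -g  # sign flipped: positive score means the likelihood still increases
}

# Brent locates the optimum to ~sqrt(eps); root-finding on the analytic score
# sharpens it to near machine precision (needed for the ANOVA-equality
# guarantee on balanced data)
reml_polish <- function(loglam, pre, span = 0.05) {
  lo <- loglam - span; hi <- loglam + span
  g_lo <- reml_score(lo, pre); g_hi <- reml_score(hi, pre)
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) return(loglam)
  uniroot(reml_score, c(lo, hi), pre = pre, tol = 1e-14)$root
}

# precompute sufficient statistics; subject must be an integer index 1..q
reml_precompute <- function(y, subject_idx, X) {
  q <- max(subject_idx)
  list(n = length(y), p = ncol(X), q = q,
       n_i = as.numeric(rowsum(rep(1, length(y)), subject_idx)[, 1]),
       Sx = rowsum(X, subject_idx),
       Sy = as.numeric(rowsum(y, subject_idx)[, 1]),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2))
}

# fit the random-intercept model from raw vectors; the workhorse behind the
# exported fitting functions and the bootstrap (which bypasses data frames)
reml_engine <- function(y, subject_idx, X, lower = log(1e-10), upper = log(1e10)) {
  pre <- reml_precompute(y, subject_idx, X)
  if (pre$n - pre$p <= 0) abort("not enough observations for REML.")
  if (all(pre$n_i < 2)) abort("within-subject variance unidentifiable: no subject has repeated visits.")
  # degenerate: no variance anywhere
  mu_ols <- tryCatch(solve(pre$XtX, pre$Xty), error = function(e) NULL)
  if (is.null(mu_ols)) abort("rank-deficient fixed-effect design.")
  tss <- pre$yty - sum(mu_ols * pre$Xty)
  if (tss <= max(1e-24, 1e-18 * pre$yty)) {
    return(list(lambda = 0, beta = drop(mu_ols), sigma2_w = 0, sigma2_b = 0,
                objective = NA_real_, singular = TRUE, degenerate = TRUE,
                pre = pre))
  }
  # zero within-subject scatter: likelihood unbounded in lambda, ICC -> 1
  ybar_i <- pre$Sy / pre$n_i
  ssw <- pre$yty - sum(pre$n_i * ybar_i^2)
  if (ssw <= max(1e-24, 1e-15 * tss)) {
    r_i <- ybar_i - drop(pre$Sx %*% mu_ols) / pre$n_i
    vb <- sum(r_i^2) / max(pre$q - pre$p, 1)
    return(list(lambda = Inf, beta = drop(mu_ols), sigma2_w = 0,
                sigma2_b = vb, objective = NA_real_, singular = FALSE,
                degenerate = FALSE, pre = pre))
  }
  opt <- optimize(reml_objective, c(lower, upper), pre = pre,
                  maximum = TRUE, tol = 1e-10)
  loglam_hat <- reml_polish(opt$maximum, pre)
  sol_in <- reml_solution(loglam_hat, pre)
  # exact boundary lambda = 0: OLS
  rVr0 <- tss
  np <- pre$n - pre$p
  obj0 <- -0.5 * (np * (log(2 * pi * rVr0 / np) + 1) +
                    2 * sum(log(diag(chol(pre$XtX)))))
  if (obj0 >= sol_in$objective - 1e-10 || sol_in$lambda <= 1.01e-10) {
    sol <- list(lambda = 0, beta = drop(mu_ols), sigma2_w = rVr0 / np,
                sigma2_b = 0, objective = obj0)
    singular <- TRUE
  } else {
    sol <- sol_in
    singular <- FALSE
  }
  c(sol, list(singular = singular, degenerate = FALSE, pre = pre))
}

# conditional residuals: (y - X beta - bhat_i) / sigma_w, bhat the BLUP
reml_residuals <- function(y, subject_idx, X, sol, type = "conditional") {
  r <- y - drop(X %*% sol$beta)
  n_i <- as.numeric(rowsum(rep(1, length(y)), subject_idx)[, 1])
  Sr <- as.numeric(rowsum(r, subject_idx)[, 1])
  bhat <- if (is.finite(sol$lambda)) sol$lambda * Sr / (1 + n_i * sol$lambda)
          else Sr / n_i
  if (type == "conditional") {
    e <- r - bhat[subject_idx]
    denom <- sqrt(sol$sigma2_w)
  } else {
    e <- r
    denom <- sqrt(sol$sigma2_w + sol$sigma2_b)
  }
  if (denom <= 0) return(list(std = rep(0, length(y)), blup = bhat))
  list(std = e / denom, blup = bhat)
}

# ---- exported fitting interface --------------------------------------------

#' Fit the crude one-way random-effects model
#'
#' Estimates the grand mean and the between-/within-subject variance
#' components of `y_ij = mu + b_i + e_ij` by restricted maximum likelihood
#' (1-D profile likelihood in the variance ratio, Brent search on the log
#' scale with the zero boundary evaluated exactly). For balanced data the
#' estimates coincide with the one-way ANOVA method-of-moments values when
#' those are non-negative; a negative between-subject solution is truncated
#' to zero and flagged singular.
#'
#' @param data Cohort tibble (long format, `subject` + `visit` + value
#'   columns).
#' @param biomarker Name of the biomarker column.
#' @param scale `"raw"` or `"log"` (natural log applied before fitting).
#' @param residual_type Standardization of the returned residuals:
#'   conditional (subject predictor removed, the default) or marginal.
#' @return An object of class `biovar_fit`: variance components
#'   (`sigma2_between`, `sigma2_within`), `grand_mean` (analysis scale),
#'   `fixed_effects`, a `residuals` tibble, `singular`, `scale`,
#'   `n_subjects_used`, `icc`, and the REML criterion value.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_subjects = 8, seed = 2))
#' fit <- fit_oneway_random(cohort, "uric_acid", scale = "log")
#' glance(fit)
fit_oneway_random <- function(data, biomarker, scale = c("raw", "log"),
                              residual_type = c("conditional", "marginal")) {
  scale <- match.arg(scale)
  residual_type <- match.arg(residual_type)
  fit_random_intercept(data, biomarker, covariates = character(),
                       scale = scale, residual_type = residual_type)
}

#' Fit the covariate-adjusted random-intercept model
#'
#' REML for `y_ij = x_ij' beta + b_i + e_ij`: fixed covariate effects plus a
#' random subject intercept, estimated by the same profile-likelihood engine
#' as [fit_oneway_random()] (generalized least squares for `beta` at each
#' candidate variance ratio). Subjects missing the biomarker or any covariate
#' at any visit are dropped listwise and reported.
#'
#' @inheritParams fit_oneway_random
#' @param covariates Character vector of covariate column names entering as
#'   fixed effects.
#' @return A `biovar_fit`; `fixed_effects` holds the intercept and one
#'   coefficient per covariate.
#' @export
fit_mixed_covariates <- function(data, biomarker, covariates,
                                 scale = c("raw", "log"),
                                 residual_type = c("conditional", "marginal")) {
  scale <- match.arg(scale)
  residual_type <- match.arg(residual_type)
  if (!length(covariates)) abort("no covariates supplied; use fit_oneway_random().")
  fit_random_intercept(data, biomarker, covariates = covariates,
                       scale = scale, residual_type = residual_type)
}

fit_random_intercept <- function(data, biomarker, covariates, scale,
                                 residual_type = "conditional") {
  if (!biomarker %in% names(data))
    abort(paste0("no biomarker column `", biomarker, "`."))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov))
    abort(paste0("covariate column(s) absent: ", paste(miss_cov, collapse = ", ")))

  used <- !is.na(data[[biomarker]])
  if (!any(used)) abort(paste0("all values of `", biomarker, "` are missing."))
  d <- data[used, c("subject", "visit", biomarker, covariates)]

  # listwise by subject: a subject missing any covariate at any visit is out
  if (length(covariates)) {
    bad_row <- rowSums(is.na(d[covariates])) > 0
    bad_subj <- unique(d$subject[bad_row])
    if (length(bad_subj))
      inform(paste0("dropping ", length(bad_subj),
                    " subject(s) with missing covariates: ",
                    paste(bad_subj, collapse = ", ")))
    d <- d[!d$subject %in% bad_subj, ]
  }
  if (length(unique(d$subject)) < 3)
    abort("need at least 3 subjects with data.")

  y <- d[[biomarker]]
  if (scale == "log") {
    if (any(y <= 0)) abort("log scale requires strictly positive values.")
    y <- log(y)
  }
  subj <- factor(d$subject)
  sidx <- as.integer(subj)
  X <- cbind(`(Intercept)` = rep(1, nrow(d)))
  if (length(covariates)) {
    Xc <- as.matrix(d[covariates])
    storage.mode(Xc) <- "double"
    keep <- apply(Xc, 2, function(col) var(col) > 0)
    if (any(!keep))
      inform(paste0("dropping constant covariate(s): ",
                    paste(covariates[!keep], collapse = ", ")))
    X <- cbind(X, Xc[, keep, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      abort(paste0("rank-deficient design; collinear column(s): ",
                   paste(dropped, collapse = ", ")))
    }
  }

  sol <- reml_engine(y, sidx, X)
  res <- reml_residuals(y, sidx, X, sol, type = residual_type)

  structure(
    list(biomarker = biomarker,
         scale = scale,
         components = list(sigma2_between = sol$sigma2_b,
                           sigma2_within = sol$sigma2_w,
                           grand_mean = mean(y),
                           scale = scale,
                           singular = sol$singular),
         fixed_effects = setNames(as.numeric(sol$beta), colnames(X)),
         residuals = tibble::tibble(subject = as.character(d$subject),
                                    visit = d$visit,
                                    std_residual = res$std),
         blup = setNames(res$blup, levels(subj)),
         singular = sol$singular,
         degenerate = isTRUE(sol$degenerate),
         icc = icc_from_components(list(sigma2_between = sol$sigma2_b,
                                        sigma2_within = sol$sigma2_w,
                                        singular = sol$singular)),
         reml_criterion = sol$objective,
         lambda = sol$lambda,
         n_subjects_used = length(levels(subj)),
         n_obs = length(y),
         adjusted = length(covariates) > 0,
         residual_type = residual_type),
    class = "biovar_fit")
}

#' @export
print.biovar_fit <- function(x, ...) {
  cat("<biovar random-intercept REML fit>  biomarker:", x$biomarker,
      "| scale:", x$scale, if (x$adjusted) "| adjusted" else "| crude", "\n")
  cat(sprintf("  sigma2_between = %.6g, sigma2_within = %.6g, ICC = %.3f%s\n",
              x$components$sigma2_between, x$components$sigma2_within,
              x$icc, if (x$singular) " (singular fit)" else ""))
  cat("  subjects used:", x$n_subjects_used, "| observations:", x$n_obs, "\n")
  invisible(x)
}

#' Intraclass correlation from variance components
#'
#' Between-subject variance over total variance. A singular fit (between
#' component truncated at zero) yields 0 by convention; both components
#' zero without the singular flag is an error.
#'
#' @param vc List with `sigma2_between`, `sigma2_within` and optionally
#'   `singular` (a `biovar_fit$components` works directly).
#' @return ICC in `[0, 1]`.
#' @export
icc_from_components <- function(vc) {
  sb <- vc$sigma2_between; sw <- vc$sigma2_within
  if (sb < 0 || sw < 0) abort("variance components must be non-negative.")
  if (sb + sw == 0) {
    if (isTRUE(vc$singular)) return(0)
    abort("both variance components are zero.")
  }
  sb / (sb + sw)
}

#' Bootstrap confidence interval for the ICC
#'
#' Resamples subjects with replacement (each subject travels with all of its
#' visits), refits the model on every replicate and returns percentile
#' 2.5/97.5 bounds clipped to `[0, 1]`. Deterministic given `seed`.
#'
#' @inheritParams fit_mixed_covariates
#' @param covariates Optional; empty for the crude model.
#' @param B Number of bootstrap replicates (2000 for reporting; a few
#'   hundred suffice for smoke tests).
#' @param seed Integer seed for the resampling stream.
#' @param type `"percentile"` (default) or `"normal"` (point estimate ±
#'   1.96 bootstrap standard errors).
#' @return A tibble of class `biovar_icc` with columns `icc`, `ci_low`,
#'   `ci_high`, `n_boot`, `adjusted`, `singular`; the replicate ICCs are in
#'   the `replicates` attribute.
#' @export
bootstrap_icc_ci <- function(data, biomarker, covariates = character(),
                             scale = c("raw", "log"), B = 2000L, seed = 1L,
                             type = c("percentile", "normal")) {
  scale <- match.arg(scale)
  type <- match.arg(type)
  if (B < 1) abort("`B` must be at least 1.")
  fit <- fit_random_intercept(data, biomarker, covariates, scale)

  # rebuild the exact vectors the fit used, then resample subject blocks
  used <- !is.na(data[[biomarker]])
  d <- data[used, c("subject", "visit", biomarker, covariates)]
  if (length(covariates)) {
    bad <- unique(d$subject[rowSums(is.na(d[covariates])) > 0])
    d <- d[!d$subject %in% bad, ]
  }
  y <- d[[biomarker]]
  if (scale == "log") y <- log(y)
  X <- cbind(`(Intercept)` = rep(1, nrow(d)))
  if (length(covariates)) {
    Xc <- as.matrix(d[covariates]); storage.mode(Xc) <- "double"
    X <- cbind(X, Xc[, apply(Xc, 2, var) > 0, drop = FALSE])
  }
  subj <- factor(d$subject)
  blocks <- split(seq_along(y), subj)
  q <- length(blocks)

  set.seed(seed)
  reps <- rep(NA_real_, B)
  fails <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(q, q, replace = TRUE)
    rows <- unlist(blocks[pick], use.names = FALSE)
    new_id <- rep.int(seq_len(q), lengths(blocks)[pick])
    sol <- tryCatch(reml_engine(y[rows], new_id, X[rows, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) { fails <- fails + 1L; next }
    tot <- sol$sigma2_b + sol$sigma2_w
    reps[b] <- if (tot == 0) 0 else sol$sigma2_b / tot
  }
  ok <- !is.na(reps)
  if (mean(!ok) > 0.5)
    abort(paste0("bootstrap failure rate ", round(mean(!ok) * 100), "% exceeds 50%."))
  r <- reps[ok]
  if (type == "percentile") {
    # (B+1)p order-statistic convention (quantile type 6), as in the classic
    # bootstrap-percentile definition
    ci <- unname(quantile(r, c(0.025, 0.975), type = 6))
  } else {
    ci <- fit$icc + c(-1, 1) * 1.96 * sd(r)
  }
  ci <- pmin(pmax(ci, 0), 1)
  out <- tibble::tibble(icc = fit$icc, ci_low = ci[1], ci_high = ci[2],
                        n_boot = sum(ok), adjusted = fit$adjusted,
                        singular = fit$singular)
  structure(out, class = unique(c("biovar_icc", class(out))),
            replicates = r, fit = fit)
}

#' Iterative exclusion of subjects with outlying residuals
#'
#' The residual sensitivity analysis: fit the model, drop every subject with
#' at least one standardized residual beyond `cutoff` in absolute value,
#' refit, and repeat until none remain (subjects, not single observations,
#' are the exclusion unit).
#'
#' @inheritParams bootstrap_icc_ci
#' @param cutoff Positive residual threshold (2.0 in common practice).
#' @return List with the final `fit` (a `biovar_fit`) and `report`, a tibble
#'   of exclusions (`iteration`, `subject`, `max_abs_residual`).
#' @export
iterative_residual_exclusion <- function(data, biomarker,
                                         covariates = character(),
                                         scale = c("raw", "log"),
                                         cutoff = 2.0) {
  scale <- match.arg(scale)
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  report <- tibble::tibble(iteration = integer(), subject = character(),
                           max_abs_residual = double())
  current <- data
  it <- 0L
  repeat {
    it <- it + 1L
    fit <- fit_random_intercept(current, biomarker, covariates, scale)
    worst <- dplyr::summarise(
      dplyr::group_by(fit$residuals, .data$subject),
      max_abs = max(abs(.data$std_residual)), .groups = "drop")
    bad <- worst[worst$max_abs > cutoff, ]
    if (nrow(bad) == 0) break
    report <- dplyr::bind_rows(report, tibble::tibble(
      iteration = it, subject = bad$subject,
      max_abs_residual = bad$max_abs))
    current <- current[!current$subject %in% bad$subject, ]
    n_left <- length(unique(current$subject[!is.na(current[[biomarker]])]))
    if (n_left < 3)
      abort(paste0("residual exclusion exhausted the cohort at iteration ", it,
                   " (", n_left, " subjects left); excluded: ",
                   paste(report$subject, collapse = ", ")))
  }
  list(fit = fit, report = report, data = current)
}
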