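# deterministic per-key substream seed so adding a biomarker never perturbs
# the draws of another; polynomial string hash folded into [0, 2^31 - 2]
substream_seed <- function(master, key) {
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 1000000007
  as.integer((as.numeric(master) + h) %% 2147483646) + 1L
}

#' Specify a synthetic repeated-measures cohort
#'
#' Defines the data-generating process used throughout the test-bench: a
#' random subject intercept plus an independent visit-level residual, on the
#' log scale for lognormal biomarkers and on the relative (fraction-of-mean)
#' scale for normal ones, with optional fixed covariate effects and
#' injectable outliers.
#'
#' For a lognormal biomarker with original-scale mean `mu` and
#' between/within coefficients of variation `cv_g`, `cv_t`, values are
#' `ln y_ij = ln(mu) + sum(slope * covariate) + b_i + e_ij` with
#' `b_i ~ N(0, ln(1 + cv_g^2))` and `e_ij ~ N(0, ln(1 + cv_t^2))`. For a
#' normal biomarker, `y_ij = mu * (1 + sum(slope * covariate) + b_i + e_ij)`
#' with `b_i ~ N(0, cv_g^2)`, `e_ij ~ N(0, cv_t^2)`.
#'
#' @param biomarkers A data frame (or list coercible to one) with columns
#'   `name`, `mu`, `cv_g`, `cv_t`, `lognormal`; see [default_panel()] for the
#'   bundled 17-biomarker antioxidant panel.
#' @param n_subjects,n_visits Cohort dimensions (default 44 subjects,
#'   3 visits — a typical short reliability panel).
#' @param covariate_effects Named list: covariate name -> named numeric
#'   vector of per-biomarker slopes, or a single numeric applied to all
#'   biomarkers, on the analysis scale.
#' @param covariate_distributions Named list: covariate -> either
#'   `list(mean=, sd_between=, sd_within=)` for a continuous covariate with
#'   a subject-level component, or `list(p=)` for a subject-constant
#'   Bernoulli flag.
#' @param outliers List of injections, each
#'   `list(subject =, kind = "variance_inflation"|"mean_shift", magnitude =,
#'   biomarker = NULL)`; `biomarker = NULL` applies to all. Magnitudes of
#'   variance inflations must exceed 1.
#' @param seed Master integer seed; every biomarker and covariate draws from
#'   its own deterministic substream.
#' @return A list with class `"biovar_spec"`.
#' @export
synthetic_spec <- function(biomarkers = default_panel(),
                           n_subjects = 44L, n_visits = 3L,
                           covariate_effects = list(),
                           covariate_distributions = default_covariates(),
                           outliers = list(),
                           seed = 1L) {
  biomarkers <- tibble::as_tibble(biomarkers)
  need <- setdiff(c("name", "mu", "cv_g", "cv_t", "lognormal"), names(biomarkers))
  if (length(need))
    abort(paste0("biomarker spec lacks column(s): ", paste(need, collapse = ", ")))
  stopifnot(n_subjects >= 2, n_visits >= 2,
            all(biomarkers$mu > 0),
            all(biomarkers$cv_g >= 0), all(biomarkers$cv_t >= 0))
  for (o in outliers) {
    if (!o$kind %in% c("variance_inflation", "mean_shift"))
      abort(paste0("unknown outlier kind: ", o$kind))
    if (o$kind == "variance_inflation" && o$magnitude <= 1)
      abort("variance_inflation magnitude must exceed 1.")
  }
  structure(list(biomarkers = biomarkers,
                 n_subjects = as.integer(n_subjects),
                 n_visits = as.integer(n_visits),
                 covariate_effects = covariate_effects,
                 covariate_distributions = covariate_distributions,
                 outliers = outliers,
                 seed = as.integer(seed)),
            class = "biovar_spec")
}

#' The bundled 17-biomarker antioxidant panel
#'
#' Per-biomarker original-scale means and between-/within-subject
#' coefficients of variation at the magnitudes reported for antioxidant
#' biomarkers in healthy premenopausal women, with the conventional choice
#' of scale (log for the strongly right-skewed plasma micronutrients; raw
#' for bilirubin, erythrocyte catalase, glutathione and the Trolox
#' equivalent antioxidant capacity).
#'
#' @return A tibble with columns `name`, `mu`, `unit`, `cv_g`, `cv_t`,
#'   `lognormal`.
#' @export
default_panel <- function() {
  tibble::tribble(
    ~name,            ~mu,     ~unit,      ~cv_g, ~cv_t, ~lognormal,
    "bilirubin",       7.3,    "umol/L",   0.343, 0.299, FALSE,
    "uric_acid",     240,      "umol/L",   0.170, 0.113, TRUE,
    "vitamin_c",      94,      "umol/L",   0.127, 0.123, TRUE,
    "alpha_tocopherol", 20.4,  "umol/L",   0.169, 0.110, TRUE,
    "gamma_tocopherol",  1.03, "umol/L",   0.409, 0.310, TRUE,
    "retinol",         2.0,    "umol/L",   0.191, 0.186, TRUE,
    "alpha_carotene",  0.34,   "umol/L",   0.547, 0.266, TRUE,
    "beta_carotene",   0.89,   "umol/L",   0.617, 0.217, TRUE,
    "lutein",          0.21,   "umol/L",   0.336, 0.227, TRUE,
    "zeaxanthin",      0.11,   "umol/L",   0.333, 0.323, TRUE,
    "beta_cryptoxanthin", 0.22, "umol/L",  0.378, 0.209, TRUE,
    "lycopene",        0.74,   "umol/L",   0.385, 0.248, TRUE,
    "coenzyme_q10",  515,      "nmol/L",   0.300, 0.166, TRUE,
    "ecat",          638,      "kU/gHb",   0.083, 0.060, FALSE,
    "egpx",           24.5,    "U/gHb",    0.236, 0.130, TRUE,
    "glutathione",   656,      "umol/L",   0.053, 0.161, FALSE,
    "teac",            1.11,   "mmol/L",   0.000, 0.070, FALSE)
}

#' Default covariate distributions for the synthetic cohort
#'
#' Magnitudes chosen to resemble a young-adult female cohort: menstrual
#' cycle day, BMI, fasting and sleep duration, contraceptive use, serum
#' cholesterol, physical activity level and daily energy intake.
#'
#' @return Named list consumed by [synthetic_spec()].
#' @export
default_covariates <- function() {
  list(
    cycle_day    = list(mean = 15,   sd_between = 4.0, sd_within = 6.0),
    bmi          = list(mean = 22,   sd_between = 2.5, sd_within = 0.3),
    fasting_h    = list(mean = 13.3, sd_between = 0.4, sd_within = 0.5),
    sleep_h      = list(mean = 8.0,  sd_between = 0.4, sd_within = 0.6),
    contraceptive = list(p = 0.5),
    cholesterol  = list(mean = 3.9,  sd_between = 0.6, sd_within = 0.25),
    pal          = list(mean = 1.6,  sd_between = 0.10, sd_within = 0.07),
    energy_mj    = list(mean = 8.1,  sd_between = 1.3, sd_within = 1.1))
}

#' Generate a synthetic cohort
#'
#' Draws a repeated-measures table from the process described in
#' [synthetic_spec()]. Deterministic given the spec's seed; each biomarker
#' and covariate uses an independent substream, so extending the panel never
#' changes existing columns.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated long cohort tibble (see [validate_cohort()]) with the
#'   spec's outlier injections applied.
#' @export
#' @examples
#' spec <- synthetic_spec(n_subjects = 6, seed = 7)
#' generate_cohort(spec)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "biovar_spec"))
  n <- spec$n_subjects; k <- spec$n_visits
  subject <- sprintf("S%03d", seq_len(n))
  out <- tibble::tibble(
    subject = rep(subject, each = k),
    visit = rep(seq_len(k), times = n))

  covs <- names(spec$covariate_distributions)
  for (cv in covs) {
    d <- spec$covariate_distributions[[cv]]
    set.seed(substream_seed(spec$seed, paste0("cov:", cv)))
    if (!is.null(d$p)) {
      x <- rep(rbinom(n, 1, d$p), each = k)
    } else {
      between <- rnorm(n, d$mean, d$sd_between)
      x <- rep(between, each = k) + rnorm(n * k, 0, d$sd_within %||% 0)
    }
    out[[cv]] <- x
  }

  for (j in seq_len(nrow(spec$biomarkers))) {
    b <- spec$biomarkers[j, ]
    sg <- sigma_from_cv(b$cv_g); sw <- sigma_from_cv(b$cv_t)
    if (!b$lognormal) { sg <- b$cv_g; sw <- b$cv_t }
    set.seed(substream_seed(spec$seed, paste0("bm:", b$name)))
    bi <- rnorm(n, 0, sg)
    eij <- rnorm(n * k, 0, sw)
    eta <- rep(bi, each = k) + eij
    for (cv in names(spec$covariate_effects)) {
      sl <- spec$covariate_effects[[cv]]
      if (is.null(names(sl))) {
        slope <- sl[[1]]
      } else {
        slope <- unname(sl[b$name])
        if (is.na(slope)) slope <- 0
      }
      if (!cv %in% names(out))
        abort(paste0("covariate effect refers to undistributed covariate: ", cv))
      eta <- eta + slope * out[[cv]]
    }
    if (b$lognormal) {
      out[[b$name]] <- exp(log(b$mu) + eta)
    } else {
      y <- b$mu * (1 + eta)
      # raw-scale draws must stay positive: redraw the visit residual of any
      # offending cell (rejection sampling; deterministic given the stream)
      tries <- 0L
      while (any(y <= 0) && sw > 0 && tries < 100L) {
        bad <- which(y <= 0)
        fresh <- rnorm(length(bad), 0, sw)
        eta[bad] <- eta[bad] - eij[bad] + fresh
        eij[bad] <- fresh
        y <- b$mu * (1 + eta)
        tries <- tries + 1L
      }
      if (any(y <= 0)) abort(paste0("cv parameters of `", b$name,
                                    "` produce non-positive values."))
      out[[b$name]] <- y
    }
  }

  cfg <- analysis_config(biomarkers = spec$biomarkers$name, covariates = covs)
  out <- validate_cohort(out, config = cfg, n_visits = k)
  inject_outliers(out, spec)
}

#' Inject aberrant subjects into a cohort
#'
#' Applies the outlier injections of a spec to an existing cohort:
#' `variance_inflation` multiplies a subject's deviations from their own
#' mean by the magnitude; `mean_shift` adds `magnitude` between-subject
#' standard deviations (approximated on the original scale as
#' `mu * cv_g`) to all of the subject's values. Untouched records are
#' returned unchanged.
#'
#' @param data A cohort tibble.
#' @param spec The [synthetic_spec()] carrying `outliers`.
#' @return The cohort with injections applied.
#' @export
inject_outliers <- function(data, spec) {
  subjects <- unique(data$subject)
  for (o in spec$outliers) {
    if (o$subject < 1 || o$subject > length(subjects))
      abort(paste0("outlier injection names unknown subject index: ", o$subject))
    sid <- subjects[o$subject]
    rows <- data$subject == sid
    targets <- o$biomarker %||% spec$biomarkers$name
    for (bm in targets) {
      b <- spec$biomarkers[spec$biomarkers$name == bm, ]
      y <- data[[bm]][rows]
      if (o$kind == "variance_inflation") {
        y <- mean(y) + o$magnitude * (y - mean(y))
        # inflation can push a lognormal-positive value below zero; clamp
        y <- pmax(y, .Machine$double.eps)
      } else {
        y <- y + o$magnitude * b$mu * b$cv_g
      }
      data[[bm]][rows] <- y
    }
  }
  data
}

#' Ground-truth parameters of a synthetic spec
#'
#' Returns, per biomarker, the intraclass correlation implied by the spec on
#' its analysis scale (between-subject variance over total variance) along
#' with the specified CVs — the reference values for parameter-recovery
#' tests.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `biomarker`, `icc`, `cv_g`, `cv_t`.
#' @export
true_params <- function(spec) {
  b <- spec$biomarkers
  vg <- ifelse(b$lognormal, log(1 + b$cv_g^2), b$cv_g^2)
  vw <- ifelse(b$lognormal, log(1 + b$cv_t^2), b$cv_t^2)
  icc <- ifelse(vg + vw == 0, NA_real_, vg / (vg + vw))
  tibble::tibble(biomarker = b$name, icc = icc, cv_g = b$cv_g, cv_t = b$cv_t)
}

#' Read a synthetic spec from YAML
#'
#' @param path YAML file with keys matching the arguments of
#'   [synthetic_spec()]; `biomarkers` as a list of records.
#' @return A `biovar_spec`.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("spec file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$biomarkers))
    raw$biomarkers <- dplyr::bind_rows(lapply(raw$biomarkers, tibble::as_tibble))
  do.call(synthetic_spec, raw)
}
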