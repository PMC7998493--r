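#' Run the full reliability analysis
#'
#' The end-to-end pipeline, per biomarker: Cochran/Reed outlier screening,
#' choice of analysis scale, crude one-way REML fit with a subject-level
#' bootstrap CI for the ICC, an optional covariate-adjusted fit with its own
#' bootstrap CI, and the closed-form biological-variation metrics (CVs,
#' index of individuality, reference change value — symmetric on the raw
#' scale, asymmetric up/down under the log transform — attenuation-limiting
#' measurement counts and the qualitative reliability band). Deterministic
#' given the config seed.
#'
#' @param data A validated cohort tibble ([read_cohort()],
#'   [generate_cohort()]).
#' @param config An [analysis_config()]; empty `biomarkers` falls back to
#'   the cohort's declared biomarker columns.
#' @return A tibble of class `biovar_reliability`, one row per biomarker
#'   (columns listed under [write_reliability_report()]), with the
#'   per-biomarker screening reports in the `screens` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_subjects = 10, seed = 3))
#' cfg <- analysis_config(biomarkers = c("uric_acid", "teac"), n_boot = 50)
#' run_reliability_analysis(cohort, cfg)
run_reliability_analysis <- function(data, config = analysis_config()) {
  biomarkers <- config$biomarkers
  if (!length(biomarkers)) biomarkers <- attr(data, "biomarkers")
  if (!length(biomarkers)) abort("no biomarkers declared in config or data.")
  covariates <- config$covariates

  screens <- list()
  rows <- purrr::map(biomarkers, function(bm) {
    usable <- data[!is.na(data[[bm]]), ]
    if (length(unique(usable$subject)) < 3)
      return(empty_row(bm, note = "fewer than 3 usable subjects"))

    scale <- resolve_scale(usable, bm, config)
    scr <- tryCatch(
      screen_outliers(usable, bm, alpha = config$cochran_alpha,
                      iterative = config$iterative_screen, scale = scale),
      error = function(e) NULL)
    if (!is.null(scr)) {
      screens[[bm]] <<- scr
      usable <- usable[!usable$subject %in% scr$subject, ]
    }
    if (length(unique(usable$subject)) < 3)
      return(empty_row(bm, note = "fewer than 3 subjects after screening"))

    seed_bm <- substream_seed(config$seed, paste0("boot:", bm))

    crude <- bootstrap_icc_ci(usable, bm, covariates = character(),
                              scale = scale, B = config$n_boot,
                              seed = seed_bm, type = config$boot_type)
    fit <- attr(crude, "fit")

    adj <- NULL
    have_cov <- length(covariates) && all(covariates %in% names(usable))
    if (have_cov) {
      adj <- tryCatch(
        bootstrap_icc_ci(usable, bm, covariates = covariates, scale = scale,
                         B = config$n_boot,
                         seed = substream_seed(config$seed, paste0("bootadj:", bm)),
                         type = config$boot_type),
        error = function(e) NULL)
    }
    metric_row(bm, fit, crude, adj, config)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = unique(c("biovar_reliability", class(out))),
            screens = screens)
}

resolve_scale <- function(data, biomarker, config) {
  tr <- config$transform
  choice <- if (length(tr) > 1 || !is.null(names(tr))) {
    unname(tr[biomarker]) %||% "auto"
  } else tr
  if (is.na(choice)) choice <- "auto"
  if (choice == "auto") {
    rec <- recommend_transform(data, biomarker, alpha = config$cochran_alpha)
    choice <- if (isTRUE(rec$log)) "log" else "raw"
  }
  choice
}

metric_row <- function(bm, fit, crude, adj, config) {
  cvs <- cv_from_components(fit$components)
  ii <- index_of_individuality(cvs[["cv_t"]], cvs[["cv_g"]])
  symmetric <- fit$scale == "raw"
  if (symmetric) {
    half <- rcv_symmetric(cvs[["cv_t"]], config$z)
    rcv_up <- half; rcv_down <- -half
  } else {
    rcv <- rcv_asymmetric(cvs[["cv_t"]], config$z)
    rcv_up <- rcv[["up"]]; rcv_down <- rcv[["down"]]
  }
  sb <- fit$components$sigma2_between
  sw <- fit$components$sigma2_within
  nb <- vapply(config$attenuation,
               function(a) as.integer(n_measurements(sw, sb, a)), integer(1))
  tibble::tibble(
    biomarker = bm,
    n_subjects = fit$n_subjects_used,
    scale = fit$scale,
    icc = crude$icc, icc_low = crude$ci_low, icc_high = crude$ci_high,
    cv_g = cvs[["cv_g"]], cv_t = cvs[["cv_t"]],
    ii = ii$ii,
    rcv_up = rcv_up, rcv_down = rcv_down, symmetric = symmetric,
    n_beta_10 = nb[1], n_beta_20 = if (length(nb) > 1) nb[2] else NA_integer_,
    category = icc_category(crude$icc),
    singular = fit$singular,
    icc_adj = if (!is.null(adj)) adj$icc else NA_real_,
    icc_adj_low = if (!is.null(adj)) adj$ci_low else NA_real_,
    icc_adj_high = if (!is.null(adj)) adj$ci_high else NA_real_,
    n_boot = crude$n_boot,
    note = NA_character_)
}

empty_row <- function(bm, note) {
  tibble::tibble(
    biomarker = bm, n_subjects = NA_integer_, scale = NA_character_,
    icc = NA_real_, icc_low = NA_real_, icc_high = NA_real_,
    cv_g = NA_real_, cv_t = NA_real_, ii = NA_real_,
    rcv_up = NA_real_, rcv_down = NA_real_, symmetric = NA,
    n_beta_10 = NA_integer_, n_beta_20 = NA_integer_,
    category = NA_character_, singular = NA,
    icc_adj = NA_real_, icc_adj_low = NA_real_, icc_adj_high = NA_real_,
    n_boot = NA_integer_, note = note)
}

#' Sensitivity analyses of the reliability pipeline
#'
#' Two modes. `"residual"` repeats the analysis after model-wise iterative
#' exclusion of subjects with at least one standardized residual beyond the
#' configured cutoff ([iterative_residual_exclusion()]). `"subgroup"` drops
#' subjects flagged by any of the given exclusion columns (binary
#' covariates such as contraceptive use, medication, vaccination, abnormal
#' cycle, health problems) or an elevated inflammation marker, re-screens
#' with Cochran/Reed and residual inspection, and reports crude-only
#' metrics — the adjusted ICC is deliberately absent at the reduced sample
#' size.
#'
#' @inheritParams run_reliability_analysis
#' @param mode `"residual"` or `"subgroup"`.
#' @param exclude_flags For subgroup mode: character vector of binary
#'   columns; a subject with a 1 in any of them at any visit is excluded.
#' @param hs_crp_column,hs_crp_threshold Optional inflammation screen for
#'   subgroup mode: exclude subjects whose marker reaches the threshold
#'   (default 95, i.e. nmol/L for hs-CRP) at any visit.
#' @return A `biovar_reliability` tibble; in subgroup mode the adjusted-ICC
#'   columns are absent.
#' @export
run_sensitivity <- function(data, config = analysis_config(),
                            mode = c("residual", "subgroup"),
                            exclude_flags = character(),
                            hs_crp_column = NULL, hs_crp_threshold = 95) {
  mode <- match.arg(mode)
  biomarkers <- config$biomarkers
  if (!length(biomarkers)) biomarkers <- attr(data, "biomarkers")

  if (mode == "subgroup") {
    if (!length(exclude_flags) && is.null(hs_crp_column))
      abort("subgroup mode needs at least one exclusion flag.")
    miss <- setdiff(exclude_flags, names(data))
    if (length(miss))
      abort(paste0("exclusion flag column(s) absent: ", paste(miss, collapse = ", ")))
    flagged <- character()
    for (fl in exclude_flags)
      flagged <- union(flagged, unique(data$subject[!is.na(data[[fl]]) & data[[fl]] == 1]))
    if (!is.null(hs_crp_column))
      flagged <- union(flagged,
                       unique(data$subject[!is.na(data[[hs_crp_column]]) &
                                             data[[hs_crp_column]] >= hs_crp_threshold]))
    reduced <- data[!data$subject %in% flagged, ]
    if (length(unique(reduced$subject)) < 3)
      abort(paste0("subgroup exclusion (",
                   paste(c(exclude_flags, hs_crp_column), collapse = ", "),
                   ") leaves fewer than 3 subjects."))
    # crude-only analysis with residual re-inspection on the reduced cohort
    cfg <- config
    cfg$covariates <- character()
    out <- run_sensitivity(reduced, cfg, mode = "residual")
    out$icc_adj <- NULL; out$icc_adj_low <- NULL; out$icc_adj_high <- NULL
    attr(out, "excluded_subjects") <- flagged
    return(out)
  }

  rows <- purrr::map(biomarkers, function(bm) {
    usable <- data[!is.na(data[[bm]]), ]
    if (length(unique(usable$subject)) < 3)
      return(empty_row(bm, note = "fewer than 3 usable subjects"))
    scale <- resolve_scale(usable, bm, config)
    scr <- tryCatch(
      screen_outliers(usable, bm, alpha = config$cochran_alpha,
                      iterative = config$iterative_screen, scale = scale),
      error = function(e) NULL)
    if (!is.null(scr)) usable <- usable[!usable$subject %in% scr$subject, ]
    covariates <- config$covariates
    if (length(covariates) && !all(covariates %in% names(usable)))
      covariates <- character()
    excl <- tryCatch(
      iterative_residual_exclusion(usable, bm, covariates = covariates,
                                   scale = scale,
                                   cutoff = config$residual_cutoff),
      error = function(e) NULL)
    if (is.null(excl))
      return(empty_row(bm, note = "residual exclusion failed"))
    kept <- excl$data
    seed_bm <- substream_seed(config$seed, paste0("sens:", bm))
    crude <- bootstrap_icc_ci(kept, bm, covariates = character(),
                              scale = scale, B = config$n_boot,
                              seed = seed_bm, type = config$boot_type)
    adj <- NULL
    if (length(covariates))
      adj <- tryCatch(
        bootstrap_icc_ci(kept, bm, covariates = covariates, scale = scale,
                         B = config$n_boot,
                         seed = substream_seed(config$seed, paste0("sensadj:", bm)),
                         type = config$boot_type),
        error = function(e) NULL)
    metric_row(bm, attr(crude, "fit"), crude, adj, config)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = unique(c("biovar_reliability", class(out))))
}

#' Longitudinal shift tests across visits
#'
#' Friedman test of a visit effect on subjects with complete visit series;
#' when the overall test is significant at `alpha`, all pairwise Wilcoxon
#' signed-rank tests follow with Bonferroni-multiplied p values, and visits
#' are labelled with compact letters (visits sharing a letter do not differ
#' significantly).
#'
#' @param data Cohort tibble.
#' @param biomarker Biomarker column name.
#' @param alpha Significance level of the overall test.
#' @return List with `statistic`, `p_overall`, `pairwise` (tibble of visit
#'   pairs and adjusted p values; empty when the overall test is not
#'   significant) and `letters` (named character vector by visit).
#' @export
longitudinal_shift_tests <- function(data, biomarker, alpha = 0.05) {
  visits <- sort(unique(data$visit))
  wide <- tidyr::pivot_wider(
    data[, c("subject", "visit", biomarker)],
    names_from = "visit", values_from = dplyr::all_of(biomarker))
  m <- as.matrix(wide[, -1])
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) abort("need at least 3 subjects with complete visits.")

  k <- ncol(m)
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    return(list(statistic = 0, p_overall = 1,
                pairwise = empty_pairwise(),
                letters = setNames(rep("a", k), colnames(m))))
  }
  fr <- friedman.test(m)
  pairwise <- empty_pairwise()
  sig <- matrix(FALSE, k, k)
  if (fr$p.value < alpha) {
    combos <- utils::combn(k, 2)
    n_pairs <- ncol(combos)
    for (j in seq_len(n_pairs)) {
      a <- combos[1, j]; b <- combos[2, j]
      p <- suppressWarnings(wilcox.test(m[, a], m[, b], paired = TRUE)$p.value)
      p_adj <- min(1, p * n_pairs)
      pairwise <- dplyr::bind_rows(pairwise, tibble::tibble(
        visit_a = colnames(m)[a], visit_b = colnames(m)[b],
        p_raw = p, p_bonferroni = p_adj))
      sig[a, b] <- sig[b, a] <- p_adj < alpha
    }
  }
  list(statistic = unname(fr$statistic), p_overall = fr$p.value,
       pairwise = pairwise,
       letters = setNames(compact_letters(!sig), colnames(m)))
}

empty_pairwise <- function() {
  tibble::tibble(visit_a = character(), visit_b = character(),
                 p_raw = double(), p_bonferroni = double())
}

# compact letter display from a "not significantly different" adjacency
# matrix: letter every maximal clique (exhaustive — visit counts are tiny)
compact_letters <- function(nsd) {
  k <- nrow(nsd)
  diag(nsd) <- TRUE
  subsets <- lapply((2^k - 1):1, function(mask) which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0))
  cliques <- list()
  for (s in subsets) {
    if (all(nsd[s, s])) {
      if (!any(vapply(cliques, function(cl) all(s %in% cl), logical(1))))
        cliques <- c(cliques, list(s))
    }
  }
  lab <- rep("", k)
  for (j in seq_along(cliques))
    lab[cliques[[j]]] <- paste0(lab[cliques[[j]]], letters[j])
  lab
}

#' Baseline rank-correlation matrix
#'
#' Spearman correlations among all biomarker pairs at one visit, with
#' two-sided p values; constant columns yield flagged undefined entries.
#'
#' @param data Cohort tibble.
#' @param visit Visit index to correlate at (1 = baseline).
#' @param biomarkers Biomarker columns; defaults to the cohort's declared
#'   set.
#' @return Object of class `biovar_cormat`: list with matrices `r` and `p`
#'   (symmetric, unit diagonal) and a tidy `pairs` tibble.
#' @export
baseline_correlation_matrix <- function(data, visit = 1, biomarkers = NULL) {
  biomarkers <- biomarkers %||% attr(data, "biomarkers")
  if (is.null(biomarkers)) abort("no biomarker columns declared.")
  d <- data[data$visit == visit, biomarkers, drop = FALSE]
  if (nrow(d) == 0) abort(paste0("no records at visit ", visit, "."))
  k <- length(biomarkers)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(biomarkers, biomarkers)
  pairs <- tibble::tibble(biomarker_a = character(), biomarker_b = character(),
                          rho = double(), p = double(), undefined = logical())
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    xa <- d[[a]]; xb <- d[[b]]
    ok <- !is.na(xa) & !is.na(xb)
    undef <- sum(ok) < 3 || var(xa[ok]) == 0 || var(xb[ok]) == 0
    if (undef) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(xa[ok], xb[ok], method = "spearman"))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    r[a, b] <- r[b, a] <- rho
    p[a, b] <- p[b, a] <- pv
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      biomarker_a = biomarkers[a], biomarker_b = biomarkers[b],
      rho = rho, p = pv, undefined = undef))
  }
  structure(list(r = r, p = p, pairs = pairs, visit = visit),
            class = "biovar_cormat")
}
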