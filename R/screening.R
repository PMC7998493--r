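#' Cochran's C statistic
#'
#' Ratio of the largest variance to the sum of all variances — the classic
#' screen for one aberrantly variable group among many.
#'
#' @param variances Numeric vector of group variances (here: per-subject
#'   intra-individual variances), all non-negative, not all zero.
#' @return The statistic `max(s_i^2) / sum(s_i^2)`, in `(0, 1]`.
#' @export
#' @examples
#' cochran_c(c(5, 1, 1, 1)) # 0.625
cochran_c <- function(variances) {
  if (length(variances) < 2) abort("need at least 2 variances.")
  if (any(variances < 0)) abort("variances must be non-negative.")
  if (sum(variances) == 0) abort("Cochran's C is undefined for all-zero variances.")
  max(variances) / sum(variances)
}

#' Upper critical value of Cochran's C
#'
#' Computed from the F-quantile relation
#' `C = 1 / (1 + (n - 1) / F)` with `F` the upper `alpha / n` quantile on
#' `(df, (n - 1) df)` degrees of freedom — the Bonferroni-style closed form,
#' which matches the Monte-Carlo null distribution of max/sum to within a
#' few thousandths at conventional levels.
#'
#' @param alpha Significance level in (0, 1).
#' @param n_groups Number of groups (subjects), at least 2.
#' @param df Within-group degrees of freedom (visits minus 1).
#' @return Critical value in (0, 1); observed statistics above it flag the
#'   maximal variance as an outlier.
#' @export
cochran_critical <- function(alpha, n_groups, df) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  stopifnot(n_groups >= 2, df >= 1)
  f <- qf(1 - alpha / n_groups, df, (n_groups - 1) * df)
  1 / (1 + (n_groups - 1) / f)
}

#' Scan a biomarker for variance outliers (Cochran)
#'
#' Computes each subject's intra-individual variance and repeatedly removes
#' the subject with the maximal variance while Cochran's C exceeds its
#' critical value, recomputing statistic and threshold each round
#' (single-pass available via `iterative = FALSE`). Subjects with fewer than
#' two visits cannot contribute a variance and are ignored by the scan.
#'
#' @param data Cohort tibble.
#' @param biomarker Biomarker column name.
#' @param alpha Significance level per scan.
#' @param iterative Repeat until clean (default) or test once.
#' @param scale Scale on which intra-individual variances are computed;
#'   lognormal biomarkers should be scanned on `"log"`, where per-subject
#'   variances are homoscedastic under the null (raw-scale variances of a
#'   lognormal marker grow with the subject mean and would trip the test).
#' @return A tibble (class `biovar_screen`) of exclusions with columns
#'   `subject`, `rule`, `statistic`, `threshold`, `iteration`; zero rows when
#'   nothing is flagged. The attribute `iterations` counts rounds performed.
#' @export
cochran_scan <- function(data, biomarker, alpha = 0.05, iterative = TRUE,
                         scale = c("raw", "log")) {
  scale <- match.arg(scale)
  v <- subject_variances(data, biomarker, scale = scale)
  if (length(v) < 3) abort("Cochran scan needs at least 3 subjects with >= 2 visits.")
  df <- attr(v, "df")
  out <- tibble::tibble(subject = character(), rule = character(),
                        statistic = double(), threshold = double(),
                        iteration = integer())
  it <- 0L
  while (length(v) >= 3 && sum(v) > 0) {
    it <- it + 1L
    stat <- cochran_c(v)
    crit <- cochran_critical(alpha, length(v), df)
    if (stat <= crit) break
    worst <- names(v)[which.max(v)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      subject = worst, rule = "cochran", statistic = stat,
      threshold = crit, iteration = it))
    v <- v[names(v) != worst]
    if (!iterative) break
  }
  structure(out, class = unique(c("biovar_screen", class(out))), iterations = it)
}

# per-subject within-subject variances of one biomarker; attaches the common
# residual df (uses the modal visit count minus 1 for the critical value)
subject_variances <- function(data, biomarker, scale = "raw") {
  if (!biomarker %in% names(data))
    abort(paste0("no biomarker column `", biomarker, "`."))
  d <- data[!is.na(data[[biomarker]]), c("subject", biomarker)]
  if (scale == "log") d[[biomarker]] <- log(d[[biomarker]])
  n_i <- table(d$subject)
  keep <- names(n_i)[n_i >= 2]
  d <- d[d$subject %in% keep, ]
  v <- tapply(d[[biomarker]], d$subject, var)
  v <- v[!is.na(v)]
  counts <- table(d$subject)
  df <- as.integer(max(counts)) - 1L
  structure(as.numeric(v), names = names(v), df = df)
}

#' Reed's criterion for extreme values
#'
#' Flags an extreme observation when its gap to the nearest remaining value
#' exceeds one third of the total range; applied at both ends and repeated
#' after each removal until no flag fires. Translation- and scale-invariant.
#' At least four values must remain for a flag: with only three, any
#' asymmetric spacing would condemn an extreme, so the gap criterion is
#' uninformative and recursion stops there.
#'
#' @param values Numeric vector (here: per-subject mean biomarker values),
#'   length at least 3.
#' @return Integer indices (into `values`) of flagged outliers, possibly
#'   empty, in the order flagged.
#' @export
#' @examples
#' reed_outliers(c(1, 2, 3, 10)) # flags the 4th value
reed_outliers <- function(values) {
  if (length(values) < 3) abort("Reed's criterion needs at least 3 values.")
  idx <- seq_along(values)
  flagged <- integer()
  repeat {
    if (length(idx) < 4) break
    x <- values[idx]
    o <- order(x)
    rng <- x[o[length(o)]] - x[o[1]]
    if (rng == 0) break
    hit <- FALSE
    lo_gap <- x[o[2]] - x[o[1]]
    hi_gap <- x[o[length(o)]] - x[o[length(o) - 1]]
    # test the larger gap first so a dominant extreme is flagged before the
    # range shrinks
    ends <- if (hi_gap >= lo_gap) c("hi", "lo") else c("lo", "hi")
    for (e in ends) {
      gap <- if (e == "hi") hi_gap else lo_gap
      if (gap > rng / 3) {
        pos <- if (e == "hi") o[length(o)] else o[1]
        flagged <- c(flagged, idx[pos])
        idx <- idx[-pos]
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  flagged
}

#' Combined pre-model outlier screen
#'
#' The screening stage of the reliability pipeline: Cochran's test on
#' intra-individual variances followed by Reed's criterion on subject mean
#' values, each (by default) re-applied until clean.
#'
#' @inheritParams cochran_scan
#' @return A `biovar_screen` tibble combining both rules.
#' @export
screen_outliers <- function(data, biomarker, alpha = 0.05, iterative = TRUE,
                            scale = c("raw", "log")) {
  scale <- match.arg(scale)
  coch <- cochran_scan(data, biomarker, alpha = alpha, iterative = iterative,
                       scale = scale)
  keep <- !data$subject %in% coch$subject & !is.na(data[[biomarker]])
  d <- data[keep, c("subject", biomarker)]
  if (scale == "log") d[[biomarker]] <- log(d[[biomarker]])
  means <- tapply(d[[biomarker]], d$subject, mean)
  reed <- if (length(means) >= 3) reed_outliers(as.numeric(means)) else integer()
  if (!iterative) reed <- head(reed, 1)
  reed_tbl <- tibble::tibble(
    subject = names(means)[reed], rule = "reed",
    statistic = as.numeric(means)[reed], threshold = NA_real_,
    iteration = seq_along(reed))
  out <- dplyr::bind_rows(tibble::as_tibble(coch), reed_tbl)
  structure(out, class = unique(c("biovar_screen", class(out))),
            iterations = attr(coch, "iterations"))
}

#' Recommend an analysis scale for a biomarker
#'
#' Applies the Shapiro–Wilk test to the pooled within-subject-centered
#' values on the raw and on the natural-log scale and recommends the log
#' transform when raw normality is rejected at `alpha` but log normality is
#' not; otherwise the raw scale is kept. Constant data are untestable and
#' retained raw.
#'
#' @inheritParams cochran_scan
#' @param alpha Significance level of the normality test.
#' @return List with elements `log` (logical recommendation), `untestable`,
#'   and `evidence` (a tibble of the two test results).
#' @export
recommend_transform <- function(data, biomarker, alpha = 0.05) {
  y <- data[[biomarker]]
  keep <- !is.na(y)
  y <- y[keep]; subj <- data$subject[keep]
  if (length(y) < 3) abort("need at least 3 non-missing values.")
  if (var(y) == 0 || length(unique(round(y, 12))) < 3)
    return(list(log = FALSE, untestable = TRUE, evidence = NULL))
  centre <- function(v) v - ave(v, subj)
  raw_c <- centre(y)
  log_c <- centre(log(y))
  p_raw <- shapiro.test(raw_c)$p.value
  p_log <- shapiro.test(log_c)$p.value
  list(log = (p_raw < alpha) && (p_log >= alpha),
       untestable = FALSE,
       evidence = tibble::tibble(scale = c("raw", "log"),
                                 shapiro_p = c(p_raw, p_log)))
}
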