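#' Analysis configuration
#'
#' Bundles the knobs of the reliability pipeline: which columns hold
#' biomarkers and covariates, the per-biomarker transform choice, the RCV
#' probability multiplier, attenuation levels for the repeat-measurement
#' calculation, bootstrap settings, outlier-screening parameters and limits
#' of quantification.
#'
#' @param biomarkers Character vector of biomarker column names.
#' @param covariates Character vector of covariate column names used by the
#'   adjusted mixed model (empty: crude analysis only).
#' @param transform Per-biomarker scale choice. Either a single string
#'   (`"auto"`, `"log"`, `"raw"`) applied to all biomarkers, or a named
#'   character vector overriding individual biomarkers; `"auto"` delegates to
#'   [recommend_transform()].
#' @param z Probability multiplier for reference change values; 1.96 gives the
#'   bidirectional 95% level.
#' @param attenuation Attenuation levels for the repeat-measurement count
#'   `n_beta`; the default `c(0.10, 0.20)` limits regression-dilution
#'   attenuation to 10% and 20% (P = 0.90 and 0.80).
#' @param n_boot Bootstrap replicate count for ICC confidence intervals.
#' @param boot_type Bootstrap interval type; only `"percentile"` is
#'   implemented as the default route, see [bootstrap_icc_ci()].
#' @param residual_cutoff Standardized-residual threshold of the residual
#'   sensitivity analysis.
#' @param residual_type `"conditional"` (subject-level best linear unbiased
#'   predictor removed) or `"marginal"`.
#' @param cochran_alpha Significance level of the Cochran variance-outlier
#'   scan.
#' @param iterative_screen Re-apply Cochran/Reed screening until no outlier
#'   remains (`TRUE`) or run a single pass.
#' @param loq Named numeric vector mapping biomarker names to limits of
#'   quantification; values below the limit are raised to it on read.
#' @param seed Integer seed controlling every stochastic step downstream.
#'
#' @return A list with class `"biovar_config"`.
#' @export
#' @examples
#' analysis_config(biomarkers = "uric_acid", z = 1.96)
analysis_config <- function(biomarkers = character(),
                            covariates = character(),
                            transform = "auto",
                            z = 1.96,
                            attenuation = c(0.10, 0.20),
                            n_boot = 2000L,
                            boot_type = c("percentile", "normal"),
                            residual_cutoff = 2.0,
                            residual_type = c("conditional", "marginal"),
                            cochran_alpha = 0.05,
                            iterative_screen = TRUE,
                            loq = NULL,
                            seed = 1L) {
  boot_type <- match.arg(boot_type)
  residual_type <- match.arg(residual_type)
  stopifnot(z > 0, all(attenuation > 0 & attenuation < 1),
            n_boot >= 1, residual_cutoff > 0,
            cochran_alpha > 0, cochran_alpha < 1)
  if (!is.null(loq) && (is.null(names(loq)) || any(!nzchar(names(loq)))))
    abort("`loq` must be a named numeric vector (biomarker -> limit).")
  structure(
    list(biomarkers = as.character(biomarkers),
         covariates = as.character(covariates),
         transform = transform,
         z = z,
         attenuation = attenuation,
         n_boot = as.integer(n_boot),
         boot_type = boot_type,
         residual_cutoff = residual_cutoff,
         residual_type = residual_type,
         cochran_alpha = cochran_alpha,
         iterative_screen = isTRUE(iterative_screen),
         loq = loq,
         seed = as.integer(seed)),
    class = "biovar_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [analysis_config()].
#' @return A `biovar_config` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  if (!is.null(raw$loq)) raw$loq <- unlist(raw$loq)
  if (!is.null(raw$transform) && length(raw$transform) > 1)
    raw$transform <- unlist(raw$transform)
  do.call(analysis_config, raw)
}

#' @export
print.biovar_config <- function(x, ...) {
  cat("<biovar analysis config>\n")
  cat("  biomarkers:", if (length(x$biomarkers)) paste(x$biomarkers, collapse = ", ") else "(from data)", "\n")
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  z =", x$z, "| attenuation =", paste(x$attenuation, collapse = "/"),
      "| bootstrap B =", x$n_boot, "\n")
  cat("  residual cutoff =", x$residual_cutoff, "(", x$residual_type, ")",
      "| Cochran alpha =", x$cochran_alpha, "\n")
  invisible(x)
}
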