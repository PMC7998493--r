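#' Read a repeated-measures cohort table
#'
#' Reads a long-format CSV (one row per subject and visit), validates it with
#' [validate_cohort()], and applies any limit-of-quantification substitution
#' configured in `config`.
#'
#' @param path CSV file, UTF-8, with a `subject` and an integer `visit`
#'   column plus one column per biomarker and covariate.
#' @param config A [analysis_config()] object; its `biomarkers`, `covariates`
#'   and `loq` entries drive validation and substitution. When `biomarkers`
#'   is empty, every numeric column other than `visit` and the declared
#'   covariates is treated as a biomarker.
#' @param n_visits Declared number of visits `V`; visit indices outside
#'   `1..V` are rejected. Default 3, the usual short-panel design.
#'
#' @return A tibble of class `biovar_cohort` with attributes `biomarkers`,
#'   `covariates`, `n_visits` and `loq_substitutions` (a tibble listing every
#'   raised cell).
#' @export
read_cohort <- function(path, config = analysis_config(), n_visits = 3L) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(data)
  if (nrow(prob) > 0)
    abort(paste0("malformed cohort file: ", nrow(prob), " parse problem(s), first at line ",
                 prob$row[1], " (", prob$expected[1], ")"))
  validate_cohort(data, config = config, n_visits = n_visits)
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a repeated-measures table: unique
#' (subject, visit) pairs, visit indices within `1..n_visits`, strictly
#' positive (or missing) biomarker values, binary contraceptive-use flags.
#' Values below a configured limit of quantification are raised to the limit
#' and recorded.
#'
#' @inheritParams read_cohort
#' @param data A data frame with `subject`, `visit` and value columns.
#' @return The validated tibble (see [read_cohort()]).
#' @export
validate_cohort <- function(data, config = analysis_config(), n_visits = 3L) {
  data <- tibble::as_tibble(data)
  need <- setdiff(c("subject", "visit"), names(data))
  if (length(need))
    abort(paste0("cohort table lacks required column(s): ", paste(need, collapse = ", ")))
  if (!is.numeric(data$visit) || any(data$visit %% 1 != 0, na.rm = TRUE))
    abort("`visit` must hold integer indices.")
  data$visit <- as.integer(data$visit)
  if (any(is.na(data$visit)) || any(data$visit < 1L | data$visit > n_visits))
    abort(paste0("visit indices must lie in 1..", n_visits, "."))

  dup <- duplicated(data[c("subject", "visit")])
  if (any(dup)) {
    d <- data[dup, c("subject", "visit")][1, ]
    abort(paste0("duplicate (subject, visit) pair: subject ", d$subject,
                 ", visit ", d$visit, "."))
  }

  covariates <- intersect(config$covariates, names(data))
  biomarkers <- config$biomarkers
  if (!length(biomarkers)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    biomarkers <- setdiff(num, c("visit", covariates))
  }
  missing_bm <- setdiff(biomarkers, names(data))
  if (length(missing_bm))
    abort(paste0("declared biomarker column(s) absent: ",
                 paste(missing_bm, collapse = ", ")))

  for (bm in biomarkers) {
    if (!is.numeric(data[[bm]]))
      abort(paste0("biomarker `", bm, "` is not numeric; check for malformed rows."))
    bad <- !is.na(data[[bm]]) & data[[bm]] <= 0
    if (any(bad))
      abort(paste0("biomarker `", bm, "` has non-positive value(s); ",
                   "values must be strictly positive or missing."))
  }
  if ("contraceptive" %in% names(data)) {
    cc <- data$contraceptive
    if (!all(is.na(cc) | cc %in% c(0, 1)))
      abort("`contraceptive` must be binary 0/1.")
  }

  subs <- tibble::tibble(subject = character(), visit = integer(),
                         biomarker = character(), original = double(),
                         loq = double())
  if (!is.null(config$loq)) {
    for (bm in intersect(names(config$loq), biomarkers)) {
      lim <- config$loq[[bm]]
      low <- which(!is.na(data[[bm]]) & data[[bm]] < lim)
      if (length(low)) {
        subs <- dplyr::bind_rows(subs, tibble::tibble(
          subject = as.character(data$subject[low]),
          visit = data$visit[low], biomarker = bm,
          original = data[[bm]][low], loq = lim))
        data[[bm]][low] <- lim
      }
    }
  }

  n_miss <- sum(vapply(biomarkers, function(b) sum(is.na(data[[b]])), 0L))
  if (n_miss > 0)
    inform(paste0("cohort has ", n_miss, " missing biomarker cell(s)."))

  structure(data,
            class = unique(c("biovar_cohort", class(data))),
            biomarkers = biomarkers,
            covariates = covariates,
            n_visits = as.integer(n_visits),
            loq_substitutions = subs)
}

#' Convert a wide clinical export to the long cohort format
#'
#' Clinical exports often carry one row per subject with per-visit columns
#' named `<biomarker>_<visit>`. This reshapes such a table to the long
#' one-row-per-subject-and-visit layout the pipeline expects.
#'
#' @param data Wide data frame with a `subject` column and columns named
#'   `<name>_<visit index>`.
#' @param sep Separator between the variable name and the visit index.
#' @return A long tibble with `subject`, `visit` and one column per variable.
#' @export
#' @examples
#' wide <- tibble::tibble(subject = c("a", "b"),
#'                        ua_1 = c(230, 250), ua_2 = c(240, 260))
#' cohort_from_wide(wide)
cohort_from_wide <- function(data, sep = "_") {
  stopifnot("subject" %in% names(data))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(data), -dplyr::all_of("subject"),
    names_to = c(".value", "visit"),
    names_pattern = paste0("^(.*)", sep, "(\\d+)$"))
  long$visit <- as.integer(long$visit)
  dplyr::arrange(long, .data$subject, .data$visit)
}

# columns of the serialized reliability report, in Table-2 order
report_columns <- c(
  "biomarker", "n_subjects", "scale", "icc", "icc_low", "icc_high",
  "cv_g", "cv_t", "ii", "rcv_up", "rcv_down", "symmetric",
  "n_beta_10", "n_beta_20", "category", "singular",
  "icc_adj", "icc_adj_low", "icc_adj_high", "n_boot", "note")

#' Write a reliability report
#'
#' Serializes the per-biomarker reliability table produced by
#' [run_reliability_analysis()] to CSV, with a JSON sidecar holding the same
#' rows at full precision. Undefined cells (for example the index of
#' individuality when the between-subject CV is zero) are rendered as `"/"`,
#' the conventional slash of biological-variation tables.
#'
#' @param rows A reliability tibble (class `biovar_reliability`).
#' @param path Output CSV path; the JSON sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    abort("`rows` must be a non-empty reliability table.")
  out <- tibble::as_tibble(rows)[intersect(report_columns, names(rows))]
  readr::write_csv(out, path, na = "/")
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(out, sidecar, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a reliability report
#'
#' Inverse of [write_reliability_report()]: slash-rendered cells come back as
#' `NA`, numeric columns are restored.
#'
#' @param path CSV path written by [write_reliability_report()].
#' @return A reliability tibble.
#' @export
read_reliability_report <- function(path) {
  if (!file.exists(path)) abort(paste0("report not found: ", path))
  num <- setdiff(report_columns,
                 c("biomarker", "scale", "category", "note", "symmetric", "singular"))
  data <- readr::read_csv(path, na = "/", show_col_types = FALSE, progress = FALSE)
  for (cl in intersect(num, names(data))) data[[cl]] <- as.numeric(data[[cl]])
  for (cl in intersect(c("symmetric", "singular"), names(data)))
    data[[cl]] <- as.logical(data[[cl]])
  for (cl in intersect(c("n_subjects", "n_boot"), names(data)))
    data[[cl]] <- as.integer(data[[cl]])
  class(data) <- c("biovar_reliability", class(data))
  data
}
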