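#' Resting metabolic rate (Müller-type linear equation)
#'
#' Linear adult RMR predictor `RMR = a0 + a_mass * mass + a_age * age +
#' a_sex * sex` in MJ/day. The default coefficient set is the published
#' adult equation of Müller and colleagues (mass coefficient 0.047 MJ/kg,
#' age coefficient −0.01452 MJ/year, sex offset 1.009 MJ for males,
#' intercept 3.21 MJ); any alternative set can be supplied.
#'
#' @param body_mass Body mass in kg.
#' @param age Age in years.
#' @param sex 0 = female, 1 = male.
#' @param coefficients Named list/vector with `intercept`, `mass`, `age`,
#'   `sex` (MJ/day scale).
#' @param unit `"MJ"` (default) or `"kcal"` per day.
#' @return RMR per day, vectorized over the inputs.
#' @export
#' @examples
#' rmr_mueller(62, 23, sex = 0)
rmr_mueller <- function(body_mass, age, sex = 0,
                        coefficients = list(intercept = 3.21, mass = 0.047,
                                            age = -0.01452, sex = 1.009),
                        unit = c("MJ", "kcal")) {
  unit <- match.arg(unit)
  if (any(body_mass <= 0) || any(age <= 0))
    abort("body mass and age must be positive.")
  need <- setdiff(c("intercept", "mass", "age", "sex"), names(coefficients))
  if (length(need))
    abort(paste0("RMR coefficient set lacks: ", paste(need, collapse = ", ")))
  if (!all(sex %in% c(0, 1))) abort("`sex` must be binary 0/1.")
  rmr <- coefficients$intercept + coefficients$mass * body_mass +
    coefficients$age * age + coefficients$sex * sex
  if (unit == "kcal") rmr <- rmr * 239.005736
  rmr
}

#' Physical activity level from an activity diary
#'
#' Total energy expenditure is the sum over diary entries of
#' `MET * RMR-per-minute * minutes`, with the unrecorded remainder of the
#' day assigned a light-effort MET (default 1.4: sitting, studying,
#' reading). PAL = TEE / RMR, which reduces to the time-weighted mean MET —
#' independent of the RMR itself.
#'
#' @param diary Data frame with columns `met` and `minutes` covering at most
#'   1440 minutes.
#' @param rmr Resting metabolic rate per day (any unit; cancels out of the
#'   PAL but scales the returned TEE).
#' @param fill_met MET assumed for unrecorded time.
#' @return List with `pal` (dimensionless) and `tee` (same unit as `rmr`).
#' @export
#' @examples
#' diary <- tibble::tibble(met = c(0.95, 6), minutes = c(480, 60))
#' pal_from_diary(diary, rmr = 5.8)
pal_from_diary <- function(diary, rmr = 1, fill_met = 1.4) {
  stopifnot(all(diary$met > 0), all(diary$minutes > 0))
  total_min <- sum(diary$minutes)
  if (total_min > 1440) abort("diary exceeds 1440 minutes in a day.")
  met_minutes <- sum(diary$met * diary$minutes) + fill_met * (1440 - total_min)
  pal <- met_minutes / 1440
  list(pal = pal, tee = pal * rmr)
}

#' Goldberg/Black plausibility cut-offs for reported energy intake
#'
#' The revised Goldberg screen: the ratio of reported energy intake to RMR
#' is plausible when it falls inside `PAL * exp(±z * S / 100)`, where the
#' combined variation over `d` diary days is
#' `S = sqrt(cv_wEI^2 / d + cv_wB^2 + cv_tP^2)` — within-subject variation
#' of energy intake, repeat-measurement variation of the metabolic rate and
#' between-subject variation of PAL, all in percent. The default CVs are
#' Black's suggested 23, 8.5 and 15.
#'
#' @param pal Physical activity level anchoring the band (commonly the
#'   study-population mean).
#' @param d Number of diary days.
#' @param cv_wei Within-subject CV of energy intake, percent.
#' @param cv_wb Repeat-measurement CV of the metabolic rate, percent.
#' @param cv_tp Between-subject CV of PAL, percent.
#' @param z Band multiplier (1.96 for a 95% band; Black's ±2 variant via
#'   `z = 2`).
#' @return List with `low`, `high` (EI:RMR cut-offs) and `s` (the combined
#'   percentage SD).
#' @export
#' @examples
#' goldberg_cutoffs(pal = 1.58, d = 3)
goldberg_cutoffs <- function(pal, d, cv_wei = 23, cv_wb = 8.5, cv_tp = 15,
                             z = 1.96) {
  stopifnot(pal > 0, d >= 1, cv_wei >= 0, cv_wb >= 0, cv_tp >= 0, z > 0)
  s <- sqrt(cv_wei^2 / d + cv_wb^2 + cv_tp^2)
  list(low = pal * exp(-z * s / 100), high = pal * exp(z * s / 100), s = s)
}

#' Classify an energy-intake report
#'
#' @param energy_intake Reported energy intake per day.
#' @param rmr Resting metabolic rate per day (same unit).
#' @param cutoffs List with `low` and `high` from [goldberg_cutoffs()].
#' @return `"low"`, `"plausible"` or `"high"`, vectorized.
#' @export
classify_reporting <- function(energy_intake, rmr, cutoffs) {
  if (any(rmr <= 0)) abort("`rmr` must be positive.")
  ratio <- energy_intake / rmr
  ifelse(ratio < cutoffs$low, "low",
         ifelse(ratio > cutoffs$high, "high", "plausible"))
}

#' Screen a cohort for energy-intake misreporting
#'
#' Per-row wrapper over [rmr_mueller()], [goldberg_cutoffs()] and
#' [classify_reporting()]: computes each subject-visit RMR from
#' anthropometry, anchors the cut-off band at the per-visit mean PAL (as is
#' customary when screening a study population) and classifies the reported
#' EI:RMR ratio.
#'
#' @param data Data frame with columns `subject`, `visit`, `body_mass`,
#'   `age`, `energy_mj` (reported intake, MJ/d) and `pal`; optional `sex`
#'   (default 0).
#' @param d Diary days behind each report.
#' @param z Band multiplier.
#' @param cv_wei,cv_wb,cv_tp Percentage CVs, see [goldberg_cutoffs()].
#' @return Tibble: input keys plus `rmr_mj`, `ei_rmr_ratio`, `cutoff_low`,
#'   `cutoff_high`, `sdev_total`, `reporter_class`.
#' @export
screen_energy_reporting <- function(data, d = 3, z = 1.96,
                                    cv_wei = 23, cv_wb = 8.5, cv_tp = 15) {
  need <- setdiff(c("subject", "visit", "body_mass", "age", "energy_mj", "pal"),
                  names(data))
  if (length(need))
    abort(paste0("energy screen needs column(s): ", paste(need, collapse = ", ")))
  sex <- if ("sex" %in% names(data)) data$sex else 0
  rmr <- rmr_mueller(data$body_mass, data$age, sex)
  out <- tibble::as_tibble(data)
  out$rmr_mj <- rmr
  out$ei_rmr_ratio <- out$energy_mj / rmr
  out <- dplyr::group_by(out, .data$visit)
  out <- dplyr::mutate(out, .pal_anchor = mean(.data$pal))
  out <- dplyr::ungroup(out)
  cuts <- goldberg_cutoffs(1, d, cv_wei, cv_wb, cv_tp, z)
  out$sdev_total <- cuts$s
  out$cutoff_low <- out$.pal_anchor * cuts$low
  out$cutoff_high <- out$.pal_anchor * cuts$high
  out$reporter_class <- ifelse(out$ei_rmr_ratio < out$cutoff_low, "low",
                               ifelse(out$ei_rmr_ratio > out$cutoff_high,
                                      "high", "plausible"))
  out$.pal_anchor <- NULL
  out
}
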