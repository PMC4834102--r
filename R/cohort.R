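# Cohort construction: eligibility at study start (aged 45-64 in completed
# years), censoring at the 65th birthday month, and the 3-month lead-in used
# only to establish prior medication history.

#' Build the eligible cohort and per-patient observation windows
#'
#' Patients aged 45-64 (completed years) at `study_start` are eligible.
#' Follow-up runs to `study_end` or is censored at the 65th birthday: by
#' default the birthday month itself is excluded, so the window ends on the
#' last day of the month before the month containing the 65th birthday
#' (`include_birthday_month = TRUE` extends it to the end of that month).
#' Patients whose censored window is empty are dropped.
#'
#' @param patients data.frame/data.table with `patient_id`, `date_of_birth`
#'   (Date), `gender`
#' @param study_start,study_end study period bounds (Date)
#' @param include_birthday_month keep dispensings in the 65th-birthday month?
#' @param leadin_months months of pre-study history retained (default 3)
#' @return data.table: `patient_id`, `gender`, `age`, `age_group`,
#'   `leadin_start`, `window_start`, `window_end`
#' @examples
#' pats <- data.frame(patient_id = "p1", date_of_birth = as.Date("1947-06-15"),
#'                    gender = "female")
#' build_cohort(pats, as.Date("2012-01-01"), as.Date("2012-12-31"))
#' @export
build_cohort <- function(patients, study_start = as.Date("2012-01-01"),
                         study_end = as.Date("2012-12-31"),
                         include_birthday_month = FALSE,
                         leadin_months = 3L) {
  stopifnot(study_end >= study_start)
  patients <- as.data.table(patients)
  if (anyNA(patients$date_of_birth))
    stop_bad("missing date of birth for %d patient(s)",
             sum(is.na(patients$date_of_birth)))
  cohort <- copy(patients)
  cohort[, age := age_at(date_of_birth, study_start)]
  cohort <- cohort[age >= 45L & age <= 64L]
  cohort[, age_group := cut(age, breaks = c(44L, 49L, 54L, 59L, 64L),
                            labels = c("45-49", "50-54", "55-59", "60-64"))]
  birthday65 <- add_years(cohort$date_of_birth, 65L)
  censor_end <- if (include_birthday_month)
    add_months(month_floor(birthday65), 1L) - 1L
  else
    month_floor(birthday65) - 1L
  cohort[, window_start := study_start]
  cohort[, window_end := pmin(censor_end, study_end)]
  cohort[, leadin_start := add_months(study_start, -leadin_months)]
  cohort <- cohort[window_end >= window_start]
  cohort[, .(patient_id, gender, age, age_group, leadin_start, window_start,
             window_end)]
}

#' Restrict dispensing events to observation windows and tag their phase
#'
#' Keeps events within `[leadin_start, window_end]` of their patient's
#' window and tags each as `"leadin"` (before `window_start`) or
#' `"observation"`. Events for patients outside the cohort are dropped.
#'
#' @param events data.table of dispensing events (`patient_id`,
#'   `dispense_date`, ...)
#' @param windows output of [build_cohort()]
#' @return events restricted and tagged with a `phase` column
#' @export
filter_events <- function(events, windows) {
  events <- as.data.table(events)
  out <- merge(events,
               windows[, .(patient_id, leadin_start, window_start,
                           window_end)],
               by = "patient_id")
  out <- out[dispense_date >= leadin_start & dispense_date <= window_end]
  out[, phase := fifelse(dispense_date < window_start, "leadin",
                         "observation")]
  out[, c("leadin_start", "window_start", "window_end") := NULL]
  out[]
}
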