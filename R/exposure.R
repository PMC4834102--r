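# Exposure reconstruction. Monthly claims carry no days-supply field, so
# continuous use is inferred by chaining dispensings of the same drug class:
# consecutive dispensings no more than `gap_tolerance_days` apart belong to
# one episode, and the final dispensing is assumed to cover
# `default_coverage_days` further days. The defaults (63 = two missed monthly
# cycles; 28 = one standard monthly supply) are configuration.

#' Build continuous-use exposure episodes
#'
#' Events must already be classified (a `class_id` column, e.g. from the
#' internal classifier or a join against [resolve_class()]). Episodes are
#' maximal runs of same patient x class events whose consecutive dispense
#' dates differ by at most `gap_tolerance_days`;
#' `end_date = last dispense + default_coverage_days - 1` and
#' `duration_days = end_date - start_date + 1`.
#'
#' @param events data.table with `patient_id`, `class_id`, `dispense_date`,
#'   `drug_code`, and optionally `quantity`, `strength_mg`
#' @param gap_tolerance_days maximum gap between chained dispensings (days)
#' @param default_coverage_days days of supply attributed to a dispensing
#' @return data.table of episodes: `patient_id`, `class_id`, `start_date`,
#'   `end_date`, `n_dispensings`, `duration_days`, `drug_codes`
#'   (list column), `mean_daily_dose_mg` (`NA` when any strength missing)
#' @export
build_episodes <- function(events, gap_tolerance_days = 63L,
                           default_coverage_days = 28L) {
  stopifnot(gap_tolerance_days >= 0L, default_coverage_days >= 1L)
  events <- copy(as.data.table(events))  # work on a copy: we add helper cols
  if (!nrow(events))
    return(data.table(patient_id = character(), class_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_dispensings = integer(), duration_days = integer(),
                      drug_codes = list(),
                      mean_daily_dose_mg = numeric()))
  if (is.null(events$quantity)) events[, quantity := NA_real_]
  if (is.null(events$strength_mg)) events[, strength_mg := NA_real_]
  setorder(events, patient_id, class_id, dispense_date)
  events[, gap := as.integer(dispense_date - shift(dispense_date)),
         by = .(patient_id, class_id)]
  events[, episode_idx := cumsum(is.na(gap) | gap > gap_tolerance_days),
         by = .(patient_id, class_id)]
  ep <- events[, {
    end_date <- max(dispense_date) + default_coverage_days - 1L
    dur <- as.integer(end_date - min(dispense_date)) + 1L
    dose_total <- sum(quantity * strength_mg)
    .(start_date = min(dispense_date), end_date = end_date,
      n_dispensings = .N, duration_days = dur,
      drug_codes = list(sort(unique(drug_code))),
      mean_daily_dose_mg = if (anyNA(dose_total)) NA_real_ else
        dose_total / dur)
  }, by = .(patient_id, class_id, episode_idx)]
  ep[, episode_idx := NULL]
  ep[]
}

#' Mean daily dose of an exposure episode
#'
#' Total dispensed drug mass divided by episode duration:
#' sum(quantity x strength_mg) / duration_days. Returns `NA` (dose-unknown;
#' dose-conditional rules then never trigger) when any contributing event
#' lacks quantity or strength.
#'
#' @param episode one-row episode as returned by [build_episodes()]
#' @param events the dispensing events belonging to that episode
#' @return mg/day, or `NA_real_`
#' @export
mean_daily_dose <- function(episode, events) {
  events <- as.data.table(events)
  tot <- sum(events$quantity * events$strength_mg)
  if (anyNA(tot)) return(NA_real_)
  tot / episode$duration_days
}

#' Calendar-month drug-class occupancy
#'
#' One record per patient x calendar month x class listing the distinct
#' chemical-level codes (full ATC code / full BNF entry) dispensed that
#' month; the substrate for same-month co-prescription and duplication
#' checks.
#'
#' @param events classified events (a `class_id` column)
#' @return data.table: `patient_id`, `calendar_month` ("YYYY-MM"),
#'   `class_id`, `distinct_chemicals` (list column), `n_chemicals`,
#'   `n_events`
#' @export
month_occupancy <- function(events) {
  events <- as.data.table(events)
  if (!nrow(events))
    return(data.table(patient_id = character(), calendar_month = character(),
                      class_id = character(), distinct_chemicals = list(),
                      n_chemicals = integer(), n_events = integer()))
  events[, .(distinct_chemicals = list(sort(unique(drug_code))),
             n_chemicals = uniqueN(drug_code), n_events = .N),
         by = .(patient_id, calendar_month = month_key(dispense_date),
                class_id)]
}
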