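# Declarative criterion engine. Five structural rule categories cover the
# shipped explicit criteria: DURATION (episode longer than a threshold),
# DOSE_DURATION (supra-maintenance dose AND long duration), CO_PRESCRIPTION
# (target class dispensed in a calendar month with none of the required
# companion classes), FIRST_LINE (new user starts the target class without a
# preferred alternative having been tried, judged against the lead-in and any
# earlier in-window history), and DUPLICATION (two or more distinct chemicals
# of one class inside a calendar month). All thresholds are tested with
# strict inequalities: ">4 weeks" flags at 29 days, never 28.

rule_target_episodes <- function(rule, episodes) {
  episodes[episodes$class_id == rule$target_class, ]
}

# Each flag_* helper is vectorised over patients and returns the distinct
# patient_ids the rule flags; the exported per-patient eval_* wrappers and
# evaluate_cohort() share this single implementation.
flag_duration <- function(rule, episodes) {
  ep <- rule_target_episodes(rule, episodes)
  unique(ep$patient_id[ep$duration_days > rule$max_duration_days])
}

flag_dose_duration <- function(rule, episodes, vocab, system) {
  ep <- rule_target_episodes(rule, episodes)
  ep <- ep[ep$duration_days > rule$max_duration_days &
             !is.na(ep$mean_daily_dose_mg), ]
  if (!nrow(ep)) return(character())
  # Episode threshold: the highest maintenance dose among involved chemicals
  # (an episode must exceed every involved drug's maintenance dose to flag).
  thr <- vapply(ep$drug_codes, function(codes) {
    th <- vapply(codes, dose_threshold, 0, vocab = vocab, system = system)
    if (anyNA(th)) NA_real_ else max(th)
  }, 0)
  if (anyNA(thr)) {
    miss <- unique(unlist(ep$drug_codes[is.na(thr)]))
    warning(sprintf("criterion %s: no dose threshold for %s; episodes skipped",
                    rule$criterion_id, paste(miss, collapse = ", ")),
            call. = FALSE)
  }
  keep <- !is.na(thr) & ep$mean_daily_dose_mg > thr
  unique(ep$patient_id[keep])
}

flag_coprescription <- function(rule, occupancy) {
  target <- occupancy[occupancy$class_id == rule$target_class,
                      c("patient_id", "calendar_month")]
  if (!nrow(target)) return(character())
  covered <- occupancy[occupancy$class_id %in% unlist(rule$required_classes),
                       c("patient_id", "calendar_month")]
  violating <- target[!covered, on = c("patient_id", "calendar_month")]
  unique(violating$patient_id)
}

flag_first_line <- function(rule, episodes, events) {
  ep <- rule_target_episodes(rule, episodes)
  if (!is.null(rule$max_duration_days))
    ep <- ep[ep$duration_days > rule$max_duration_days, ]
  if (!nrow(ep)) return(character())
  history_classes <- c(rule$target_class,
                       unlist(rule$preferred_alternative_classes))
  hist <- events[events$class_id %in% history_classes,
                 c("patient_id", "dispense_date")]
  first_hist <- if (nrow(hist))
    hist[, .(first_date = min(dispense_date)), by = patient_id]
  else data.table(patient_id = character(),
                  first_date = as.Date(character()))
  ep <- merge(ep, first_hist, by = "patient_id", all.x = TRUE)
  # new-user condition: nothing from the target or alternative classes was
  # dispensed before the episode started (lead-in or earlier in-window)
  new_user <- is.na(ep$first_date) | ep$first_date >= ep$start_date
  unique(ep$patient_id[new_user])
}

flag_duplication <- function(rule, occupancy) {
  occ <- occupancy[occupancy$class_id == rule$target_class &
                     occupancy$n_chemicals >= 2L, ]
  unique(occ$patient_id)
}

flag_rule <- function(rule, episodes, occupancy, events, vocab, system) {
  switch(rule$category,
         DURATION = flag_duration(rule, episodes),
         DOSE_DURATION = flag_dose_duration(rule, episodes, vocab, system),
         CO_PRESCRIPTION = flag_coprescription(rule, occupancy),
         FIRST_LINE = flag_first_line(rule, episodes, events),
         DUPLICATION = flag_duplication(rule, occupancy),
         stop_bad("unknown rule category: %s", rule$category))
}

#' Evaluate a duration criterion for one patient
#'
#' TRUE iff any episode of the rule's target class lasts strictly longer
#' than `max_duration_days`.
#'
#' @param rule a criterion rule (element of `vocab$rules`)
#' @param episodes the patient's episodes from [build_episodes()]
#' @return logical scalar
#' @export
eval_duration_rule <- function(rule, episodes) {
  stopifnot(rule$category == "DURATION")
  length(flag_duration(rule, episodes)) > 0L
}

#' Evaluate a dose-plus-duration criterion for one patient
#'
#' TRUE iff some target-class episode exceeds `max_duration_days` AND its
#' mean daily dose is strictly above the involved drug's maintenance dose.
#' Dose-unknown episodes never trigger; drugs absent from the dose table are
#' skipped with a warning.
#'
#' @inheritParams eval_duration_rule
#' @param vocab a `pip_vocabulary` (supplies the dose-threshold table)
#' @param system "ATC" or "BNF"
#' @return logical scalar
#' @export
eval_dose_duration_rule <- function(rule, episodes, vocab,
                                    system = c("ATC", "BNF")) {
  stopifnot(rule$category == "DOSE_DURATION")
  length(flag_dose_duration(rule, episodes, vocab, match.arg(system))) > 0L
}

#' Evaluate a co-prescription criterion for one patient
#'
#' TRUE iff some calendar month has at least one target-class dispensing and
#' zero dispensings of every required companion class.
#'
#' @inheritParams eval_duration_rule
#' @param occupancy the patient's [month_occupancy()] table
#' @return logical scalar
#' @export
eval_coprescription_rule <- function(rule, occupancy) {
  stopifnot(rule$category == "CO_PRESCRIPTION")
  length(flag_coprescription(rule, occupancy)) > 0L
}

#' Evaluate a first-line criterion for one patient
#'
#' TRUE iff a target-class episode starts with no prior dispensing of the
#' target class or any preferred alternative class (looking back over the
#' lead-in and earlier observation events), and exceeds `max_duration_days`
#' when the rule sets one (unset: any new use triggers).
#'
#' @inheritParams eval_duration_rule
#' @param events the patient's classified events, all phases
#' @return logical scalar
#' @export
eval_first_line_rule <- function(rule, episodes, events) {
  stopifnot(rule$category == "FIRST_LINE")
  length(flag_first_line(rule, episodes, as.data.table(events))) > 0L
}

#' Evaluate a same-month duplication criterion for one patient
#'
#' TRUE iff some calendar month contains two or more distinct chemical codes
#' of the target class.
#'
#' @inheritParams eval_coprescription_rule
#' @return logical scalar
#' @export
eval_duplication_rule <- function(rule, occupancy) {
  stopifnot(rule$category == "DUPLICATION")
  length(flag_duplication(rule, occupancy)) > 0L
}

derive_profile_summary <- function(profiles, rules, duplication_in_any_pip) {
  counted <- names(rules)[vapply(rules, function(r)
    isTRUE(duplication_in_any_pip) || isTRUE(r$counts_in_any_pip), NA)]
  flag_mat <- as.matrix(profiles[, counted, with = FALSE])
  profiles[, n_pip := as.integer(rowSums(flag_mat))]
  profiles[, any_pip := n_pip >= 1L]
  profiles[, pip_category := cut(n_pip, breaks = c(-1L, 0L, 1L, 2L, Inf),
                                 labels = c("0", "1", "2", "3+"))]
  dup_rules <- names(rules)[vapply(rules, function(r)
    r$category == "DUPLICATION", NA)]
  if (length(dup_rules)) {
    dup_mat <- as.matrix(profiles[, dup_rules, with = FALSE])
    profiles[, any_duplication := rowSums(dup_mat) >= 1L]
  } else profiles[, any_duplication := FALSE]
  profiles[]
}

#' Screen a whole cohort against the rule set
#'
#' Runs the full screening pass: classifies events against the vocabulary,
#' restricts them to observation windows, builds observation-phase exposure
#' episodes and month occupancy, and evaluates every rule. Episodes and
#' occupancy are built from observation-phase events only; lead-in events
#' feed exclusively the first-line lookback.
#'
#' @param events dispensing events (`patient_id`, `dispense_date`,
#'   `drug_code`, `quantity`, `strength_mg`)
#' @param windows cohort windows from [build_cohort()]
#' @param vocab a `pip_vocabulary`
#' @param system coding system of `events`, "ATC" or "BNF"
#' @param gap_tolerance_days,default_coverage_days episode parameters, see
#'   [build_episodes()]
#' @param require_any_dispensing restrict the denominator to patients with at
#'   least one observation-phase dispensing (the convention for claims
#'   denominators)? Default TRUE.
#' @param duplication_in_any_pip should duplication flags count toward
#'   `n_pip`/`any_pip`? Default FALSE: duplication is summarised separately
#'   (`any_duplication`).
#' @return data.table with one row per denominator patient: a logical column
#'   per criterion, plus `n_pip`, `any_pip`, `pip_category`,
#'   `any_duplication`
#' @export
evaluate_cohort <- function(events, windows, vocab,
                            system = c("ATC", "BNF"),
                            gap_tolerance_days = 63L,
                            default_coverage_days = 28L,
                            require_any_dispensing = TRUE,
                            duplication_in_any_pip = FALSE) {
  system <- match.arg(system)
  events <- filter_events(as.data.table(events), windows)
  classified <- classify_events(events, vocab, system)
  obs <- classified[classified$phase == "observation", ]
  episodes <- build_episodes(obs, gap_tolerance_days, default_coverage_days)
  occupancy <- month_occupancy(obs)
  denom_ids <- if (require_any_dispensing)
    sort(unique(events$patient_id[events$phase == "observation"]))
  else sort(windows$patient_id)
  profiles <- data.table(patient_id = denom_ids)
  for (rule in vocab$rules) {
    flagged <- flag_rule(rule, episodes, occupancy, classified, vocab, system)
    profiles[, (rule$criterion_id) := patient_id %in% flagged]
  }
  derive_profile_summary(profiles, vocab$rules, duplication_in_any_pip)
}

#' Evaluate all rules for a single patient
#'
#' Per-patient counterpart of [evaluate_cohort()] operating on
#' pre-built inputs; used mainly for audit and testing.
#'
#' @param rules named list of criterion rules (`vocab$rules`)
#' @param episodes the patient's observation-phase episodes
#' @param occupancy the patient's observation-phase month occupancy
#' @param events the patient's classified events, all phases
#' @param vocab a `pip_vocabulary`
#' @param system "ATC" or "BNF"
#' @param duplication_in_any_pip as in [evaluate_cohort()]
#' @return one-row data.table profile
#' @export
evaluate_patient <- function(rules, episodes, occupancy, events, vocab,
                             system = c("ATC", "BNF"),
                             duplication_in_any_pip = FALSE) {
  system <- match.arg(system)
  events <- as.data.table(events)
  ids <- unique(c(episodes$patient_id, occupancy$patient_id,
                  events$patient_id))
  stopifnot("inputs must belong to one patient" = length(ids) <= 1L)
  profile <- data.table(patient_id = if (length(ids)) ids else NA_character_)
  for (rule in rules) {
    flagged <- flag_rule(rule, episodes, occupancy, events, vocab, system)
    profile[, (rule$criterion_id) := length(flagged) > 0L]
  }
  derive_profile_summary(profile, rules, duplication_in_any_pip)
}
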