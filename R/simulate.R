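# Synthetic dispensing-data generator. Emulates the structure of monthly
# claims extracts: a registry of adults aged 45-64 at study start, a 12-month
# study year plus 3-month lead-in, and per-patient dispensing streams in
# either coding dialect. Criterion-positive and criterion-negative patterns
# can be planted at configurable rates; plantings follow a fixed day-offset
# schedule inside the patient's observation window, with the schedules of
# rules that share drug classes separated by more than the episode gap
# tolerance (63 days) or assigned distinct calendar months, so that planted
# labels are exactly recoverable by the engine when background dispensing is
# off. Background dispensing is a per-class per-month Bernoulli process over
# drug classes no rule reads, so it perturbs polypharmacy but never the
# criterion flags.

#' Simulation configuration
#'
#' Defaults state the emulated world: study year 2012 with a 3-month
#' lead-in; 49.4% female; age-band weights 28.5/25.9/22.1/23.5% over
#' 45-49/50-54/55-59/60-64 (uniform within band); planted criterion rates
#' matching the published criterion prevalences of the full-population
#' dataset (the tricyclic first-line rate, unprinted, is set to 1%);
#' background dispensing calibrated so that about 20.3% of patients meet the
#' polypharmacy definition; 28-unit packs of 10 mg units (PPI plantings use
#' 20 mg units and double packs to exceed the maintenance dose).
#'
#' @param n_patients registry size
#' @param seed integer RNG seed
#' @param study_start,study_end study window (Dates)
#' @param female_fraction proportion female
#' @param age_band_weights weights over the four 5-year age bands
#' @param coding_system "ATC" or "BNF"
#' @param planted_rates named proportions: patients planted positive per
#'   criterion
#' @param negative_rates named proportions: patients planted with hard
#'   boundary negatives per criterion
#' @param polypharmacy_target target proportion meeting the polypharmacy
#'   definition through background dispensing (0 disables background)
#' @param bg_monthly_rate monthly dispensing probability for a background
#'   class a patient uses
#' @return a `pip_sim_config` list
#' @export
sim_config <- function(n_patients = 1000L, seed = 1L,
                       study_start = as.Date("2012-01-01"),
                       study_end = as.Date("2012-12-31"),
                       female_fraction = 0.494,
                       age_band_weights = c(`45-49` = 0.285, `50-54` = 0.259,
                                            `55-59` = 0.221,
                                            `60-64` = 0.235),
                       coding_system = c("ATC", "BNF"),
                       planted_rates = c(
                         opioid_no_laxative = 0.069,
                         ppi_high_dose_gt8w = 0.069,
                         benzo_gt_4w = 0.029,
                         first_gen_antihistamine_first_line_gt7d = 0.025,
                         zdrug_gt_4w = 0.025,
                         nsaid_gt_3m = 0.014,
                         tca_first_line = 0.010,
                         dup_opioids = 0.037,
                         dup_benzodiazepines = 0.012,
                         dup_nsaids = 0.004,
                         dup_stimulant_laxatives = 0.001),
                       negative_rates = NULL,
                       polypharmacy_target = 0.203,
                       bg_monthly_rate = 0.8) {
  coding_system <- match.arg(coding_system)
  if (is.null(negative_rates))
    negative_rates <- stats::setNames(rep(0.02, length(planted_rates)),
                                      names(planted_rates))
  stopifnot(n_patients >= 1L, study_end > study_start,
            female_fraction >= 0, female_fraction <= 1,
            all(planted_rates >= 0), all(planted_rates <= 1),
            all(negative_rates >= 0),
            polypharmacy_target >= 0, polypharmacy_target < 1,
            bg_monthly_rate >= 0, bg_monthly_rate <= 1)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 study_start = study_start, study_end = study_end,
                 female_fraction = female_fraction,
                 age_band_weights = age_band_weights / sum(age_band_weights),
                 coding_system = coding_system,
                 planted_rates = planted_rates,
                 negative_rates = negative_rates,
                 polypharmacy_target = polypharmacy_target,
                 bg_monthly_rate = bg_monthly_rate),
            class = "pip_sim_config")
}

# Deterministic chemical-level codes for a class: first member prefix plus a
# fixed suffix; k = 1 or 2 selects distinct chemicals of the same class.
sim_code <- function(vocab, class_id, system, k = 1L) {
  tab <- vocab$classes
  px <- tab$prefix[tab$class_id == class_id & tab$system == system][1L]
  if (is.na(px)) stop_bad("class %s has no %s prefixes", class_id, system)
  if (system == "ATC") paste0(px, c("01", "05")[k])
  else paste0(px, c(".1", ".2")[k])
}

#' Generate a synthetic patient registry
#'
#' Deterministic given the config seed. Ages at `study_start` follow the
#' configured band weights (uniform within band); date of birth is uniform
#' within the implied one-year interval.
#'
#' @param config a [sim_config()]
#' @return data.table: `patient_id`, `date_of_birth`, `gender`
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "pip_sim_config"))
  withr::with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_patients
  band_lo <- c(45L, 50L, 55L, 60L)
  band <- sample.int(4L, n, replace = TRUE, prob = config$age_band_weights)
  age <- band_lo[band] + sample.int(5L, n, replace = TRUE) - 1L
  dob_hi <- add_years(config$study_start, -age)
  dob_lo <- add_years(config$study_start, -(age + 1L)) + 1L
  span <- as.integer(dob_hi - dob_lo)
  dob <- dob_lo + floor(runif(n) * (span + 1L))
  data.table(patient_id = sprintf("P%06d", seq_len(n)),
             date_of_birth = dob,
             gender = fifelse(runif(n) < config$female_fraction,
                              "female", "male"))
}

# Planting schedule: fixed day offsets from window_start. Rules sharing a
# drug class are separated by > 63 days (episode gap tolerance) or distinct
# calendar months so plantings never interact. An entry is only emitted when
# the patient's window is long enough to hold it (needed_days).
plant_schedule <- function(criterion_id, positive) {
  s <- switch(criterion_id,
    benzo_gt_4w = if (positive)
      list(days = c(0L, 30L), class = "benzodiazepines")
    else list(days = 0L, class = "benzodiazepines"),
    zdrug_gt_4w = if (positive)
      list(days = c(40L, 70L), class = "z_drugs")
    else list(days = 45L, class = "z_drugs"),
    nsaid_gt_3m = if (positive)
      list(days = c(80L, 115L, 143L), class = "nsaids")
    else list(days = c(80L, 142L), class = "nsaids"),
    NULL)
  s
}

plant_events_one <- function(window, criterion_id, positive, vocab, system) {
  pid <- window$patient_id
  w0 <- window$window_start
  wlen <- as.integer(window$window_end - w0) + 1L
  ev <- function(days, code, quantity = 28, strength = 10)
    data.table(patient_id = pid, dispense_date = w0 + days,
               drug_code = code, quantity = quantity, strength_mg = strength)
  code <- function(class_id, k = 1L) sim_code(vocab, class_id, system, k)
  fits <- function(need) wlen >= need

  simple <- plant_schedule(criterion_id, positive)
  if (!is.null(simple)) {
    need <- max(simple$days) + 1L
    if (!fits(need)) return(NULL)
    return(ev(simple$days, code(simple$class)))
  }
  switch(criterion_id,
    ppi_high_dose_gt8w = {
      days <- if (positive) c(150L, 180L) else c(150L, 178L)
      if (!fits(max(days) + 1L)) return(NULL)
      ev(days, code("ppi"), quantity = 56, strength = 20)
    },
    opioid_no_laxative = {
      if (!fits(206L)) return(NULL)
      out <- ev(205L, code("strong_opioids"))
      if (!positive)
        out <- rbind(out, ev(205L, code("stimulant_laxatives")))
      out
    },
    first_gen_antihistamine_first_line_gt7d = {
      if (!fits(236L)) return(NULL)
      out <- ev(235L, code("first_gen_antihistamines"))
      if (!positive)
        out <- rbind(out, data.table(
          patient_id = pid, dispense_date = window$leadin_start + 10L,
          drug_code = code("second_gen_antihistamines"),
          quantity = 28, strength_mg = 10))
      out
    },
    tca_first_line = {
      if (!fits(266L)) return(NULL)
      out <- ev(265L, code("tca"))
      if (!positive)
        out <- rbind(out, data.table(
          patient_id = pid, dispense_date = window$leadin_start + 20L,
          drug_code = code("ssri"), quantity = 28, strength_mg = 10))
      out
    },
    dup_opioids = {
      if (!fits(300L)) return(NULL)
      codes <- if (positive) c(code("strong_opioids", 1L),
                               code("strong_opioids", 2L))
      else rep(code("strong_opioids", 1L), 2L)
      # laxative cover keeps the co-prescription rule quiet this month
      rbind(ev(c(299L, 299L), codes), ev(299L, code("osmotic_laxatives")))
    },
    dup_benzodiazepines = {
      if (!fits(96L)) return(NULL)
      codes <- if (positive) c(code("benzodiazepines", 1L),
                               code("benzodiazepines", 2L))
      else rep(code("benzodiazepines", 1L), 2L)
      ev(c(95L, 95L), codes)
    },
    dup_nsaids = {
      if (!fits(11L)) return(NULL)
      codes <- if (positive) c(code("nsaids", 1L), code("nsaids", 2L))
      else rep(code("nsaids", 1L), 2L)
      ev(c(10L, 10L), codes)
    },
    dup_stimulant_laxatives = {
      if (!fits(330L)) return(NULL)
      codes <- if (positive) c(code("stimulant_laxatives", 1L),
                               code("stimulant_laxatives", 2L))
      else rep(code("stimulant_laxatives", 1L), 2L)
      ev(c(329L, 329L), codes)
    },
    stop_bad("unknown criterion_id: %s", criterion_id)
  )
}

#' Plant a criterion-positive dispensing pattern
#'
#' Emits events guaranteed to trigger `criterion_id` under the engine's
#' operationalisation, inside the patient's observation window. Returns
#' `NULL` when the window (censoring) is too short to hold the pattern.
#'
#' @param window one-row observation window from [build_cohort()]
#' @param criterion_id id of a shipped rule
#' @param vocab a `pip_vocabulary`
#' @param system coding system of the emitted codes
#' @return data.table of dispensing events, or `NULL`
#' @export
plant_criterion_positive <- function(window, criterion_id, vocab,
                                     system = c("ATC", "BNF")) {
  system <- match.arg(system)
  if (!criterion_id %in% names(vocab$rules))
    stop_bad("unknown criterion_id: %s", criterion_id)
  plant_events_one(window, criterion_id, TRUE, vocab, system)
}

#' Plant a hard criterion-negative dispensing pattern
#'
#' Emits events that exercise the criterion's drug classes but sit exactly
#' at the rule boundary (28-day episode for ">4 weeks", 56 days for
#' ">8 weeks", 90 days for ">3 months", same-month laxative cover, an
#' alternative agent in the lead-in, a repeated rather than distinct
#' chemical) and are guaranteed NOT to trigger it.
#'
#' @inheritParams plant_criterion_positive
#' @return data.table of dispensing events, or `NULL`
#' @export
plant_criterion_negative <- function(window, criterion_id, vocab,
                                     system = c("ATC", "BNF")) {
  system <- match.arg(system)
  if (!criterion_id %in% names(vocab$rules))
    stop_bad("unknown criterion_id: %s", criterion_id)
  plant_events_one(window, criterion_id, FALSE, vocab, system)
}

# Background classes: vocabulary classes no shipped rule reads, so
# background dispensing exercises polypharmacy without touching flags.
background_classes <- function(vocab) {
  used <- unique(unlist(lapply(vocab$rules, function(r)
    c(r$target_class, unlist(r$required_classes),
      unlist(r$preferred_alternative_classes)))))
  setdiff(unique(vocab$classes$class_id), used)
}

# Solve the per-class use probability q so that the expected share of
# patients with >= 4 qualifying classes hits the polypharmacy target:
# P(Binom(n_classes, q * p3) >= 4) = target, where p3 is the chance a used
# class accrues >= 3 dispensings over 12 months.
calibrate_background <- function(target, n_classes, monthly_rate,
                                 n_months = 12L) {
  if (target <= 0 || monthly_rate <= 0) return(0)
  p3 <- 1 - stats::pbinom(2L, n_months, monthly_rate)
  f <- function(q) 1 - stats::pbinom(3L, n_classes, q * p3) - target
  if (f(1) < 0)
    stop_bad("polypharmacy target %.3f unreachable with %d background classes",
             target, n_classes)
  uniroot(f, c(0, 1), tol = 1e-9)$root
}

generate_background <- function(windows, vocab, config) {
  classes <- background_classes(vocab)
  q <- calibrate_background(config$polypharmacy_target, length(classes),
                            config$bg_monthly_rate)
  if (q == 0 || !nrow(windows)) return(NULL)
  system <- config$coding_system
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i]
    months <- seq(month_floor(w$leadin_start), month_floor(w$window_end),
                  by = "month")
    uses <- classes[runif(length(classes)) < q]
    if (!length(uses)) next
    grid <- CJ(class_id = uses, month = months)
    grid <- grid[runif(nrow(grid)) < config$bg_monthly_rate]
    if (!nrow(grid)) next
    last <- pmin(add_months(grid$month, 1L) - 1L, w$window_end)
    day <- grid$month +
      floor(runif(nrow(grid)) * (as.integer(last - grid$month) + 1L))
    rows[[i]] <- data.table(
      patient_id = w$patient_id, dispense_date = day,
      drug_code = vapply(grid$class_id, sim_code, "", vocab = vocab,
                         system = system),
      quantity = 28, strength_mg = 10)
  }
  rbindlist(rows)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws the registry, builds observation windows, plants
#' criterion-positive and criterion-negative patterns independently per
#' patient x criterion at the configured rates, adds background dispensing,
#' and returns the ground-truth planting labels alongside the data.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()]
#' @param vocab vocabulary/rule set (default: shipped)
#' @return list: `patients`, `windows`, `events`, `truth` (patient x
#'   criterion 0/1, planted positive), `planted_negative` (same shape),
#'   `config`
#' @export
generate_dataset <- function(config, vocab = load_vocabulary()) {
  stopifnot(inherits(config, "pip_sim_config"))
  withr::with_seed(config$seed, {
    patients <- generate_population_impl(config)
    windows <- build_cohort(patients, config$study_start, config$study_end)
    system <- config$coding_system
    crits <- names(config$planted_rates)
    stopifnot(all(crits %in% names(vocab$rules)))

    truth <- data.table(patient_id = windows$patient_id)
    negative <- data.table(patient_id = windows$patient_id)
    planted <- list()
    for (cr in crits) {
      u <- runif(nrow(windows))
      p_pos <- config$planted_rates[[cr]]
      p_neg <- config$negative_rates[[cr]] %||% 0
      status <- fifelse(u < p_pos, 1L, fifelse(u < p_pos + p_neg, -1L, 0L))
      got <- logical(nrow(windows))
      for (i in which(status != 0L)) {
        evs <- plant_events_one(windows[i], cr, status[i] == 1L, vocab,
                                system)
        if (!is.null(evs)) {
          planted[[length(planted) + 1L]] <- evs
          got[i] <- TRUE
        }
      }
      truth[, (cr) := as.integer(status == 1L & got)]
      negative[, (cr) := as.integer(status == -1L & got)]
    }
    events <- rbindlist(c(planted,
                          list(generate_background(windows, vocab, config))),
                        use.names = TRUE)
    if (!nrow(events))
      events <- data.table(patient_id = character(),
                           dispense_date = as.Date(character()),
                           drug_code = character(), quantity = numeric(),
                           strength_mg = numeric())
    setorder(events, patient_id, dispense_date, drug_code)
    list(patients = patients, windows = windows, events = events,
         truth = truth, planted_negative = negative, config = config)
  })
}

#' Write a synthetic dataset to delimited text
#'
#' Registry, events and truth table as CSV with ISO-8601 dates.
#'
#' @param dataset output of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "events.csv", "truth.csv"))
  fwrite(dataset$patients, paths[1L], dateTimeAs = "ISO")
  fwrite(dataset$events, paths[2L], dateTimeAs = "ISO")
  fwrite(dataset$truth, paths[3L], dateTimeAs = "ISO")
  invisible(paths)
}
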