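# Orchestration: simulate (or load) -> cohort -> screen -> analyse ->
# report, writing plain-CSV tables, a run log, and a manifest with config
# and rule-set hashes plus row counts per stage, so a run is auditable and
# reproducible from its output directory alone.

#' Assemble the patient-level analysis table
#'
#' Joins criterion profiles with demographics and the polypharmacy
#' indicator, with modelling-ready factor references (male, age 45-49,
#' no polypharmacy).
#'
#' @param profiles output of [evaluate_cohort()]
#' @param windows output of [build_cohort()]
#' @param polypharmacy output of [compute_polypharmacy()]
#' @return data.table, one row per denominator patient
#' @export
build_analysis_table <- function(profiles, windows, polypharmacy) {
  tab <- merge(profiles,
               windows[, .(patient_id, gender, age, age_group)],
               by = "patient_id")
  tab <- merge(tab, polypharmacy, by = "patient_id", all.x = TRUE)
  tab[is.na(n_classes_ge3), n_classes_ge3 := 0L]
  tab[is.na(polypharmacy), polypharmacy := FALSE]
  tab[, gender := factor(gender, levels = c("male", "female"))]
  tab[, age_group := factor(age_group,
                            levels = c("45-49", "50-54", "55-59", "60-64"))]
  tab[]
}

hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full screening pipeline
#'
#' Simulates a dataset (or loads one from CSV), builds the cohort, screens
#' it against the rule set, computes polypharmacy, fits the regressions,
#' and writes every table plus `manifest.json` and `log.txt` to `out_dir`.
#' Deterministic given the simulation seed.
#'
#' @param out_dir output directory (created if needed)
#' @param config a [sim_config()]; used when `events_path` is `NULL`
#' @param events_path,patients_path optional CSV paths of an existing
#'   dataset (columns as written by [write_dataset()]); both or neither
#' @param vocab_path vocabulary/rule configuration file
#' @param include_birthday_month see [build_cohort()]
#' @param require_any_dispensing,duplication_in_any_pip see
#'   [evaluate_cohort()]
#' @param gap_tolerance_days,default_coverage_days see [build_episodes()]
#' @param ci_method "wald" or "wilson"
#' @param fit_regression fit the logistic models? (needs outcome and
#'   covariate variation; default TRUE)
#' @return invisibly, a list with the in-memory tables and file paths
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         events_path = NULL, patients_path = NULL,
                         vocab_path = default_vocabulary_path(),
                         include_birthday_month = FALSE,
                         require_any_dispensing = TRUE,
                         duplication_in_any_pip = FALSE,
                         gap_tolerance_days = 63L,
                         default_coverage_days = 28L,
                         ci_method = "wald", fit_regression = TRUE) {
  if (!file.exists(vocab_path))
    stop_bad("vocabulary config not found: %s", vocab_path)
  if (xor(is.null(events_path), is.null(patients_path)))
    stop_bad("events_path and patients_path must be given together")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("[%s] pipeline start\n", format(Sys.time())), file = log_path)
  say <- function(fmt, ...) {
    cat(sprintf(paste0("[%s] ", fmt, "\n"), format(Sys.time()), ...),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_bad("stage '%s' failed: %s", name, conditionMessage(e)))
    say("stage %-12s ok (%.2fs)", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  vocab <- stage("vocabulary", load_vocabulary(vocab_path))
  if (is.null(events_path)) {
    dataset <- stage("simulate", generate_dataset(config, vocab))
    patients <- dataset$patients
    events <- dataset$events
  } else {
    dataset <- NULL
    patients <- stage("load", fread(patients_path,
                                    colClasses = c(patient_id = "character")))
    patients[, date_of_birth := as.Date(date_of_birth)]
    events <- fread(events_path, colClasses = c(patient_id = "character",
                                                drug_code = "character"))
    events[, dispense_date := as.Date(dispense_date)]
  }
  windows <- stage("cohort",
                   build_cohort(patients, config$study_start,
                                config$study_end,
                                include_birthday_month = include_birthday_month))
  say("registry %d patients; cohort %d (excluded %d)",
      nrow(patients), nrow(windows), nrow(patients) - nrow(windows))
  profiles <- stage("screen",
                    evaluate_cohort(events, windows, vocab,
                                    system = config$coding_system,
                                    gap_tolerance_days = gap_tolerance_days,
                                    default_coverage_days = default_coverage_days,
                                    require_any_dispensing = require_any_dispensing,
                                    duplication_in_any_pip = duplication_in_any_pip))
  obs_events <- filter_events(events, windows)[phase == "observation"]
  poly <- stage("polypharmacy",
                compute_polypharmacy(obs_events, config$coding_system))
  analysis <- stage("analysis_table",
                    build_analysis_table(profiles, windows, poly))
  counts <- stage("prevalence", pip_count_table(profiles, method = ci_method))
  crit_prev <- stage("criterion_prevalence",
                     criterion_prevalence_table(profiles, vocab$rules,
                                                method = ci_method))
  regression <- NULL
  if (fit_regression && length(unique(analysis$any_pip)) == 2L)
    regression <- stage("regression", fit_logistic(analysis))
  else say("regression skipped (disabled or outcome has no variation)")

  paths <- list(flag_table = file.path(out_dir, "flag_table.csv"),
                analysis_table = file.path(out_dir, "analysis_table.csv"),
                pip_count_table = file.path(out_dir, "pip_count_table.csv"),
                criterion_prevalence = file.path(out_dir,
                                                 "criterion_prevalence.csv"),
                odds_ratios = file.path(out_dir, "odds_ratios.csv"))
  fwrite(flag_table(profiles), paths$flag_table)
  fwrite(analysis, paths$analysis_table, dateTimeAs = "ISO")
  fwrite(counts, paths$pip_count_table)
  fwrite(crit_prev, paths$criterion_prevalence)
  if (!is.null(regression)) fwrite(regression, paths$odds_ratios)
  if (!is.null(dataset)) write_dataset(dataset, file.path(out_dir, "data"))

  cfg_path <- file.path(out_dir, "config.json")
  cfg_json <- unclass(config)
  cfg_json$study_start <- format(config$study_start)
  cfg_json$study_end <- format(config$study_end)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    config_hash = hash_file(cfg_path),
    ruleset_hash = hash_file(vocab_path),
    coding_system = config$coding_system,
    row_counts = list(registry = nrow(patients), cohort = nrow(windows),
                      events = nrow(events), denominator = nrow(profiles)),
    toggles = list(include_birthday_month = include_birthday_month,
                   require_any_dispensing = require_any_dispensing,
                   duplication_in_any_pip = duplication_in_any_pip,
                   ci_method = ci_method))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline done")
  invisible(list(windows = windows, profiles = profiles, analysis = analysis,
                 pip_count_table = counts, criterion_prevalence = crit_prev,
                 regression = regression, paths = paths,
                 manifest = manifest))
}

# 0/1 flag table for CSV export.
flag_table <- function(profiles) {
  out <- copy(profiles)
  flags <- setdiff(names(out), c("patient_id", "pip_category"))
  for (cl in flags)
    if (is.logical(out[[cl]])) out[, (cl) := as.integer(get(cl))]
  out[, pip_category := as.character(pip_category)]
  out[]
}
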