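# Brute-force reference implementations, kept independent of the package
# internals: episode grouping by connected components of the pairwise
# within-gap graph (the engine chains consecutive dispensings instead), and
# per-rule checks as plain loops over months / episode sets.

# Connected components of the graph joining any two dispense dates <= gap
# apart; each component is an episode [min, max + coverage - 1].
oracle_episodes <- function(dates, gap = 63L, coverage = 28L) {
  n <- length(dates)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(as.integer(dates[i] - dates[j])) <= gap &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(k) {
    d <- dates[comp == k]
    list(idx = which(comp == k), start = min(d),
         end = max(d) + coverage - 1L,
         duration = as.integer(max(d) - min(d)) + coverage)
  })
}

oracle_class_of <- function(codes) {
  CODE_POOL$class_id[match(codes, CODE_POOL$code)]
}

# Oracle maintenance-dose threshold for an episode: max over involved codes
# (chemical entry beats the subgroup default).
oracle_ppi_threshold <- function(codes) {
  max(ifelse(startsWith(codes, "A02BC03"), 15, 20))
}

# All criterion flags for ONE patient's raw events, by exhaustive loops.
# `window`: one row of build_cohort() output; events outside
# [leadin_start, window_end] are ignored, lead-in events feed only the
# first-line history.
oracle_patient_flags <- function(events, window, gap = 63L,
                                 coverage = 28L) {
  events <- events[dispense_date >= window$leadin_start &
                     dispense_date <= window$window_end]
  events[, class_id := oracle_class_of(drug_code)]
  obs <- events[dispense_date >= window$window_start]

  episodes_of <- function(cls) {
    sub <- obs[class_id == cls]
    eps <- oracle_episodes(sub$dispense_date, gap, coverage)
    lapply(eps, function(e) {
      rows <- sub[e$idx]
      dose <- sum(rows$quantity * rows$strength_mg) / e$duration
      c(e, list(codes = unique(rows$drug_code), dose = dose))
    })
  }
  months_of <- function(cls) unique(format(
    obs$dispense_date[obs$class_id == cls], "%Y-%m"))

  duration_flag <- function(cls, maxd)
    any(vapply(episodes_of(cls), function(e) e$duration > maxd, NA))
  dose_duration_flag <- function(cls, maxd)
    any(vapply(episodes_of(cls), function(e)
      e$duration > maxd && !is.na(e$dose) &&
        e$dose > oracle_ppi_threshold(e$codes), NA))
  coprescription_flag <- function(cls, required) {
    covered <- unique(unlist(lapply(required, months_of)))
    any(!months_of(cls) %in% covered)
  }
  first_line_flag <- function(cls, alts, maxd = NULL) {
    hist_dates <- events$dispense_date[events$class_id %in% c(cls, alts)]
    any(vapply(episodes_of(cls), function(e) {
      dur_ok <- is.null(maxd) || e$duration > maxd
      dur_ok && !any(hist_dates < e$start)
    }, NA))
  }
  duplication_flag <- function(cls) {
    sub <- obs[class_id == cls]
    any(vapply(months_of(cls), function(m)
      length(unique(sub$drug_code[format(sub$dispense_date,
                                         "%Y-%m") == m])) >= 2L, NA))
  }

  c(opioid_no_laxative = coprescription_flag(
      "strong_opioids", c("osmotic_laxatives", "stimulant_laxatives")),
    ppi_high_dose_gt8w = dose_duration_flag("ppi", 56L),
    benzo_gt_4w = duration_flag("benzodiazepines", 28L),
    first_gen_antihistamine_first_line_gt7d = first_line_flag(
      "first_gen_antihistamines", "second_gen_antihistamines", 7L),
    zdrug_gt_4w = duration_flag("z_drugs", 28L),
    nsaid_gt_3m = duration_flag("nsaids", 90L),
    tca_first_line = first_line_flag("tca", "ssri"),
    dup_opioids = duplication_flag("strong_opioids"),
    dup_benzodiazepines = duplication_flag("benzodiazepines"),
    dup_nsaids = duplication_flag("nsaids"),
    dup_stimulant_laxatives = duplication_flag("stimulant_laxatives"))
}

# any(logical(0)) is FALSE, which is what every rule wants for "no episodes".
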