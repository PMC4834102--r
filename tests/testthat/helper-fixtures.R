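# Shared fixtures, built in code at test time.

library(data.table)

VOCAB <- load_vocabulary()

D <- function(x) as.Date(x)

# One patient guaranteed a full 12-month window under the default study year.
one_patient <- function(id = "p1", dob = "1960-06-15", gender = "female") {
  data.table(patient_id = id, date_of_birth = D(dob), gender = gender)
}

full_window <- function(id = "p1") build_cohort(one_patient(id))

# Quick event constructor; dates relative to the default study start.
ev <- function(id, dates, codes, quantity = 28, strength = 10,
               class_id = NULL) {
  out <- data.table(patient_id = id, dispense_date = D(dates),
                    drug_code = codes, quantity = quantity,
                    strength_mg = strength)
  if (!is.null(class_id)) out[, class_id := class_id]
  out
}

# Exact code -> class lookup used by the oracles and the micro-cohort
# generator; deliberately a flat table, independent of the package's
# prefix-matching vocabulary.
CODE_POOL <- rbindlist(list(
  data.table(class_id = "strong_opioids", code = c("N02AA01", "N02AA05")),
  data.table(class_id = "osmotic_laxatives", code = "A06AD11"),
  data.table(class_id = "stimulant_laxatives", code = c("A06AB02", "A06AB08")),
  data.table(class_id = "ppi", code = c("A02BC01", "A02BC03")),
  data.table(class_id = "benzodiazepines", code = c("N05BA01", "N05CD02")),
  data.table(class_id = "z_drugs", code = c("N05CF01", "N05CF02")),
  data.table(class_id = "first_gen_antihistamines",
             code = c("R06AB04", "R06AD02")),
  data.table(class_id = "second_gen_antihistamines", code = "R06AE07"),
  data.table(class_id = "nsaids", code = c("M01AE01", "M01AB05")),
  data.table(class_id = "tca", code = "N06AA09"),
  data.table(class_id = "ssri", code = "N06AB06")
))

# Random micro-cohort: <= 10 patients, <= 50 events, random ages (including
# censored 64-year-olds), random dates spilling outside the windows, PPI
# strengths that can exceed maintenance dose, occasional missing strength.
random_micro_cohort <- function() {
  n_pat <- sample.int(10L, 1L)
  patients <- data.table(
    patient_id = sprintf("m%02d", seq_len(n_pat)),
    date_of_birth = D("2012-01-01") - 365L * sample(45:64, n_pat, TRUE) -
      sample.int(364L, n_pat, TRUE),
    gender = sample(c("male", "female"), n_pat, TRUE))
  n_ev <- sample.int(50L, 1L)
  idx <- sample.int(nrow(CODE_POOL), n_ev, TRUE)
  events <- data.table(
    patient_id = sample(patients$patient_id, n_ev, TRUE),
    dispense_date = D("2011-09-15") + sample.int(500L, n_ev, TRUE),
    drug_code = CODE_POOL$code[idx],
    quantity = sample(c(28, 56, 84), n_ev, TRUE),
    strength_mg = sample(c(10, 20, 40), n_ev, TRUE))
  events[runif(n_ev) < 0.1, strength_mg := NA_real_]
  list(patients = patients, events = events)
}
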