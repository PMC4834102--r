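# Polypharmacy: the number of distinct medication classes (five-character
# ATC chemical subgroup / BNF section) dispensed at least three times to a
# patient during the observation year; four or more such classes is the
# conventional polypharmacy indicator. Lead-in dispensings do not count.

#' Compute per-patient polypharmacy
#'
#' @param events dispensing events restricted to the observation phase
#'   (e.g. `filter_events(...)[phase == "observation"]`)
#' @param system coding system, "ATC" or "BNF"
#' @param min_dispensings dispensings needed for a class to count (default 3)
#' @param min_classes classes needed for the polypharmacy indicator
#'   (default 4)
#' @return data.table: `patient_id`, `n_classes_ge3`, `polypharmacy`
#' @examples
#' ev <- data.frame(patient_id = "p1",
#'                  dispense_date = as.Date("2012-01-01") + 0:11 * 28,
#'                  drug_code = rep(c("C10AA01", "C09AA02", "C07AB02",
#'                                    "A10BA02"), each = 3))
#' compute_polypharmacy(ev, "ATC")
#' @export
compute_polypharmacy <- function(events, system = c("ATC", "BNF"),
                                 min_dispensings = 3L, min_classes = 4L) {
  system <- match.arg(system)
  events <- as.data.table(events)
  if (!nrow(events))
    return(data.table(patient_id = character(), n_classes_ge3 = integer(),
                      polypharmacy = logical()))
  counts <- events[, .N,
                   by = .(patient_id,
                          class_key = classify_for_polypharmacy(drug_code,
                                                                system))]
  rec <- counts[, .(n_classes_ge3 = sum(N >= min_dispensings)),
                by = patient_id]
  rec[, polypharmacy := n_classes_ge3 >= min_classes]
  setorder(rec, patient_id)
  rec[]
}
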