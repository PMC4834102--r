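# Drug vocabulary: drug classes keyed by code prefixes in two coding systems
# (WHO ATC and BNF dotted section codes), a maintenance-dose threshold table,
# and the declarative criterion rule set. All three are configuration, loaded
# from one JSON file, so the same rule set runs against either dataset dialect.

RULE_CATEGORIES <- c("DURATION", "DOSE_DURATION", "CO_PRESCRIPTION",
                     "FIRST_LINE", "DUPLICATION")

#' Path of the shipped default vocabulary/rule configuration
#'
#' The shipped drug lists follow the class names of the published criteria;
#' dose thresholds are formulary-derived placeholders (the source criteria do
#' not print them) and BNF pseudo-section codes for sub-class splits are
#' synthetic. All are user-overridable via [load_vocabulary()].
#'
#' @return file path of the bundled JSON configuration
#' @export
default_vocabulary_path <- function() {
  system.file("extdata", "prompt_vocabulary.json", package = "pipscreen",
              mustWork = TRUE)
}

#' Load a drug vocabulary and criterion rule set
#'
#' Parses and validates a JSON configuration holding drug classes (with ATC
#' and BNF member prefixes), a maintenance daily-dose threshold table, and
#' the criterion rules. Validation collects *every* problem before failing.
#'
#' @param path configuration file; defaults to the shipped rule set
#' @return an immutable `pip_vocabulary` object (list with `classes`,
#'   `dose_thresholds`, `rules`)
#' @examples
#' vocab <- load_vocabulary()
#' names(vocab$rules)
#' @export
load_vocabulary <- function(path = default_vocabulary_path()) {
  if (!file.exists(path)) stop_bad("vocabulary file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  errs <- character()
  bad <- function(fmt, ...) errs[[length(errs) + 1L]] <<- sprintf(fmt, ...)

  classes <- cfg$classes %||% list()
  if (length(classes) == 0L) bad("config defines zero drug classes")
  ids <- vapply(classes, function(cl) cl$id %||% "", "")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) bad("duplicate class_id: %s", d)
  for (cl in classes) {
    atc <- unlist(cl$atc_prefixes)
    bnf <- unlist(cl$bnf_prefixes)
    if (length(atc) + length(bnf) == 0L)
      bad("class %s has an empty member prefix list", cl$id)
    for (sys in c("ATC", "BNF")) {
      px <- if (sys == "ATC") atc else bnf
      if (length(px) > 1L) {
        nest <- outer(px, px, function(a, b)
          a != b & mapply(prefix_match, a, b, MoreArgs = list(system = sys)))
        if (any(nest))
          bad("class %s has nested member prefixes: %s", cl$id,
              paste(px[which(nest, arr.ind = TRUE)[, 1L]], collapse = ", "))
      }
    }
  }
  class_tab <- data.table(
    class_id = rep(ids, lengths(lapply(classes, function(cl)
      c(unlist(cl$atc_prefixes), unlist(cl$bnf_prefixes))))),
    system = unlist(lapply(classes, function(cl)
      c(rep("ATC", length(unlist(cl$atc_prefixes))),
        rep("BNF", length(unlist(cl$bnf_prefixes)))))),
    prefix = unlist(lapply(classes, function(cl)
      c(unlist(cl$atc_prefixes), unlist(cl$bnf_prefixes))))
  )

  doses <- rbindlist(lapply(cfg$dose_thresholds %||% list(), as.data.table),
                     fill = TRUE)
  if (nrow(doses)) {
    for (i in which(!(doses$maintenance_mg_per_day > 0)))
      bad("non-positive dose threshold for prefix %s", doses$prefix[i])
    if (anyDuplicated(doses[, .(system, prefix)]))
      bad("duplicate dose-threshold prefix entries")
  }

  rules <- lapply(cfg$criteria %||% list(), validate_rule, ids = ids,
                  bad = bad)
  names(rules) <- vapply(rules, function(r) r$criterion_id %||% "", "")
  if (anyDuplicated(names(rules)))
    bad("duplicate criterion_id: %s",
        paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "))

  if (length(errs))
    stop_bad("invalid vocabulary config (%d problems):\n  - %s",
             length(errs), paste(errs, collapse = "\n  - "))

  labels <- vapply(classes, function(cl) cl$label %||% cl$id, "")
  structure(list(classes = class_tab,
                 class_labels = stats::setNames(labels, ids),
                 dose_thresholds = doses, rules = rules),
            class = "pip_vocabulary")
}

validate_rule <- function(r, ids, bad) {
  id <- r$criterion_id %||% "<unnamed>"
  if (is.null(r$category) || !r$category %in% RULE_CATEGORIES)
    bad("criterion %s: unknown category %s", id, r$category %||% "<missing>")
  refs <- c(r$target_class, unlist(r$required_classes),
            unlist(r$preferred_alternative_classes))
  for (cl in setdiff(refs, ids))
    bad("criterion %s references unknown class %s", id, cl)
  need_dur <- identical(r$category, "DURATION") ||
    identical(r$category, "DOSE_DURATION")
  if (need_dur && !(length(r$max_duration_days) && r$max_duration_days > 0))
    bad("criterion %s: category %s needs a positive max_duration_days",
        id, r$category)
  if (identical(r$category, "CO_PRESCRIPTION") &&
      length(unlist(r$required_classes)) == 0L)
    bad("criterion %s: CO_PRESCRIPTION needs required_classes", id)
  r$window <- r$window %||% "same_month"
  r$counts_in_any_pip <- r$counts_in_any_pip %||%
    !identical(r$category, "DUPLICATION")
  r
}

#' @export
print.pip_vocabulary <- function(x, ...) {
  cat(sprintf("<pip_vocabulary> %d classes, %d dose thresholds, %d rules\n",
              length(x$class_labels), nrow(x$dose_thresholds),
              length(x$rules)))
  invisible(x)
}

# Prefix match that respects coding-system structure: ATC is a plain string
# hierarchy; BNF prefixes must align on dotted-component boundaries so that
# "2.4" matches "2.4.1" but not "2.45".
prefix_match <- function(codes, prefix, system) {
  if (system == "ATC") startsWith(codes, prefix)
  else codes == prefix | startsWith(codes, paste0(prefix, "."))
}

#' Resolve a drug code to its vocabulary classes
#'
#' Returns every class whose member prefixes (of the code's coding system)
#' prefix-match the code. Unknown codes resolve to the empty set.
#'
#' @param code drug code string (scalar)
#' @param vocab a `pip_vocabulary`
#' @param system "ATC" or "BNF"
#' @return character vector of class ids (possibly empty), sorted
#' @export
resolve_class <- function(code, vocab, system = c("ATC", "BNF")) {
  system <- match.arg(system)
  keep <- vocab$classes[["system"]] == system
  tab <- vocab$classes[keep, ]
  hit <- vapply(tab$prefix, function(p) prefix_match(code, p, system), NA)
  sort(unique(tab$class_id[hit]))
}

# Vectorised event classification: one output row per (event, matched class).
classify_events <- function(events, vocab, system) {
  keep <- vocab$classes[["system"]] == system
  tab <- vocab$classes[keep, ]
  out <- rbindlist(lapply(seq_len(nrow(tab)), function(i) {
    ev <- events[prefix_match(events$drug_code, tab$prefix[i], system)]
    if (nrow(ev)) ev[, class_id := tab$class_id[i]] else NULL
  }))
  if (nrow(out)) unique(out) else
    cbind(events[0L], data.table(class_id = character()))
}

#' Polypharmacy class key of a drug code
#'
#' Medication classes for the polypharmacy count are the five-character ATC
#' chemical subgroup, or the BNF section (first two dotted components).
#'
#' @param code drug code character vector
#' @param system "ATC" or "BNF"
#' @return character vector of class keys
#' @export
classify_for_polypharmacy <- function(code, system = c("ATC", "BNF")) {
  system <- match.arg(system)
  if (system == "ATC") {
    if (any(nchar(code) < 5L))
      stop_bad("ATC code shorter than 5 characters: %s",
               paste(code[nchar(code) < 5L], collapse = ", "))
    substr(code, 1L, 5L)
  } else {
    vapply(strsplit(code, ".", fixed = TRUE), function(p)
      paste(head(p, 2L), collapse = "."), "")
  }
}

#' Maintenance daily-dose threshold for a drug code
#'
#' Longest-prefix match over the dose-threshold table, mirroring the ATC
#' hierarchy: a chemical-level entry beats a subgroup-level default.
#'
#' @param code drug code (scalar)
#' @param vocab a `pip_vocabulary`
#' @param system "ATC" or "BNF"
#' @return maintenance dose in mg/day, or `NA_real_` when no entry matches
#' @export
dose_threshold <- function(code, vocab, system = c("ATC", "BNF")) {
  system <- match.arg(system)
  tab <- vocab$dose_thresholds
  if (!nrow(tab)) return(NA_real_)
  keep <- tab[["system"]] == system
  tab <- tab[keep, ]
  hit <- vapply(tab$prefix, function(p) prefix_match(code, p, system), NA)
  tab <- tab[hit, ]
  if (!nrow(tab)) return(NA_real_)
  tab$maintenance_mg_per_day[which.max(nchar(tab$prefix))]
}
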