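# Prevalence and determinant analysis: Wald (default) or Wilson intervals
# for prevalence proportions, the PIP-count summary table, and
# unadjusted/adjusted logistic regression for the any-PIP outcome.

#' Prevalence with a 95% confidence interval
#'
#' Percent = 100 n/N rounded half-up to one decimal. The default interval is
#' the Wald normal approximation on the percent scale,
#' 100 (p +/- 1.96 sqrt(p(1-p)/N)), clamped to \[0, 100\] and rounded the
#' same way — the convention that reproduces printed claims-study tables.
#' `method = "wilson"` gives the Wilson score interval instead.
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`
#' @param method "wald" (default) or "wilson"
#' @param conf_level confidence level (default 0.95)
#' @return one-row data.table: `numerator`, `denominator`, `percent`,
#'   `ci_low`, `ci_high`
#' @examples
#' prevalence_ci(93319, 441925)  # 21.1 (21.0, 21.2)
#' @export
prevalence_ci <- function(numerator, denominator,
                          method = c("wald", "wilson"), conf_level = 0.95) {
  method <- match.arg(method)
  if (denominator <= 0) stop_bad("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop_bad("numerator must lie in [0, denominator]")
  p <- numerator / denominator
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / denominator)
    lo <- p - half
    hi <- p + half
  } else {
    n <- denominator
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  }
  data.table(numerator = numerator, denominator = denominator,
             percent = round_half_up(100 * p, 1),
             ci_low = round_half_up(pmax(0, 100 * lo), 1),
             ci_high = round_half_up(pmin(100, 100 * hi), 1))
}

#' PIP-count summary table
#'
#' Prevalence rows for the any-PIP outcome, the PIP-count categories
#' (1, 2, >=3 flagged criteria), and same-month duplication, all over the
#' same denominator. Asserts the partition identity: category counts sum to
#' the any-PIP count.
#'
#' @param profiles output of [evaluate_cohort()]
#' @param method CI method, see [prevalence_ci()]
#' @return data.table with columns `row`, `numerator`, `denominator`,
#'   `percent`, `ci_low`, `ci_high`
#' @export
pip_count_table <- function(profiles, method = "wald") {
  N <- nrow(profiles)
  counts <- c(overall_pip = sum(profiles$any_pip),
              pip_1 = sum(profiles$pip_category == "1"),
              pip_2 = sum(profiles$pip_category == "2"),
              pip_3plus = sum(profiles$pip_category == "3+"),
              duplication = sum(profiles$any_duplication))
  stopifnot("PIP-count categories must partition the any-PIP count" =
              sum(counts[c("pip_1", "pip_2", "pip_3plus")]) ==
              counts[["overall_pip"]])
  if (N == 0L)
    return(data.table(row = names(counts), numerator = 0L, denominator = 0L,
                      percent = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_))
  out <- rbindlist(lapply(counts, prevalence_ci, denominator = N,
                          method = method))
  cbind(data.table(row = names(counts)), out)
}

#' Per-criterion prevalence table
#'
#' @param profiles output of [evaluate_cohort()]
#' @param rules named rule list (`vocab$rules`)
#' @param method CI method, see [prevalence_ci()]
#' @return data.table: `criterion_id`, `numerator`, `denominator`,
#'   `percent`, `ci_low`, `ci_high`
#' @export
criterion_prevalence_table <- function(profiles, rules, method = "wald") {
  N <- nrow(profiles)
  rows <- rbindlist(lapply(names(rules), function(id)
    cbind(data.table(criterion_id = id),
          prevalence_ci(sum(profiles[[id]]), N, method = method))))
  rows[]
}

or_from_fit <- function(fit, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  data.table(term = names(est), or = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se))
}

check_fit <- function(fit, label) {
  if (!fit$converged)
    stop_bad("logistic fit (%s) did not converge after %d IRLS iterations",
             label, fit$iter)
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10))
    stop_bad(paste("logistic fit (%s): fitted probabilities numerically 0/1",
                   "- likely perfect separation; merge sparse levels or",
                   "drop the offending covariate"), label)
  invisible(fit)
}

#' Unadjusted and adjusted logistic regression for a binary outcome
#'
#' Fits one univariate logistic model per covariate (unadjusted odds
#' ratios) and one joint model with all covariates (adjusted), by maximum
#' likelihood. Odds ratios are exponentiated coefficients with Wald 95%
#' intervals on the log-odds scale. Categorical covariates use their first
#' factor level as the reference, which is reported with OR 1 and no CI.
#'
#' @param data data.frame/data.table holding outcome and covariates
#' @param outcome name of the logical/0-1 outcome column
#' @param covariates character vector of covariate column names; factor
#'   levels define references (relevel before calling to change them)
#' @param conf_level confidence level (default 0.95)
#' @return data.table: `term`, `level`, `reference`, `or_unadjusted`,
#'   `ci_low_unadjusted`, `ci_high_unadjusted`, `or_adjusted`,
#'   `ci_low_adjusted`, `ci_high_adjusted`
#' @export
fit_logistic <- function(data, outcome = "any_pip",
                         covariates = c("polypharmacy", "gender",
                                        "age_group"),
                         conf_level = 0.95) {
  data <- as.data.table(data)
  stopifnot(all(c(outcome, covariates) %in% names(data)))
  y <- as.integer(data[[outcome]])
  stopifnot(all(y %in% 0:1))

  term_levels <- function(v) {
    x <- data[[v]]
    if (is.logical(x)) data.table(term = v, level = c("FALSE", "TRUE"),
                                  coef_name = c(NA, paste0(v, "TRUE")),
                                  reference = c(TRUE, FALSE))
    else {
      x <- as.factor(x)
      data.table(term = v, level = levels(x),
                 coef_name = c(NA, paste0(v, levels(x)[-1L])),
                 reference = c(TRUE, rep(FALSE, nlevels(x) - 1L)))
    }
  }
  skeleton <- rbindlist(lapply(covariates, term_levels))

  fill <- function(skel, ors, suffix) {
    skel <- merge(skel, ors, by.x = "coef_name", by.y = "term",
                  all.x = TRUE, sort = FALSE)
    skel[reference == TRUE, or := 1]
    setnames(skel, c("or", "ci_low", "ci_high"),
             paste0(c("or", "ci_low", "ci_high"), "_", suffix))
    skel
  }

  unadj <- rbindlist(lapply(covariates, function(v) {
    fit <- glm(y ~ x, family = binomial(),
               data = data.frame(y = y, x = data[[v]]))
    check_fit(fit, paste("unadjusted:", v))
    ors <- or_from_fit(fit, conf_level)
    ors[, term := sub("^x", v, term)]
    ors
  }))
  adj_fit <- glm(stats::reformulate(covariates, response = outcome),
                 family = binomial(), data = data)
  check_fit(adj_fit, "adjusted")
  adj <- or_from_fit(adj_fit, conf_level)

  out <- fill(skeleton, unadj, "unadjusted")
  out <- fill(out, adj, "adjusted")
  out[, coef_name := NULL]
  setcolorder(out, c("term", "level", "reference"))
  out[]
}
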