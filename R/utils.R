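#' @import data.table
#' @importFrom stats glm binomial coef qnorm rbinom runif vcov uniroot
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; printed epidemiological tables
#' conventionally round half up. Positive inputs only in this package.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Shift a date by whole calendar months
#'
#' Day-of-month is clamped to the target month's length (2012-01-31 plus one
#' month is 2012-02-29).
#'
#' @param date a `Date` vector
#' @param n integer number of months (may be negative)
#' @return `Date` vector
#' @export
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + n
  first <- as.Date(lt)
  lt$mon <- lt$mon + 1L
  last <- as.integer(as.Date(lt) - first)  # days in target month
  first + pmin(day, last) - 1L
}

#' Shift a date by whole years, clamping Feb 29
#' @param date a `Date` vector
#' @param n integer number of years
#' @return `Date` vector
#' @export
add_years <- function(date, n) add_months(date, 12L * n)

month_length <- function(first_of_month) {
  lt <- as.POSIXlt(first_of_month)
  lt$mon <- lt$mon + 1L
  as.integer(as.Date(lt) - first_of_month)
}

#' First day of the calendar month containing `date`
#' @param date a `Date` vector
#' @return `Date` vector
#' @export
month_floor <- function(date) {
  lt <- as.POSIXlt(date)
  lt$mday <- 1L
  as.Date(lt)
}

#' Calendar-month key ("YYYY-MM") of a date
#' @param date a `Date` vector
#' @return character vector
#' @export
month_key <- function(date) format(date, "%Y-%m")

#' Age in completed years at a reference date
#' @param dob date of birth (`Date`)
#' @param at reference date (`Date`)
#' @return integer vector
#' @export
age_at <- function(dob, at) {
  age <- as.POSIXlt(at)$year - as.POSIXlt(dob)$year
  birthday <- add_years(dob, age)
  as.integer(age - (birthday > at))
}

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
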