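#' Construct a standard population
#'
#' @param age_lo,age_hi Integer band bounds (half-open; `NA` upper bound for
#'   the terminal open-ended band).
#' @param weight Non-negative band weights; they are normalised to sum to 1.
#' @return An object of class `standard_population` (a data frame with
#'   columns `age_lo`, `age_hi`, `weight`).
#' @export
standard_population <- function(age_lo, age_hi, weight) {
  stopifnot(length(age_lo) == length(weight),
            length(age_hi) == length(weight))
  if (any(weight < 0)) stop("standard population weights must be >= 0")
  s <- sum(weight)
  if (s <= 0) stop("standard population weights must sum to a positive value")
  out <- data.frame(age_lo = as.integer(age_lo),
                    age_hi = ifelse(is.finite(age_hi), as.integer(age_hi),
                                    NA_integer_),
                    weight = weight / s)
  out <- out[order(out$age_lo), ]
  rownames(out) <- NULL
  class(out) <- c("standard_population", "data.frame")
  out
}

#' WHO World Standard Population
#'
#' The WHO World Standard Population (based on the world average population
#' 2000--2025), bundled as a plain-text data file and normalised so the
#' weights sum to exactly 1.
#'
#' @return A [standard_population] with 5-year bands from 0--4 to 95--99 and
#'   an open-ended 100+ band.
#' @export
who_standard_population <- function() {
  path <- system.file("extdata", "who_standard_population.csv",
                      package = "regcomplete", mustWork = TRUE)
  x <- utils::read.csv(path)
  standard_population(x$age_lo, x$age_hi, x$weight)
}

#' Directly age-standardise a rate table
#'
#' Computes the weighted mean of the band-specific rates using a standard
#' population's age weights.  Standard-population bands are aggregated onto
#' the (possibly coarser) table bands; a standard band that straddles a table
#' band boundary is a band mismatch and errors.  Weights are renormalised
#' over the bands the table covers.  When every band carries a standard
#' error, the standardised rate's variance is propagated as
#' `sum(w^2 * se^2)`.
#'
#' @param table A single-stratum [rate_table].
#' @param std A [standard_population]; defaults to the WHO World Standard.
#' @param level Confidence level for the normal-approximation interval.
#' @return A list with `rate`, `se` and `ci` (lo, hi; `NA` when standard
#'   errors are unavailable).
#' @export
age_standardize <- function(table, std = who_standard_population(),
                            level = 0.95) {
  rt_assert_single(table)
  table <- table[order(table$age_lo), ]
  lo <- table$age_lo
  hi <- table$age_hi
  hi[is.na(hi)] <- Inf
  s_lo <- std$age_lo
  s_hi <- std$age_hi
  s_hi[is.na(s_hi)] <- Inf
  w <- numeric(nrow(table))
  for (k in seq_along(s_lo)) {
    j <- which(lo <= s_lo[k] & s_hi[k] <= hi)
    if (length(j) == 1L) {
      w[j] <- w[j] + std$weight[k]
    } else if (any(lo < s_hi[k] & s_lo[k] < hi)) {
      stop("band mismatch: standard band [", s_lo[k], ",",
           ifelse(is.finite(s_hi[k]), s_hi[k], "Inf"),
           ") straddles the table's bands")
    }
    ## standard bands wholly outside the table's coverage are dropped
  }
  if (sum(w) <= 0) stop("band mismatch: no standard weight maps onto table")
  w <- w / sum(w)
  rate <- sum(w * table$value)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (all(!is.na(table$se))) {
    se <- sqrt(sum(w^2 * table$se^2))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(max(0, rate - z * se), rate + z * se)
  }
  list(rate = rate, se = se, ci = ci)
}

#' Confidence interval for a Poisson rate (Byar's approximation)
#'
#' Byar's approximation to the exact Poisson interval for an event count
#' observed over a known number of person-years.  For `count = 0` the lower
#' limit is 0.
#'
#' @param count Non-negative event count(s).
#' @param py Person-years at risk (> 0).
#' @param level Coverage level, default 0.95.
#' @return A data frame with columns `lo` and `hi` (rates per person-year).
#' @examples
#' poisson_rate_ci(100, 1e5)
#' @export
poisson_rate_ci <- function(count, py, level = 0.95) {
  if (any(py <= 0)) stop("person-years must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  n <- max(length(count), length(py))
  count <- rep_len(count, n)
  py <- rep_len(py, n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- ifelse(count == 0, 0,
               count * (1 - 1 / (9 * count) - z / (3 * sqrt(count)))^3 / py)
  cp1 <- count + 1
  hi <- cp1 * (1 - 1 / (9 * cp1) + z / (3 * sqrt(cp1)))^3 / py
  data.frame(lo = pmax(lo, 0), hi = hi)
}
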