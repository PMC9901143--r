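## Ages used on the single-age grid.  Entry a + 1 of a schedule holds the
## value for the single-year age interval [a, a + 1), a = 0..99, evaluated at
## the interval midpoint a + 0.5.
.grid_ages <- 0:99

#' Construct a single-age schedule
#'
#' @param values Numeric vector of length 100 (ages 0..99).
#' @param measure Measure name (see [rate_table]); values must lie in its
#'   admissible range.
#' @param disease,sex,year Optional stratum labels carried as attributes.
#' @return A numeric vector of class `single_age_schedule`.
#' @export
single_age_schedule <- function(values, measure, disease = NA_character_,
                                sex = NA_character_, year = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) != 100L)
    stop("a single-age schedule has exactly 100 entries (ages 0..99)")
  if (anyNA(values)) stop("single-age schedule contains missing values")
  if (!measure %in% .measures) stop("unknown measure '", measure, "'")
  rng <- .measure_range(measure)
  if (any(values < rng[1] | values > rng[2]))
    stop(measure, " schedule has values outside [", rng[1], ", ", rng[2], "]")
  structure(values, measure = measure, disease = disease, sex = sex,
            year = year, class = "single_age_schedule")
}

#' @export
print.single_age_schedule <- function(x, ...) {
  cat("Single-age schedule (", attr(x, "measure"), "), ages 0-99\n", sep = "")
  print(unclass(x)[seq(1, 100, by = 10)])
  invisible(x)
}

## Knot abscissa for each band: the band midpoint; an open-ended terminal
## band gets its knot at lo + 5 (midpoint of an implied ten-year band).
.band_knots <- function(lo, hi) {
  ifelse(is.na(hi), lo + 5, lo + (hi - lo) / 2)
}

#' Interpolate an age-band table to single ages
#'
#' Fits a natural cubic spline through (band midpoint, band value) knots and
#' evaluates it at the single-age midpoints 0.5, 1.5, ..., 99.5.  Beyond the
#' outer knots the schedule is held constant at the nearest knot value, and
#' the result is clamped to the measure's admissible range (prevalence to
#' \[0, 1\], rates to non-negative values).  An open-ended terminal band's
#' knot sits five years above its lower bound.
#'
#' @param table A single-stratum [rate_table] with at least two bands.
#' @return A [single_age_schedule].
#' @export
to_single_ages <- function(table) {
  key <- rt_assert_single(table)
  table <- table[order(table$age_lo), ]
  if (nrow(table) < 2L)
    stop("need at least two age bands to interpolate")
  x <- .band_knots(table$age_lo, table$age_hi)
  y <- table$value
  fun <- stats::splinefun(x, y, method = "natural")
  xout <- pmin(pmax(.grid_ages + 0.5, min(x)), max(x))  # constant beyond knots
  v <- fun(xout)
  rng <- .measure_range(key$measure)
  v <- pmin(pmax(v, rng[1]), rng[2])
  single_age_schedule(v, key$measure, key$disease, key$sex, key$year)
}

#' Collapse a single-age schedule back onto age bands
#'
#' Per-band arithmetic (or population-weighted) means of the single-age
#' values.
#'
#' @param schedule A [single_age_schedule] or plain numeric vector of
#'   length 100.
#' @param bands Data frame with columns `age_lo`, `age_hi` (`NA` upper bound
#'   for an open-ended terminal band, which absorbs ages up to 99).
#' @param weights Optional per-age population (length 100) used as weights.
#' @return Numeric vector of band means, named `"lo-hi"`.
#' @export
band_means <- function(schedule, bands, weights = NULL) {
  v <- as.numeric(schedule)
  stopifnot(length(v) == 100L)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    stopifnot(length(weights) == 100L, all(weights >= 0))
  }
  lo <- bands$age_lo
  hi <- bands$age_hi
  hi[is.na(hi)] <- 100L
  out <- numeric(length(lo))
  for (b in seq_along(lo)) {
    if (lo[b] < 0 || lo[b] > 99 || hi[b] <= lo[b])
      stop("band ", b, " is empty or outside the 0..99 grid")
    idx <- (lo[b]:min(hi[b] - 1L, 99L)) + 1L
    if (is.null(weights)) {
      out[b] <- mean(v[idx])
    } else {
      wsum <- sum(weights[idx])
      if (wsum <= 0) stop("band ", b, " has zero population weight")
      out[b] <- sum(weights[idx] * v[idx]) / wsum
    }
  }
  names(out) <- paste0(lo, "-", ifelse(hi >= 100, "", hi - 1L))
  out
}
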