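#' @keywords internal
"_PACKAGE"

## Admissible measures and their value ranges.  Rates and hazards are stored
## per person-year throughout; "per 100,000" only ever appears at I/O and in
## formatted reports.
.measures <- c("incidence", "prevalence", "remission", "csmr",
               "all_cause_mortality", "relative_risk")

.measure_range <- function(measure) {
  if (identical(measure, "prevalence")) c(0, 1) else c(0, Inf)
}

.rt_required <- c("disease", "sex", "year", "age_lo", "age_hi",
                  "measure", "value")
.rt_optional <- c("se", "ci_lo", "ci_hi", "count", "person_years")

#' Construct a validated rate table
#'
#' A rate table holds age-band-specific epidemiological quantities for one or
#' more strata (disease x sex x year x measure).  Age bands are half-open
#' `[age_lo, age_hi)` in integer years; the terminal band may be open-ended,
#' encoded by a missing `age_hi`.  Within each stratum the bands must be
#' sorted and non-overlapping, and values must lie in the measure's
#' admissible range (prevalence in \[0, 1\], rates and relative risks
#' non-negative).
#'
#' @param x A data frame with columns `disease`, `sex`, `year`, `age_lo`,
#'   `age_hi`, `measure`, `value` and optionally `se`, `ci_lo`, `ci_hi`,
#'   `count`, `person_years`.  Missing optional columns are added as `NA`.
#' @return An object of class `rate_table` (a data frame).
#' @examples
#' rate_table(data.frame(
#'   disease = "ami", sex = "male", year = 2015,
#'   age_lo = c(0, 30, 65), age_hi = c(30, 65, NA),
#'   measure = "prevalence", value = c(0.0001, 0.004, 0.02)))
#' @export
rate_table <- function(x) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.rt_required, names(x))
  if (length(miss) > 0L)
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in .rt_optional) if (!col %in% names(x)) x[[col]] <- NA_real_
  x <- x[c(.rt_required, .rt_optional)]
  x$disease <- as.character(x$disease)
  x$sex <- as.character(x$sex)
  x$year <- as.integer(x$year)
  x$age_lo <- as.integer(x$age_lo)
  ## open-ended terminal band: NA (or infinite) upper bound
  hi <- suppressWarnings(as.numeric(x$age_hi))
  x$age_hi <- ifelse(is.finite(hi), as.integer(hi), NA_integer_)
  x$measure <- as.character(x$measure)
  for (col in c("value", .rt_optional)) x[[col]] <- as.numeric(x[[col]])
  rownames(x) <- NULL
  class(x) <- c("rate_table", "data.frame")
  validate_rate_table(x)
  x
}

#' Validate a rate table's invariants
#'
#' Checks sexes, measure names, admissible value ranges, band ordering and
#' non-overlap within each stratum, and count/person-years consistency
#' (`value == count / person_years` to 1e-9 relative, where both are given).
#' Errors name the offending row.
#'
#' @param x A `rate_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_rate_table <- function(x) {
  bad_sex <- !x$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("row ", which(bad_sex)[1L], ": sex must be 'male' or 'female'")
  bad_m <- !x$measure %in% .measures
  if (any(bad_m))
    stop("row ", which(bad_m)[1L], ": unknown measure '",
         x$measure[which(bad_m)[1L]], "'")
  if (any(is.na(x$value)))
    stop("row ", which(is.na(x$value))[1L], ": missing value")
  for (j in seq_len(nrow(x))) {
    rng <- .measure_range(x$measure[j])
    if (x$value[j] < rng[1] || x$value[j] > rng[2])
      stop("row ", j, ": ", x$measure[j], " value ", format(x$value[j]),
           " outside admissible range [", rng[1], ", ", rng[2], "]")
  }
  if (any(x$age_lo < 0, na.rm = TRUE))
    stop("row ", which(x$age_lo < 0)[1L], ": age_lo must be >= 0")
  closed <- !is.na(x$age_hi)
  if (any(closed & x$age_hi <= x$age_lo))
    stop("row ", which(closed & x$age_hi <= x$age_lo)[1L],
         ": age_hi must exceed age_lo unless the band is open-ended")
  key <- interaction(x$disease, x$sex, x$year, x$measure, drop = TRUE)
  for (g in split(seq_len(nrow(x)), key)) {
    lo <- x$age_lo[g]; hi <- x$age_hi[g]
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]; g <- g[o]
    n <- length(lo)
    if (anyDuplicated(lo))
      stop("row ", g[which(duplicated(lo))[1L]], ": duplicated age band")
    open <- is.na(hi)
    if (any(open & seq_len(n) != n))
      stop("row ", g[which(open)[1L]],
           ": open-ended band must be the terminal band")
    if (n > 1L) {
      over <- hi[-n] > lo[-1L]
      over[is.na(over)] <- TRUE   # open-ended before another band
      if (any(over))
        stop("row ", g[which(over)[1L] + 1L], ": overlapping age bands (",
             "[", lo[which(over)[1L]], ",", hi[which(over)[1L]], ") and [",
             lo[which(over)[1L] + 1L], ",...))")
    }
  }
  has_cp <- !is.na(x$count) & !is.na(x$person_years)
  if (any(has_cp)) {
    j <- which(has_cp)
    rel <- abs(x$value[j] - x$count[j] / x$person_years[j]) /
      pmax(abs(x$value[j]), .Machine$double.xmin)
    bad <- rel > 1e-9 & !(x$value[j] == 0 & x$count[j] == 0)
    if (any(bad))
      stop("row ", j[which(bad)[1L]],
           ": value does not equal count/person_years")
  }
  invisible(x)
}

#' Read a rate table from CSV
#'
#' Expects the column schema
#' `disease,sex,year,age_lo,age_hi,measure,value,se,ci_lo,ci_hi,count,person_years`
#' (the last five optional; empty cells allowed).  An empty `age_hi` encodes
#' an open-ended terminal band.
#'
#' @param path Path to a CSV file.
#' @param measure Optional measure name; if given, every row must carry it.
#' @return A validated [rate_table].
#' @export
read_rate_table <- function(path, measure = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.rt_required, names(x))
  if (length(miss) > 0L)
    stop("'", path, "' is missing column(s): ", paste(miss, collapse = ", "))
  tab <- rate_table(x)
  if (!is.null(measure) && !all(tab$measure == measure))
    stop("'", path, "' contains measures other than '", measure, "'")
  tab
}

#' Write a rate table to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the table bit-exactly.
#'
#' @param x A `rate_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  out <- as.data.frame(x)
  num <- c("value", .rt_optional)
  for (col in num)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  out$age_hi <- ifelse(is.na(x$age_hi), "", as.character(x$age_hi))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Subset a rate table to one stratum
#'
#' Filters by any combination of disease, sex, year and measure, returning
#' the matching rows sorted by age band.  Errors when nothing matches.
#'
#' @param x A [rate_table].
#' @param disease,sex,year,measure Optional filters.
#' @return A [rate_table] with the matching rows.
#' @export
rt_stratum <- function(x, disease = NULL, sex = NULL, year = NULL,
                       measure = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(disease)) keep <- keep & x$disease == disease
  if (!is.null(sex)) keep <- keep & x$sex == sex
  if (!is.null(year)) keep <- keep & x$year == year
  if (!is.null(measure)) keep <- keep & x$measure == measure
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no rows for stratum ",
         paste(c(disease, sex, year, measure), collapse = "/"))
  out <- out[order(out$age_lo), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

## A single-stratum check used by operations that need one curve.
rt_assert_single <- function(x) {
  key <- unique(x[c("disease", "sex", "year", "measure")])
  if (nrow(key) != 1L)
    stop("expected a single disease/sex/year/measure stratum, found ",
         nrow(key))
  invisible(key)
}

## Bands of a (single-stratum, sorted) table as a data frame lo/hi with the
## open-ended band's hi set to NA.
rt_bands <- function(x) {
  data.frame(age_lo = x$age_lo, age_hi = x$age_hi)
}

#' @export
print.rate_table <- function(x, ...) {
  key <- unique(x[c("disease", "sex", "year", "measure")])
  cat("Rate table: ", nrow(x), " rows, ", nrow(key), " stratum(s)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
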