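#' Assemble a completeness report across strata
#'
#' Combines fitted strata and the observed registry table into (a) an
#' observed/modelled/trend-adjusted rate table, (b) a completeness-ratio
#' table (both untrended and trend-adjusted entries), and (c) one-sided
#' Z-tests for an increase in completeness from the earliest year to each
#' later year within every disease/sex/age-group stratum.
#'
#' @param fits A list of [fit_incidence()] objects (one per
#'   disease/sex/year stratum).
#' @param observed A [rate_table] of observed registry incidence covering
#'   the fitted strata (measure `incidence`, ideally with
#'   `count`/`person_years`).
#' @param config Optional metadata list (stored verbatim; pass the run
#'   seed/config here for reproducibility).
#' @param level Confidence level.
#' @return An object of class `completeness_report` with components
#'   `entries`, `table1`, `table2`, `tests` and `metadata`.
#' @export
build_report <- function(fits, observed, config = list(), level = 0.95) {
  entries <- list()
  t1 <- list()
  for (fit in fits) {
    obs <- rt_stratum(observed, fit$disease, fit$sex, fit$year, "incidence")
    entries[[length(entries) + 1L]] <- completeness(fit, obs, trended = FALSE,
                                                    level = level)
    if (!is.null(fit$incidence$trended))
      entries[[length(entries) + 1L]] <- completeness(fit, obs,
                                                      trended = TRUE,
                                                      level = level)
    t1[[length(t1) + 1L]] <- .table1_rows(fit, obs, level)
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  table1 <- do.call(rbind, t1)
  rownames(table1) <- NULL

  band_lab <- function(lo, hi)
    ifelse(is.na(lo), "total",
           paste0(lo, "-", ifelse(is.na(hi), "+", hi - 1)))
  table2 <- data.frame(
    disease = entries$disease, sex = entries$sex, year = entries$year,
    age_group = band_lab(entries$age_lo, entries$age_hi),
    trended = entries$trended,
    irr = entries$irr, lo = entries$lo, hi = entries$hi,
    irr_2dp = round(entries$irr, 2))

  tests <- .irr_year_tests(entries)
  metadata <- list(package = "regcomplete",
                   version = as.character(utils::packageVersion("regcomplete")),
                   level = level, config = config)
  structure(list(entries = entries, table1 = table1, table2 = table2,
                 tests = tests, metadata = metadata),
            class = "completeness_report")
}

## Observed and modelled rates (per 100,000 person-years) per band + total.
.table1_rows <- function(fit, obs, level) {
  obs <- obs[order(obs$age_lo), ]
  have_counts <- all(!is.na(obs$count)) && all(!is.na(obs$person_years))
  if (have_counts) {
    ci <- poisson_rate_ci(obs$count, obs$person_years, level)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- data.frame(lo = obs$value - z * obs$se, hi = obs$value + z * obs$se)
  }
  br <- fit$band_rates
  n <- nrow(br)
  row <- data.frame(disease = fit$disease, sex = fit$sex, year = fit$year,
                    age_lo = br$age_lo, age_hi = br$age_hi,
                    observed = obs$value, observed_lo = ci$lo,
                    observed_hi = ci$hi, modeled = br$rate,
                    modeled_lo = NA_real_, modeled_hi = NA_real_,
                    modeled_trended = if (is.null(br$rate_trended)) NA_real_
                    else br$rate_trended,
                    modeled_trended_lo = NA_real_,
                    modeled_trended_hi = NA_real_)
  if (!is.null(fit$boot$untrended)) {
    row$modeled_lo <- fit$boot$untrended$ci_rate$lo
    row$modeled_hi <- fit$boot$untrended$ci_rate$hi
  }
  if (!is.null(fit$boot$trended)) {
    row$modeled_trended_lo <- fit$boot$trended$ci_rate$lo
    row$modeled_trended_hi <- fit$boot$trended$ci_rate$hi
  }
  ## total row
  p <- fit$schedules$p
  tot <- data.frame(disease = fit$disease, sex = fit$sex, year = fit$year,
                    age_lo = NA_integer_, age_hi = NA_integer_,
                    observed = NA_real_, observed_lo = NA_real_,
                    observed_hi = NA_real_,
                    modeled = .total_rate(as.numeric(fit$incidence$untrended) *
                                            (1 - p), fit$population),
                    modeled_lo = NA_real_, modeled_hi = NA_real_,
                    modeled_trended = NA_real_,
                    modeled_trended_lo = NA_real_,
                    modeled_trended_hi = NA_real_)
  if (have_counts) {
    ct <- sum(obs$count); pyt <- sum(obs$person_years)
    tot$observed <- ct / pyt
    tci <- poisson_rate_ci(ct, pyt, level)
    tot$observed_lo <- tci$lo; tot$observed_hi <- tci$hi
  }
  if (!is.null(fit$incidence$trended))
    tot$modeled_trended <- .total_rate(as.numeric(fit$incidence$trended) *
                                         (1 - p), fit$population)
  if (!is.null(fit$boot$untrended)) {
    tot$modeled_lo <- fit$boot$untrended$ci_total[1]
    tot$modeled_hi <- fit$boot$untrended$ci_total[2]
  }
  if (!is.null(fit$boot$trended)) {
    tot$modeled_trended_lo <- fit$boot$trended$ci_total[1]
    tot$modeled_trended_hi <- fit$boot$trended$ci_total[2]
  }
  rbind(row, tot)
}

## One-sided tests: earliest year against each later year, within
## disease x sex x trended x age group.
.irr_year_tests <- function(entries) {
  key <- interaction(entries$disease, entries$sex, entries$trended,
                     ifelse(is.na(entries$age_lo), -1L, entries$age_lo),
                     drop = TRUE)
  out <- list()
  for (g in split(seq_len(nrow(entries)), key)) {
    if (length(g) < 2L) next
    g <- g[order(entries$year[g])]
    base <- g[1L]
    for (j in g[-1L]) {
      tst <- tryCatch(ztest_irr_increase(entries[base, ], entries[j, ]),
                      error = function(e) list(z = NA_real_, p = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        disease = entries$disease[base], sex = entries$sex[base],
        trended = entries$trended[base],
        age_group = ifelse(is.na(entries$age_lo[base]), "total",
                           paste0(entries$age_lo[base], "-",
                                  ifelse(is.na(entries$age_hi[base]), "+",
                                         entries$age_hi[base] - 1))),
        year1 = entries$year[base], year2 = entries$year[j],
        irr1 = entries$irr[base], irr2 = entries$irr[j],
        z = tst$z, p = tst$p)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("Completeness report: ", nrow(x$entries), " entries, ",
      if (is.null(x$tests)) 0L else nrow(x$tests), " temporal tests\n",
      sep = "")
  tot <- x$entries[is.na(x$entries$age_lo), ]
  if (nrow(tot) > 0) {
    cat("\nTotal completeness (observed / modelled):\n")
    disp <- data.frame(disease = tot$disease, sex = tot$sex,
                       year = tot$year,
                       branch = ifelse(tot$trended, "trended", "untrended"),
                       irr = sprintf("%.2f (%.2f, %.2f)", tot$irr, tot$lo,
                                     tot$hi))
    print(disp, row.names = FALSE)
  }
  invisible(x)
}

#' Write a completeness report to disk
#'
#' Emits `report.json` (entries, tests, metadata), `table1.csv` (observed
#' and modelled rates, printed per 100,000 person-years) and `table2.csv`
#' (completeness ratios rounded to two decimals, with raw values kept).
#' Output is deterministic given the report.
#'
#' @param report A [build_report()] object.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "completeness_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  jp <- file.path(dir, "report.json")
  jsonlite::write_json(list(entries = report$entries, tests = report$tests,
                            metadata = report$metadata),
                       jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- c(paths, jp)

  t1 <- report$table1
  per1e5 <- function(v) ifelse(is.na(v), "", sprintf("%d", round(1e5 * v)))
  t1out <- data.frame(disease = t1$disease, sex = t1$sex, year = t1$year,
                      age_group = ifelse(is.na(t1$age_lo), "total",
                                         paste0(t1$age_lo, "-",
                                                ifelse(is.na(t1$age_hi), "+",
                                                       t1$age_hi - 1))))
  for (col in c("observed", "observed_lo", "observed_hi", "modeled",
                "modeled_lo", "modeled_hi", "modeled_trended",
                "modeled_trended_lo", "modeled_trended_hi"))
    t1out[[col]] <- per1e5(t1[[col]])
  p1 <- file.path(dir, "table1.csv")
  utils::write.csv(t1out, p1, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p1)

  t2 <- report$table2
  t2out <- t2[c("disease", "sex", "year", "age_group", "trended")]
  t2out$irr <- sprintf("%.2f", t2$irr)
  t2out$lo <- sprintf("%.2f", t2$lo)
  t2out$hi <- ifelse(is.na(t2$hi), "", sprintf("%.2f", t2$hi))
  t2out$irr_raw <- sprintf("%.17g", t2$irr)
  p2 <- file.path(dir, "table2.csv")
  utils::write.csv(t2out, p2, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p2)

  invisible(paths)
}
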