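#' Completeness of reporting as an incidence rate ratio
#'
#' The headline statistic: observed registry incidence divided by modelled
#' ("true") incidence.  The confidence interval uses a normal approximation
#' on the log ratio with
#' `var(log irr) = var_obs / obs^2 + var_mod / mod^2`.
#'
#' @param observed Observed incidence rate(s), per person-year.
#' @param modeled Modelled incidence rate(s), per person-year (> 0).
#' @param var_obs,var_mod Variances of the observed and modelled rates
#'   (default 0; the modelled variance typically comes from bootstrap
#'   replicates).
#' @param level Confidence level.
#' @return A data frame with columns `irr`, `lo`, `hi` and `se_log`.
#' @examples
#' ## per-100,000 rates cancel in the ratio
#' completeness_ratio(69e-5, 146e-5)      # ~0.47
#' @export
completeness_ratio <- function(observed, modeled, var_obs = 0, var_mod = 0,
                               level = 0.95) {
  n <- max(length(observed), length(modeled))
  observed <- rep_len(observed, n); modeled <- rep_len(modeled, n)
  var_obs <- rep_len(var_obs, n); var_mod <- rep_len(var_mod, n)
  if (any(modeled <= 0)) stop("modeled rate must be > 0")
  if (any(observed < 0)) stop("observed rate must be >= 0")
  irr <- observed / modeled
  se_log <- ifelse(observed > 0,
                   sqrt(var_obs / observed^2 + var_mod / modeled^2),
                   NA_real_)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- ifelse(observed > 0, irr * exp(-z * se_log), 0)
  hi <- ifelse(observed > 0, irr * exp(z * se_log), NA_real_)
  data.frame(irr = irr, lo = lo, hi = hi, se_log = se_log)
}

## Extract (irr, se_log) from a completeness entry given as a one-row data
## frame or list; se_log recovered from the CI when absent.
.entry_irr_se <- function(e) {
  irr <- e$irr
  se <- e$se_log
  if (is.null(se) || is.na(se)) {
    if (is.null(e$lo) || is.null(e$hi) || is.na(e$lo) || is.na(e$hi))
      stop("entry carries neither se_log nor a confidence interval")
    se <- (log(e$hi) - log(e$lo)) / (2 * stats::qnorm(0.975))
  }
  c(irr = irr, se_log = se)
}

#' One-sided Z-test for an increase in completeness
#'
#' Tests H1: the incidence rate ratio of the later stratum exceeds that of
#' the earlier one, on the log scale:
#' `z = (log irr2 - log irr1) / sqrt(se1^2 + se2^2)`, `p = 1 - Phi(z)`.
#'
#' @param e1,e2 Completeness entries (rows of [completeness_ratio()] output
#'   or of a report's entries) for the earlier and later period.
#' @return A list with `z` and the one-sided `p`.
#' @export
ztest_irr_increase <- function(e1, e2) {
  a <- .entry_irr_se(e1)
  b <- .entry_irr_se(e2)
  if (a["irr"] <= 0 || b["irr"] <= 0)
    stop("IRRs must be positive for the log-scale test")
  se <- sqrt(a["se_log"]^2 + b["se_log"]^2)
  if (se == 0) stop("zero combined standard error")
  z <- unname((log(b["irr"]) - log(a["irr"])) / se)
  list(z = z, p = 1 - stats::pnorm(z))
}

#' Incidence-to-mortality rate ratio diagnostic
#'
#' Element-wise ratio of observed incidence to cause-specific mortality
#' rates over matching strata, with log-scale normal confidence intervals.
#' Variances come from `se` columns when present, else from Poisson counts
#' (`count / person_years^2`).  A registry that captures most cases of a
#' disease with case fatality below 1 should show ratios above 1; ratios
#' below 1 flag under-ascertainment.
#'
#' @param incidence,mortality [rate_table]s with matching
#'   disease/sex/year/age bands.
#' @param level Confidence level.
#' @return A data frame of strata with `ratio`, `lo`, `hi`.
#' @export
incidence_mortality_ratio <- function(incidence, mortality, level = 0.95) {
  keycols <- c("disease", "sex", "year", "age_lo")
  inc <- as.data.frame(incidence)
  mor <- as.data.frame(mortality)
  mrg <- merge(inc, mor, by = keycols, suffixes = c("_inc", "_mor"))
  if (nrow(mrg) != nrow(inc))
    stop("strata of the incidence and mortality tables do not match")
  if (any(mrg$value_mor <= 0)) stop("zero mortality rate in a stratum")
  var_of <- function(value, se, count, py)
    ifelse(!is.na(se), se^2,
           ifelse(!is.na(count) & !is.na(py), count / py^2, 0))
  v_i <- var_of(mrg$value_inc, mrg$se_inc, mrg$count_inc, mrg$person_years_inc)
  v_m <- var_of(mrg$value_mor, mrg$se_mor, mrg$count_mor, mrg$person_years_mor)
  ratio <- mrg$value_inc / mrg$value_mor
  se_log <- sqrt(v_i / mrg$value_inc^2 + v_m / mrg$value_mor^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- mrg[c(keycols, "age_hi_inc")]
  names(out)[names(out) == "age_hi_inc"] <- "age_hi"
  out$ratio <- ratio
  out$lo <- ratio * exp(-z * se_log)
  out$hi <- ratio * exp(z * se_log)
  out[order(out$disease, out$sex, out$year, out$age_lo), ]
}

#' Completeness entries for one fitted stratum
#'
#' Compares an observed registry incidence table with the modelled rates of
#' an [fit_incidence()] fit, band by band plus a person-year-weighted total
#' row.  Observed variances come from Poisson counts (or `se`); modelled
#' variances from the fit's bootstrap replicates when present.
#'
#' @param fit An `incidence_fit`.
#' @param observed A single-stratum [rate_table] of observed incidence with
#'   the same bands as the fit.
#' @param trended Compare against the trend-adjusted modelled rate?
#'   Defaults to `TRUE` when the fit carries a trend.
#' @param level Confidence level.
#' @param total_age_min Lower age bound of the "total" row (default 0).
#' @return A data frame of class `completeness_entries` with stratum labels,
#'   `age_lo`/`age_hi` (total row flagged by `age_lo = NA`), observed and
#'   modelled rates, `irr`, `lo`, `hi`, `se_log`, `trended`.
#' @export
completeness <- function(fit, observed, trended = NULL, level = 0.95,
                         total_age_min = 0L) {
  stopifnot(inherits(fit, "incidence_fit"))
  rt_assert_single(observed)
  observed <- observed[order(observed$age_lo), ]
  if (!identical(rt_bands(observed), fit$bands))
    stop("observed table's bands differ from the fit's bands")
  if (is.null(trended)) trended <- !is.null(fit$incidence$trended)
  if (trended && is.null(fit$incidence$trended))
    stop("fit has no trended estimate")

  mod_band <- if (trended) fit$band_rates$rate_trended else
    fit$band_rates$rate
  vmod_band <- rep(0, nrow(fit$bands))
  vmod_total <- 0
  bb <- if (trended) fit$boot$trended else fit$boot$untrended
  if (!is.null(bb)) {
    vmod_band <- bb$var_rate
    vmod_total <- bb$var_total
  }

  vobs_band <- ifelse(!is.na(observed$se), observed$se^2,
                      ifelse(!is.na(observed$count) &
                               !is.na(observed$person_years),
                             observed$count / observed$person_years^2, 0))
  bands_cr <- completeness_ratio(observed$value, mod_band,
                                 vobs_band, vmod_band, level)

  ## total row: observed as pooled count/person-years when available,
  ## modelled as the person-year-weighted mean of single-age rates
  i_sched <- as.numeric(if (trended) fit$incidence$trended else
    fit$incidence$untrended)
  mod_total <- .total_rate(i_sched * (1 - fit$schedules$p),
                           fit$population, age_min = total_age_min)
  keep <- observed$age_lo >= total_age_min
  if (all(!is.na(observed$count[keep])) &&
      all(!is.na(observed$person_years[keep]))) {
    ct <- sum(observed$count[keep]); pyt <- sum(observed$person_years[keep])
    obs_total <- ct / pyt
    vobs_total <- ct / pyt^2
  } else {
    w <- if (is.null(fit$population)) rep(1, 100L) else fit$population
    bl <- observed$age_lo; bh <- observed$age_hi; bh[is.na(bh)] <- 100L
    bw <- mapply(function(l, h) sum(w[(l:min(h - 1L, 99L)) + 1L]), bl, bh)
    bw[!keep] <- 0
    obs_total <- sum(bw * observed$value) / sum(bw)
    vobs_total <- sum((bw / sum(bw))^2 * vobs_band)
  }
  tot_cr <- completeness_ratio(obs_total, mod_total, vobs_total, vmod_total,
                               level)

  out <- data.frame(disease = fit$disease, sex = fit$sex, year = fit$year,
                    age_lo = c(observed$age_lo, NA),
                    age_hi = c(observed$age_hi, NA),
                    observed = c(observed$value, obs_total),
                    modeled = c(mod_band, mod_total),
                    rbind(bands_cr, tot_cr),
                    trended = trended)
  rownames(out) <- NULL
  class(out) <- c("completeness_entries", "data.frame")
  out
}
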