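#' Fit the illness-death incidence model to age-band inputs
#'
#' The central estimator: converts age-band prevalence, remission and
#' cause-specific mortality (and optionally all-cause mortality relative
#' risk) into single-age schedules, derives the case-fatality and
#' other-cause mortality hazards, back-calculates the incidence schedule
#' consistent with the prevalence ODE of the three-state illness-death
#' model, optionally re-solves under a secular incidence trend along cohort
#' lines, and optionally attaches bootstrap uncertainty intervals.
#'
#' The primary case-fatality pathway is `f = csmr / p`; where prevalence
#' falls below `eps` the relative-risk pathway (`m = m_all / (1 + p(RR-1))`,
#' `f = m(RR-1)`) is used as a fallback if `relative_risk` and `all_cause`
#' are supplied.  The relative-risk input otherwise only enters the
#' internal-consistency residuals.
#'
#' @param prevalence,remission,csmr Single-stratum [rate_table]s sharing
#'   sex, year and disease, carrying the `prevalence`, `remission` and
#'   `csmr` measures.
#' @param relative_risk,all_cause Optional [rate_table]s with the
#'   `relative_risk` and `all_cause_mortality` measures.
#' @param trend Optional [trend_spec]; when supplied both the untrended and
#'   the trend-adjusted incidence are estimated.
#' @param boot Optional [bootstrap_spec]; when supplied, percentile
#'   bootstrap intervals for the band-level incidence are computed by
#'   perturbing prevalence.
#' @param population Optional person-years per single age (length 100) used
#'   to weight band and total summaries; unweighted means otherwise.
#' @param eps Prevalence floor for the case-fatality ratio.
#' @return An object of class `incidence_fit`.  Key components:
#'   `incidence` (single-age schedules, `untrended` and possibly `trended`),
#'   `band_rates` (per-band incidence hazards and population-scale rates per
#'   person-year), `solution` (the forward-solved life table), `residuals`
#'   (internal-consistency diagnostics) and `boot` (bootstrap results).
#' @seealso [completeness()], [forward_solve()], [invert_incidence()]
#' @export
fit_incidence <- function(prevalence, remission, csmr, relative_risk = NULL,
                          all_cause = NULL, trend = NULL, boot = NULL,
                          population = NULL, eps = 1e-6) {
  key <- rt_assert_single(prevalence)
  for (tab in list(remission, csmr)) {
    k2 <- rt_assert_single(tab)
    if (!identical(k2$sex, key$sex) || !identical(k2$year, key$year))
      stop("input tables do not share sex/year")
  }
  p_s <- to_single_ages(prevalence)
  r_s <- to_single_ages(remission)
  c_s <- to_single_ages(csmr)
  rr_s <- if (!is.null(relative_risk)) to_single_ages(relative_risk)
  ma_s <- if (!is.null(all_cause)) to_single_ages(all_cause)

  m <- numeric(100L)
  f_fallback <- NULL
  if (!is.null(rr_s) && !is.null(ma_s)) {
    rrpath <- case_fatality_from_rr(rr_s, ma_s, p_s)
    m <- rrpath$m
    f_fallback <- pmax(rrpath$f, 0)
  }
  f <- case_fatality_from_csmr(c_s, p_s, eps = eps, fallback = f_fallback)

  p_inv <- pmin(as.numeric(p_s), 1 - 1e-9)
  i_unt <- invert_incidence(p_inv, r_s, f)
  i_tr <- NULL
  if (!is.null(trend)) {
    stopifnot(inherits(trend, "trend_spec"))
    i_tr <- invert_incidence_trended(p_inv, r_s, f, trend, p0 = p_inv[1L])
  }

  hz <- hazard_set(pmax(as.numeric(i_unt), 0), r_s, f, m)
  sol <- forward_solve(hz, p0 = p_inv[1L])
  resid <- consistency_residuals(
    list(p = as.numeric(p_s), csmr = as.numeric(c_s),
         rr = if (!is.null(rr_s)) as.numeric(rr_s)), sol)

  bands <- rt_bands(prevalence[order(prevalence$age_lo), ])
  band_rates <- .band_rate_summary(i_unt, i_tr, p_inv, bands, population)

  boot_res <- NULL
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "bootstrap_spec"))
    boot_res <- list(
      untrended = bootstrap_incidence(prevalence, remission, csmr,
                                      relative_risk = relative_risk,
                                      all_cause = all_cause, trend = NULL,
                                      spec = boot, population = population,
                                      eps = eps),
      trended = if (!is.null(trend))
        bootstrap_incidence(prevalence, remission, csmr,
                            relative_risk = relative_risk,
                            all_cause = all_cause, trend = trend,
                            spec = boot, population = population, eps = eps))
  }

  structure(list(disease = key$disease, sex = key$sex, year = key$year,
                 schedules = list(p = as.numeric(p_s), r = as.numeric(r_s),
                                  csmr = as.numeric(c_s), f = f, m = m,
                                  rr = if (!is.null(rr_s)) as.numeric(rr_s),
                                  m_all = if (!is.null(ma_s)) as.numeric(ma_s)),
                 incidence = list(untrended = i_unt, trended = i_tr),
                 trend = trend, hazards = hz, solution = sol,
                 residuals = resid, bands = bands, band_rates = band_rates,
                 boot = boot_res, population = population,
                 call = match.call()),
            class = "incidence_fit")
}

## Band/total summaries of an incidence schedule, on two scales: the hazard
## among susceptibles and the population-scale rate i (1 - p) (new cases per
## total person-year, the quantity a registry reports).
.band_rate_summary <- function(i_unt, i_tr, p, bands, population) {
  w <- if (is.null(population)) rep(1, 100L) else as.numeric(population)
  out <- data.frame(age_lo = bands$age_lo, age_hi = bands$age_hi)
  out$hazard <- band_means(as.numeric(i_unt), bands, weights = w)
  out$rate <- band_means(as.numeric(i_unt) * (1 - p), bands, weights = w)
  if (!is.null(i_tr)) {
    out$hazard_trended <- band_means(as.numeric(i_tr), bands, weights = w)
    out$rate_trended <- band_means(as.numeric(i_tr) * (1 - p), bands,
                                   weights = w)
  }
  rownames(out) <- NULL
  out
}

## Person-year-weighted total of a single-age rate schedule over bands'
## coverage (used for "total" report rows).
.total_rate <- function(rate_schedule, population = NULL, age_min = 0L) {
  w <- if (is.null(population)) rep(1, 100L) else as.numeric(population)
  idx <- (age_min:99) + 1L
  sum(w[idx] * rate_schedule[idx]) / sum(w[idx])
}

#' @export
print.incidence_fit <- function(x, ...) {
  cat("Illness-death incidence model fit\n")
  cat("  stratum: ", x$disease, "/", x$sex, "/", x$year, "\n", sep = "")
  if (!is.null(x$trend))
    cat("  trend: ", sprintf("%+.1f%%", 100 * x$trend$delta),
        " per year since ", x$trend$base_year, "\n", sep = "")
  tot <- .total_rate(as.numeric(x$incidence$untrended) *
                       (1 - x$schedules$p), x$population)
  cat("  modelled incidence (crude, per 100,000 person-years): ",
      sprintf("%.1f", 1e5 * tot), "\n", sep = "")
  if (!is.null(x$incidence$trended)) {
    tot_t <- .total_rate(as.numeric(x$incidence$trended) *
                           (1 - x$schedules$p), x$population)
    cat("  trend-adjusted:                                     ",
        sprintf("%.1f", 1e5 * tot_t), "\n", sep = "")
  }
  cat("  bands: ", nrow(x$bands), "; bootstrap: ",
      if (is.null(x$boot)) "none" else
        paste0(x$boot$untrended$spec$n_iter, " iterations"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.incidence_fit <- function(object, ...) {
  res <- object$residuals
  structure(list(fit = object,
                 band_rates = object$band_rates,
                 max_p_rel = max(abs(res$p_rel), na.rm = TRUE),
                 max_csmr_rel = max(abs(res$csmr_rel), na.rm = TRUE),
                 floored = sum(attr(object$incidence$untrended, "floored"))),
            class = "summary.incidence_fit")
}

#' @export
print.summary.incidence_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-band modelled incidence (per 100,000 person-years):\n")
  br <- x$band_rates
  disp <- data.frame(band = paste0(br$age_lo, "-",
                                   ifelse(is.na(br$age_hi), "+", br$age_hi - 1)),
                     rate = round(1e5 * br$rate))
  if (!is.null(br$rate_trended))
    disp$rate_trended <- round(1e5 * br$rate_trended)
  print(disp, row.names = FALSE)
  cat("\nConsistency: max |rel. residual| prevalence ",
      format(x$max_p_rel, digits = 3), ", csmr ",
      format(x$max_csmr_rel, digits = 3), "; ", x$floored,
      " age(s) floored at zero incidence\n", sep = "")
  invisible(x)
}

#' @export
coef.incidence_fit <- function(object, ...) {
  br <- object$band_rates
  v <- if (!is.null(br$rate_trended)) br$rate_trended else br$rate
  names(v) <- paste0(br$age_lo, "-", ifelse(is.na(br$age_hi), "+",
                                            br$age_hi - 1))
  v
}

#' @export
fitted.incidence_fit <- function(object, ...) {
  v <- object$incidence$trended
  if (is.null(v)) v <- object$incidence$untrended
  as.numeric(v)
}

#' Predict from a fitted illness-death incidence model
#'
#' @param object An `incidence_fit`.
#' @param ages Integer ages (0..99) at which to evaluate.
#' @param type `"hazard"` (incidence among susceptibles), `"rate"`
#'   (population-scale incidence `i (1-p)`) or `"prevalence"`.
#' @param trended Use the trend-adjusted schedule?  Defaults to `TRUE` when
#'   a trend was fitted.
#' @param ... Unused.
#' @return Named numeric vector over `ages`, per person-year.
#' @export
predict.incidence_fit <- function(object, ages = 0:99,
                                  type = c("hazard", "rate", "prevalence"),
                                  trended = NULL, ...) {
  type <- match.arg(type)
  stopifnot(all(ages >= 0 & ages <= 99))
  if (is.null(trended)) trended <- !is.null(object$incidence$trended)
  if (trended && is.null(object$incidence$trended))
    stop("no trended estimate in this fit")
  i <- as.numeric(if (trended) object$incidence$trended else
    object$incidence$untrended)
  p <- object$schedules$p
  v <- switch(type, hazard = i, rate = i * (1 - p), prevalence = p)
  stats::setNames(v[ages + 1L], ages)
}

#' @export
residuals.incidence_fit <- function(object, ...) object$residuals

#' Plot a fitted illness-death incidence model
#'
#' Two panels: the input and refitted prevalence schedules, and the
#' back-calculated incidence (untrended and, when present, trend-adjusted)
#' on the log-friendly per-100,000 scale.
#'
#' @param x An `incidence_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.incidence_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  age <- 0:99
  graphics::matplot(age, cbind(x$schedules$p, x$solution$p), type = "l",
                    lty = c(1, 2), col = c("black", "red"),
                    xlab = "age", ylab = "prevalence",
                    main = paste(x$disease, x$sex, x$year), ...)
  graphics::legend("topleft", c("input", "refitted"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  inc <- cbind(untrended = as.numeric(x$incidence$untrended),
               trended = if (!is.null(x$incidence$trended))
                 as.numeric(x$incidence$trended))
  graphics::matplot(age, 1e5 * inc, type = "l", lty = 1:2,
                    col = c("blue", "darkgreen"), xlab = "age",
                    ylab = "incidence per 100,000 py",
                    main = "back-calculated incidence", ...)
  if (ncol(inc) == 2)
    graphics::legend("topleft", c("untrended", "trended"), lty = 1:2,
                     col = c("blue", "darkgreen"), bty = "n")
  invisible(x)
}
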