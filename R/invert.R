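#' Back-calculate incidence from prevalence, remission and case fatality
#'
#' Inverts the prevalence ODE of the illness-death model,
#' \deqn{p' = i(1-p) - rp - fp(1-p),}
#' giving \eqn{i(a) = [p'(a) + r(a)p(a) + f(a)p(a)(1-p(a))] / (1-p(a))}.
#' The derivative is taken by centred finite differences on the single-age
#' grid (fourth-order in the interior, second-order beside the ends,
#' one-sided at the grid ends).  Ages where the inversion yields a
#' negative incidence are floored at 0 and flagged in the `"floored"`
#' attribute.
#'
#' @param p Prevalence schedule (length 100, values in \[0, 1\)).
#' @param r Remission schedule (length 100, >= 0).
#' @param f Case-fatality schedule (length 100, >= 0).
#' @return Incidence schedule (length 100) with a logical attribute
#'   `"floored"` marking ages where a negative estimate was clipped.
#' @export
invert_incidence <- function(p, r, f) {
  p <- as.numeric(p); r <- as.numeric(r); f <- as.numeric(f)
  stopifnot(length(p) == 100L, length(r) == 100L, length(f) == 100L)
  if (any(p < 0) || any(p >= 1))
    stop("prevalence must lie in [0, 1) everywhere for the inversion")
  if (any(r < 0) || any(f < 0)) stop("remission and case fatality must be >= 0")
  n <- 100L
  dp <- numeric(n)
  dp[1L] <- p[2L] - p[1L]
  dp[n] <- p[n] - p[n - 1L]
  dp[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / 2
  ## fourth-order centred stencil where both second neighbours exist
  k <- 3:(n - 2L)
  dp[k] <- (-p[k + 2L] + 8 * p[k + 1L] - 8 * p[k - 1L] + p[k - 2L]) / 12
  i <- (dp + r * p + f * p * (1 - p)) / (1 - p)
  floored <- i < 0
  i[floored] <- 0
  attr(i, "floored") <- floored
  i
}

#' Specify a secular incidence trend
#'
#' A constant annual proportional change in incidence since a base year,
#' applied along cohort lines: the hazard a cohort experienced at a past age
#' differs from the current rate by `(1 + delta)` per calendar year of lag,
#' frozen at the base-year level for calendar years before `base_year`.
#'
#' @param delta Annual proportional change (e.g. `-0.02` for a 2 per cent
#'   annual decline); must exceed -1.
#' @param survey_year Calendar year of the cross-section being modelled.
#' @param base_year First calendar year the trend applies (default 2000).
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(delta, survey_year, base_year = 2000L) {
  if (delta <= -1) stop("delta must be > -1")
  if (base_year > survey_year) stop("base_year must not exceed survey_year")
  structure(list(delta = delta, survey_year = as.integer(survey_year),
                 base_year = as.integer(base_year)), class = "trend_spec")
}

#' Past-rate multiplier under a secular trend
#'
#' The factor by which the incidence hazard `lag` years before the survey
#' year differs from the current rate: `(1 + delta)^(-lag)`, with the lag
#' capped at `survey_year - base_year` (rates frozen before the base year).
#'
#' @param trend A [trend_spec].
#' @param lag Years before the survey year (>= 0; fractional allowed).
#' @return Multiplier(s) applied to the current-rate schedule.
#' @examples
#' trend_multiplier(trend_spec(-0.02, 2015), 10)  # (0.98)^-10 ~= 1.2240
#' @export
trend_multiplier <- function(trend, lag) {
  stopifnot(inherits(trend, "trend_spec"))
  eff <- pmin(pmax(lag, 0), trend$survey_year - trend$base_year)
  (1 + trend$delta)^(-eff)
}

#' Cohort-consistent hazard surface under a secular trend
#'
#' Expands a current-rate incidence schedule into the hazard surface
#' experienced by each cohort alive at the survey year: entry `[a + 1,
#' u + 1]` is the incidence hazard the cohort aged `a` at the survey
#' experienced at age `u <= a`, namely `i_current(u)` times the past-rate
#' multiplier at lag `a - u - 0.5` (interval midpoint).  With `delta = 0`
#' every row equals the current schedule.
#'
#' @param i_current Current-rate incidence schedule (length 100).
#' @param trend A [trend_spec].
#' @return A 100 x 100 lower-triangular matrix of class `trend_surface`
#'   (entries with `u > a` are `NA`), with the trend attached as an
#'   attribute.
#' @export
apply_trend <- function(i_current, trend) {
  i_current <- as.numeric(i_current)
  stopifnot(length(i_current) == 100L, inherits(trend, "trend_spec"))
  M <- matrix(NA_real_, 100L, 100L,
              dimnames = list(age = .grid_ages, cohort_age = .grid_ages))
  for (a in 0:99) {
    u <- 0:a
    M[a + 1L, u + 1L] <- i_current[u + 1L] *
      trend_multiplier(trend, pmax(a - u - 0.5, 0))
  }
  structure(M, trend = trend, class = c("trend_surface", "matrix", "array"))
}

## Prevalence at age `a` (at the survey) of the cohort aged `a`, obtained by
## stepping the (S, C) system along the cohort's trended incidence hazards.
## Other-cause mortality cancels out of prevalence and is omitted.
.cohort_prevalence <- function(i_current, r, f, trend, p0 = 0) {
  ## All 100 cohorts are stepped simultaneously: at inner age u, every
  ## cohort with a > u advances one year under its own lagged hazard.
  S <- rep(1 - p0, 100L)
  C <- rep(p0, 100L)
  a <- 0:99
  for (u in 0:98) {
    act <- (u + 2L):100L      # cohorts with survey age a > u (1-based)
    iu <- i_current[u + 1L] *
      trend_multiplier(trend, pmax(a[act] - u - 0.5, 0))
    st <- .sc_at(1, S[act], C[act], iu, r[u + 1L], f[u + 1L], 0)
    S[act] <- st[, 1L]
    C[act] <- st[, 2L]
  }
  ## half-step through each cohort's own current-age interval so the result
  ## sits at the interval midpoint, the single-age schedule convention
  st <- .sc_at(0.5, S, C, i_current, r, f, 0)
  alive <- st[, 1L] + st[, 2L]
  ifelse(alive > 0, st[, 2L] / alive, 0)
}

#' Back-calculate incidence under a secular trend
#'
#' Finds the current-rate incidence schedule whose cohort-consistent hazard
#' surface (see [apply_trend()]) reproduces the observed cross-sectional
#' prevalence.  The system is triangular in age: the prevalence of the
#' cohort aged `a` at the survey depends on the current-rate schedule only
#' at ages up to `a`, and on `i(a)` only through the cohort's final
#' half-year interval.  A single forward sweep therefore inverts it
#' exactly: all cohorts are advanced one interval at a time along their own
#' lagged hazards, and each cohort's current-age incidence is obtained by a
#' monotone one-dimensional root solve as it reaches its survey age.  Ages
#' where even zero incidence overshoots the observed prevalence are floored
#' at 0 and flagged.  With `delta = 0` the untrended inversion is returned
#' unchanged (bit for bit).
#'
#' @inheritParams invert_incidence
#' @param trend A [trend_spec] (or `NULL` for the untrended inversion).
#' @param p0 Birth prevalence.
#' @param i_max Upper bracket for the per-age root solve (per person-year).
#' @return Incidence schedule (length 100) with attributes `"floored"`,
#'   `"converged"` and `"misfit"` (maximum absolute prevalence misfit of
#'   the returned schedule, nonzero only at floored ages).
#' @export
invert_incidence_trended <- function(p, r, f, trend, p0 = 0, i_max = 10) {
  if (is.null(trend) || trend$delta == 0) {
    i0 <- invert_incidence(p, r, f)
    attr(i0, "converged") <- TRUE
    attr(i0, "misfit") <- 0
    return(i0)
  }
  p <- as.numeric(p); r <- as.numeric(r); f <- as.numeric(f)
  stopifnot(length(p) == 100L, length(r) == 100L, length(f) == 100L)
  if (any(p < 0) || any(p >= 1))
    stop("prevalence must lie in [0, 1) everywhere for the inversion")
  if (any(r < 0) || any(f < 0)) stop("remission and case fatality must be >= 0")
  i <- numeric(100L)
  floored <- logical(100L)
  misfit <- 0
  ## running (S, C) state of every cohort a = 0..99, all starting at birth
  S <- rep(1 - p0, 100L)
  C <- rep(p0, 100L)
  ages <- 0:99
  for (a in 0:99) {
    j <- a + 1L
    ## cohort a has reached exact age a; its midpoint prevalence is a
    ## monotone function of its own current-rate incidence i(a)
    g <- function(ii) {
      st <- .sc_at(0.5, S[j], C[j], ii, r[j], f[j], 0)
      st[1L, 2L] / (st[1L, 1L] + st[1L, 2L]) - p[j]
    }
    if (g(0) >= 0) {
      i[j] <- 0
      floored[j] <- g(0) > 0
      misfit <- max(misfit, g(0))
    } else if (g(i_max) <= 0) {
      i[j] <- i_max
      misfit <- max(misfit, -g(i_max))
      warning("trended inversion hit the incidence bracket at age ", a)
    } else {
      i[j] <- stats::uniroot(g, c(0, i_max), tol = 1e-14)$root
    }
    ## advance all older-at-survey cohorts through age interval [a, a+1)
    ## under their own lagged version of the just-solved hazard
    if (a < 99L) {
      act <- (a + 2L):100L
      iu <- i[j] * trend_multiplier(trend, ages[act] - a - 0.5)
      st <- .sc_at(1, S[act], C[act], iu, r[j], f[j], 0)
      S[act] <- st[, 1L]
      C[act] <- st[, 2L]
    }
  }
  attr(i, "floored") <- floored
  attr(i, "converged") <- TRUE
  attr(i, "misfit") <- misfit
  i
}
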