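#' Construct a hazard set for the illness-death model
#'
#' Bundles the four transition hazards of the three-state
#' (healthy/diseased/dead) model, each as a single-age schedule on the 0..99
#' grid: incidence `i` (healthy to diseased), remission `r` (diseased to
#' healthy), case fatality `f` (diseased to cause-specific death) and
#' other-cause mortality `m` (either living state to death from other
#' causes).  All hazards are per person-year and constant within each
#' single-year age interval.
#'
#' @param i,r,f,m Numeric vectors of length 100, all non-negative.
#' @return An object of class `hazard_set`.
#' @export
hazard_set <- function(i, r, f, m) {
  h <- list(i = as.numeric(i), r = as.numeric(r),
            f = as.numeric(f), m = as.numeric(m))
  for (nm in names(h)) {
    if (length(h[[nm]]) != 100L)
      stop("hazard '", nm, "' must have length 100 (ages 0..99)")
    if (anyNA(h[[nm]]) || any(h[[nm]] < 0))
      stop("hazard '", nm, "' contains negative or missing values")
  }
  structure(h, class = "hazard_set")
}

#' @export
print.hazard_set <- function(x, ...) {
  cat("Illness-death hazard set (per person-year), ages 0-99\n")
  s <- sapply(x, function(v) c(min = min(v), max = max(v)))
  print(round(s, 6))
  invisible(x)
}

#' Case fatality from cause-specific mortality and prevalence
#'
#' In the illness-death model the cause-specific mortality rate (cause
#' deaths per person-year in the whole population) equals case fatality
#' times prevalence, so `f = csmr / p`.  Where prevalence falls below `eps`
#' the division is unstable: the fallback schedule (typically from the
#' relative-risk pathway) is used if supplied, otherwise `f` is set to 0
#' with a warning when a positive csmr is being discarded.
#'
#' @param csmr Cause-specific mortality schedule (length 100, >= 0).
#' @param p Prevalence schedule (length 100, in \[0, 1\]).
#' @param eps Prevalence floor below which the ratio is not formed.
#' @param fallback Optional case-fatality schedule used where `p < eps`.
#' @return Case-fatality schedule (length 100).
#' @export
case_fatality_from_csmr <- function(csmr, p, eps = 1e-6, fallback = NULL) {
  csmr <- as.numeric(csmr); p <- as.numeric(p)
  stopifnot(length(csmr) == 100L, length(p) == 100L)
  if (any(csmr < 0)) stop("csmr must be >= 0")
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]")
  low <- p < eps
  if (any(csmr > 0 & p == 0) && is.null(fallback))
    stop("inconsistent inputs: csmr > 0 where prevalence is 0 and no ",
         "fallback case fatality is available")
  f <- numeric(100L)
  f[!low] <- csmr[!low] / p[!low]
  if (any(low)) {
    if (!is.null(fallback)) {
      fallback <- as.numeric(fallback)
      stopifnot(length(fallback) == 100L)
      f[low] <- fallback[low]
    } else if (any(csmr[low] > 0)) {
      warning("prevalence below ", eps, " at ", sum(low & csmr > 0),
              " age(s) with positive csmr; case fatality set to 0 there")
    }
  }
  f
}

#' Case fatality and background mortality from the relative-risk pathway
#'
#' Splits an all-cause mortality schedule into other-cause mortality `m` and
#' case fatality `f` using the all-cause mortality relative risk of cases
#' versus non-cases, `RR = (m + f) / m`.  The population mixture identity
#' `m_all = m (1 - p) + (m + f) p` gives
#' `m = m_all / (1 + p (RR - 1))` and `f = m (RR - 1)`.
#'
#' @param rr Relative-risk schedule (length 100, >= 0).
#' @param m_all All-cause mortality schedule (length 100, >= 0).
#' @param p Prevalence schedule (length 100, in \[0, 1\]).
#' @return A list with schedules `f` and `m`.
#' @export
case_fatality_from_rr <- function(rr, m_all, p) {
  rr <- as.numeric(rr); m_all <- as.numeric(m_all); p <- as.numeric(p)
  stopifnot(length(rr) == 100L, length(m_all) == 100L, length(p) == 100L)
  if (any(rr < 0)) stop("relative risk must be >= 0")
  if (any(m_all < 0)) stop("all-cause mortality must be >= 0")
  denom <- 1 + p * (rr - 1)
  if (any(denom <= 0))
    stop("degenerate mixture: 1 + p * (rr - 1) <= 0 at some age")
  m <- m_all / denom
  f <- m * (rr - 1)
  list(f = f, m = m)
}
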