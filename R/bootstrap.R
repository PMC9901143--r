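#' Specify a bootstrap for modelled incidence uncertainty
#'
#' The uncertainty exercise perturbs the prevalence input: in each replicate
#' every band value is drawn independently from a normal distribution
#' centred on the observed value with its per-band standard deviation,
#' truncated to \[0, 1\], and the whole inversion pipeline is re-run.
#' Intervals are percentile intervals across replicates; the point estimate
#' always comes from the unperturbed run.
#'
#' @param n_iter Number of bootstrap iterations (default 100).
#' @param level Interval coverage level (default 0.95).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_iter = 100L, level = 0.95, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), level = level,
                 seed = as.integer(seed)), class = "bootstrap_spec")
}

#' Bootstrap uncertainty for back-calculated incidence
#'
#' Re-runs the interpolation / case-fatality / inversion pipeline `n_iter`
#' times with prevalence perturbed per band by independent normal noise
#' (truncated to \[0, 1\]), and summarises per-band incidence with
#' percentile intervals.  Per-band standard deviations are taken from the
#' prevalence table's `se` column, or derived as `(ci_hi - ci_lo) / (2 *
#' 1.96)` when only interval bounds are given.
#'
#' @inheritParams fit_incidence
#' @param spec A [bootstrap_spec].
#' @param sd Optional per-band standard deviations overriding the table's.
#' @return An object of class `incidence_boot`: point estimates and
#'   percentile intervals per band (hazard and population-rate scales) and
#'   for the person-year-weighted total rate, replicate matrices, replicate
#'   variances, and the spec.
#' @export
bootstrap_incidence <- function(prevalence, remission, csmr,
                                relative_risk = NULL, all_cause = NULL,
                                trend = NULL, spec = bootstrap_spec(),
                                sd = NULL, population = NULL, eps = 1e-6) {
  rt_assert_single(prevalence)
  prevalence <- prevalence[order(prevalence$age_lo), ]
  bands <- rt_bands(prevalence)
  nb <- nrow(bands)
  if (is.null(sd)) {
    sd <- prevalence$se
    need <- is.na(sd)
    sd[need] <- (prevalence$ci_hi[need] - prevalence$ci_lo[need]) / (2 * 1.96)
  }
  sd <- rep_len(as.numeric(sd), nb)
  if (anyNA(sd))
    stop("no standard deviation available for the prevalence perturbation ",
         "(supply 'sd', or 'se'/'ci_lo'/'ci_hi' columns)")
  if (any(sd < 0)) stop("standard deviations must be >= 0")

  r_s <- to_single_ages(remission)
  c_s <- to_single_ages(csmr)
  rr_s <- if (!is.null(relative_risk)) to_single_ages(relative_risk)
  ma_s <- if (!is.null(all_cause)) to_single_ages(all_cause)

  one_run <- function(prev_values) {
    tab <- prevalence
    tab$value <- pmin(pmax(prev_values, 0), 1)
    tab$se <- tab$ci_lo <- tab$ci_hi <- NA_real_
    p_s <- pmin(as.numeric(to_single_ages(tab)), 1 - 1e-9)
    f_fb <- NULL
    if (!is.null(rr_s) && !is.null(ma_s))
      f_fb <- pmax(case_fatality_from_rr(rr_s, ma_s, p_s)$f, 0)
    f <- case_fatality_from_csmr(c_s, p_s, eps = eps, fallback = f_fb)
    i <- if (is.null(trend)) invert_incidence(p_s, r_s, f) else
      invert_incidence_trended(p_s, r_s, f, trend, p0 = p_s[1L])
    w <- if (is.null(population)) rep(1, 100L) else as.numeric(population)
    hz <- band_means(as.numeric(i), bands, weights = w)
    rt <- band_means(as.numeric(i) * (1 - p_s), bands, weights = w)
    list(hazard = hz, rate = rt,
         total_rate = .total_rate(as.numeric(i) * (1 - p_s), population))
  }

  point <- one_run(prevalence$value)

  ## deterministic given spec$seed, without disturbing the caller's RNG
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  rep_hazard <- matrix(NA_real_, spec$n_iter, nb)
  rep_rate <- matrix(NA_real_, spec$n_iter, nb)
  rep_total <- rep(NA_real_, spec$n_iter)
  failures <- character(0)
  for (b in seq_len(spec$n_iter)) {
    draw <- stats::rnorm(nb, mean = prevalence$value, sd = sd)
    res <- tryCatch(suppressWarnings(one_run(draw)), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("replicate ", b, ": ",
                                     conditionMessage(res)))
      next
    }
    rep_hazard[b, ] <- res$hazard
    rep_rate[b, ] <- res$rate
    rep_total[b] <- res$total_rate
  }
  if (all(is.na(rep_total)))
    stop("all bootstrap replicates failed:\n",
         paste(utils::head(failures, 5), collapse = "\n"))

  a2 <- (1 - spec$level) / 2
  qs <- function(mat) apply(mat, 2, stats::quantile,
                            probs = c(a2, 1 - a2), na.rm = TRUE)
  qh <- qs(rep_hazard); qr <- qs(rep_rate)
  qt <- stats::quantile(rep_total, probs = c(a2, 1 - a2), na.rm = TRUE)
  structure(list(bands = bands, point = point,
                 ci_hazard = data.frame(lo = qh[1, ], hi = qh[2, ]),
                 ci_rate = data.frame(lo = qr[1, ], hi = qr[2, ]),
                 ci_total = unname(qt),
                 var_rate = apply(rep_rate, 2, stats::var, na.rm = TRUE),
                 var_total = stats::var(rep_total, na.rm = TRUE),
                 replicates = list(hazard = rep_hazard, rate = rep_rate,
                                   total = rep_total),
                 failures = failures, spec = spec),
            class = "incidence_boot")
}

#' @export
print.incidence_boot <- function(x, ...) {
  cat("Incidence bootstrap: ", x$spec$n_iter, " iterations, ",
      100 * x$spec$level, "% percentile intervals, seed ", x$spec$seed,
      "\n", sep = "")
  disp <- data.frame(
    band = paste0(x$bands$age_lo, "-",
                  ifelse(is.na(x$bands$age_hi), "+", x$bands$age_hi - 1)),
    rate = 1e5 * x$point$rate,
    lo = 1e5 * x$ci_rate$lo, hi = 1e5 * x$ci_rate$hi)
  print(cbind(disp["band"], round(disp[-1], 1)), row.names = FALSE)
  if (length(x$failures) > 0)
    cat(length(x$failures), "replicate(s) failed\n")
  invisible(x)
}
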