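## Default 5-year reporting bands 0-4 ... 90-94, 95+.
.default_bands <- function() {
  data.frame(age_lo = as.integer(seq(0, 95, 5)),
             age_hi = c(as.integer(seq(5, 95, 5)), NA_integer_))
}

## Preset hazard parameters.  Magnitudes are chosen to resemble urban
## Chinese cardio/cerebrovascular epidemiology: exponential-in-age incidence
## and case fatality, near-zero chronic remission for the stroke-like
## preset, a faster acute resolution rate for the AMI-like preset, Gompertz
## other-cause mortality, and the secular trends (-2 %/yr AMI both sexes;
## +3 %/+2 %/yr stroke men/women since 2000).
.preset_params <- function(preset) {
  switch(preset,
    ami_like = list(
      male = list(i0 = 1.9e-5, ki = 0.086, f0 = 0.10, kf = 0.015,
                  r = 0.30, delta = -0.02, rho = 0.42),
      female = list(i0 = 9.0e-6, ki = 0.090, f0 = 0.08, kf = 0.015,
                    r = 0.30, delta = -0.02, rho = 0.30)),
    stroke_like = list(
      male = list(i0 = 3.0e-5, ki = 0.085, f0 = 0.010, kf = 0.045,
                  r = 0.02, delta = 0.03, rho = 0.55),
      female = list(i0 = 2.0e-5, ki = 0.085, f0 = 0.008, kf = 0.045,
                    r = 0.02, delta = 0.02, rho = 0.53)),
    custom = list(
      male = list(i0 = 2.0e-5, ki = 0.08, f0 = 0.02, kf = 0.03,
                  r = 0.10, delta = 0, rho = 0.5),
      female = list(i0 = 1.5e-5, ki = 0.08, f0 = 0.02, kf = 0.03,
                    r = 0.10, delta = 0, rho = 0.5)))
}

## Default population: person-years per single age, a gently ageing urban
## pyramid (flat through mid-life, tapering at old ages).
.default_population <- function() {
  a <- 0:99
  ifelse(a < 60, 1e5, pmax(1e5 - (a - 60) * 2400, 5e3))
}

#' Generate a synthetic epidemiological world
#'
#' Builds an internally consistent illness-death "world" with known
#' hazards, known secular trend and known reporting fractions, against
#' which the whole back-calculation pipeline can be validated.  Hazards are
#' smooth parametric curves (exponential-in-age incidence and case
#' fatality, constant remission, Gompertz other-cause mortality); the
#' world's "true" cross-sectional prevalence is obtained by forward-solving
#' every cohort along its own trended incidence history, so the emitted
#' inputs and the trend-adjusted inversion are mutually consistent by
#' construction.  The seed applies a small deterministic jitter to the
#' hazard parameters so that replicate worlds differ.
#'
#' @param preset `"ami_like"`, `"stroke_like"` or `"custom"`.
#' @param params Named list overriding preset parameters, either globally or
#'   per sex (e.g. `list(male = list(i0 = 1e-5), rho = 0.5)`).  Recognised
#'   fields per sex: `i0`, `ki` (incidence level/slope), `f0`, `kf` (case
#'   fatality), `r` (remission), `delta` (annual incidence trend), `rho`
#'   (reporting fraction: scalar or one value per band),
#'   `recurrence_inflation` (late-recurrence incidence inflation factor,
#'   default 1).  Global fields: `population` (length 100), `bands`,
#'   `m0`/`km` (other-cause mortality), `jitter` (parameter jitter scale,
#'   default 0.08).
#' @param seed Integer seed; worlds are deterministic given
#'   `preset`/`params`/`seed`.
#' @param survey_year Cross-section year (default 2015).
#' @param base_year First year the trend applies (default 2000).
#' @return An object of class `synthetic_world`: per-sex hazards,
#'   [trend_spec]s, reporting fractions per band, population, and the true
#'   cross-sectional `p`, `csmr`, population-scale incidence `rate` and
#'   implied relative risk.
#' @export
make_world <- function(preset = c("ami_like", "stroke_like", "custom"),
                       params = list(), seed = 1L, survey_year = 2015L,
                       base_year = 2000L) {
  preset <- match.arg(preset)
  defaults <- .preset_params(preset)
  bands <- if (!is.null(params$bands)) params$bands else .default_bands()
  nb <- nrow(bands)
  population <- if (!is.null(params$population)) params$population else
    .default_population()
  stopifnot(length(population) == 100L)
  if (any(population <= 0)) stop("population must be > 0 at every age")
  m0 <- if (!is.null(params$m0)) params$m0 else 2e-5
  km <- if (!is.null(params$km)) params$km else 0.10
  jitter_sd <- if (!is.null(params$jitter)) params$jitter else 0.08

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  a <- 0:99
  sexes <- list()
  for (sex in c("male", "female")) {
    par <- defaults[[sex]]
    for (nm in names(params))
      if (nm %in% names(par)) par[[nm]] <- params[[nm]]
    if (!is.null(params[[sex]]))
      for (nm in names(params[[sex]])) par[[nm]] <- params[[sex]][[nm]]
    infl <- if (!is.null(par$recurrence_inflation))
      par$recurrence_inflation else 1
    ## deterministic seed-driven jitter so replicate worlds differ
    par$i0 <- par$i0 * exp(stats::rnorm(1, 0, jitter_sd))
    par$f0 <- par$f0 * exp(stats::rnorm(1, 0, jitter_sd))
    par$ki <- par$ki + stats::rnorm(1, 0, 0.002)

    i <- infl * par$i0 * exp(par$ki * a)
    f <- par$f0 * exp(par$kf * a)
    r <- rep(par$r, 100L)
    m <- m0 * exp(km * a)
    hz <- hazard_set(i, r, f, m)
    trend <- trend_spec(par$delta, survey_year, base_year)

    p_true <- if (par$delta == 0) forward_solve(hz)$p_mid else
      .cohort_prevalence(i, r, f, trend)
    if (max(p_true) >= 0.95)
      stop("preset parameters imply prevalence approaching 1 (max ",
           format(max(p_true), digits = 3), "); reduce incidence or ",
           "increase remission/mortality")
    rho <- rep_len(as.numeric(par$rho), nb)
    if (any(rho < 0 | rho > 1))
      stop("reporting fraction rho must lie in [0, 1]")
    sexes[[sex]] <- list(
      hazards = hz, trend = trend, rho = rho,
      truth = list(p = p_true, csmr = f * p_true,
                   rate = i * (1 - p_true),
                   rr = (m + f) / m))
  }
  structure(list(preset = preset, seed = as.integer(seed),
                 survey_year = as.integer(survey_year),
                 base_year = as.integer(base_year), bands = bands,
                 population = population, sexes = sexes),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic illness-death world ('", x$preset, "', seed ", x$seed,
      ", survey year ", x$survey_year, ")\n", sep = "")
  for (sex in names(x$sexes)) {
    s <- x$sexes[[sex]]
    cat("  ", sex, ": trend ", sprintf("%+.0f%%", 100 * s$trend$delta),
        "/yr, max prevalence ", sprintf("%.3f", max(s$truth$p)),
        ", mean reporting fraction ", sprintf("%.2f", mean(s$rho)),
        "\n", sep = "")
  }
  invisible(x)
}

#' Implied all-cause mortality relative risk of a synthetic world
#'
#' The relative risk of death among cases versus non-cases implied by the
#' generating hazards, `(m + f) / m`, per single age.
#'
#' @param world A [make_world()] object.
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector of length 100.
#' @export
implied_rr <- function(world, sex = "male") {
  stopifnot(inherits(world, "synthetic_world"))
  world$sexes[[sex]]$truth$rr
}

#' Emit model input tables from a synthetic world
#'
#' Band-averages the world's true prevalence, remission, cause-specific
#' mortality and implied relative risk (person-year-weighted within bands)
#' into the rate-table format the fitting pipeline consumes, attaching
#' standard deviations `noise * value`, and optionally perturbing the
#' values once with the same normal model.
#'
#' @param world A [make_world()] object.
#' @param noise Coefficient of variation for the attached standard
#'   deviations (0 allowed).
#' @param perturb Draw one normal perturbation of the emitted values?
#' @param seed Seed for the perturbation draw.
#' @return A list of [rate_table]s: `prevalence`, `remission`, `csmr`,
#'   `relative_risk`, each covering both sexes.
#' @export
emit_model_inputs <- function(world, noise = 0, perturb = FALSE, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  bands <- world$bands
  w <- world$population
  rows <- list()
  for (sex in names(world$sexes)) {
    s <- world$sexes[[sex]]
    vals <- list(
      prevalence = band_means(s$truth$p, bands, weights = w),
      remission = band_means(as.numeric(s$hazards$r), bands, weights = w),
      csmr = band_means(s$truth$csmr, bands, weights = w),
      relative_risk = band_means(s$truth$rr, bands, weights = w))
    for (ms in names(vals))
      rows[[paste(sex, ms)]] <- data.frame(
        disease = world$preset, sex = sex, year = world$survey_year,
        age_lo = bands$age_lo, age_hi = bands$age_hi, measure = ms,
        value = vals[[ms]], se = noise * vals[[ms]])
  }
  big <- do.call(rbind, rows)
  if (perturb) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    big$value <- stats::rnorm(nrow(big), big$value, big$se)
    big$value <- pmax(big$value, 0)
    big$value[big$measure == "prevalence"] <-
      pmin(big$value[big$measure == "prevalence"], 1)
  }
  tab <- rate_table(big)
  out <- lapply(c(prevalence = "prevalence", remission = "remission",
                  csmr = "csmr", relative_risk = "relative_risk"),
                function(ms) {
                  sub <- tab[tab$measure == ms, , drop = FALSE]
                  rownames(sub) <- NULL
                  class(sub) <- c("rate_table", "data.frame")
                  sub
                })
  out
}

#' Emit degraded registry and mortality surveillance from a world
#'
#' Incident events are thinned by the per-band reporting fraction and
#' counted with Poisson noise: expected registry counts per band are
#' `sum_a pop(a) i(a) (1 - p(a)) rho_band`; death counts are Poisson around
#' `sum_a pop(a) csmr(a)` with full completeness (death registration being
#' mandatory).  Rates are counts over person-years.
#'
#' @param world A [make_world()] object.
#' @param seed Seed for the Poisson draws (deterministic given seed).
#' @return A list of [rate_table]s: `incidence` (measure `incidence`, with
#'   `count`/`person_years`) and `mortality` (measure `csmr`).
#' @export
emit_surveillance <- function(world, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  bands <- world$bands
  pop <- world$population
  lo <- bands$age_lo
  hi <- bands$age_hi; hi[is.na(hi)] <- 100L

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  inc_rows <- list(); mor_rows <- list()
  for (sex in names(world$sexes)) {
    s <- world$sexes[[sex]]
    for (b in seq_along(lo)) {
      idx <- (lo[b]:min(hi[b] - 1L, 99L)) + 1L
      py <- sum(pop[idx])
      mu_inc <- sum(pop[idx] * s$truth$rate[idx]) * s$rho[b]
      mu_mor <- sum(pop[idx] * s$truth$csmr[idx])
      n_inc <- stats::rpois(1L, mu_inc)
      n_mor <- stats::rpois(1L, mu_mor)
      inc_rows[[paste(sex, b)]] <- data.frame(
        disease = world$preset, sex = sex, year = world$survey_year,
        age_lo = lo[b], age_hi = bands$age_hi[b], measure = "incidence",
        value = n_inc / py, count = n_inc, person_years = py)
      mor_rows[[paste(sex, b)]] <- data.frame(
        disease = world$preset, sex = sex, year = world$survey_year,
        age_lo = lo[b], age_hi = bands$age_hi[b], measure = "csmr",
        value = n_mor / py, count = n_mor, person_years = py)
    }
  }
  list(incidence = rate_table(do.call(rbind, inc_rows)),
       mortality = rate_table(do.call(rbind, mor_rows)))
}

#' Ground-truth reporting fractions of a synthetic world
#'
#' @param world A [make_world()] object.
#' @return A data frame with `sex`, `age_lo`, `age_hi`, `rho` exactly as
#'   configured.
#' @export
true_completeness <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  do.call(rbind, lapply(names(world$sexes), function(sex)
    data.frame(sex = sex, age_lo = world$bands$age_lo,
               age_hi = world$bands$age_hi,
               rho = world$sexes[[sex]]$rho)))
}

#' Write a synthetic world's full input bundle to disk
#'
#' Writes the model-input CSVs (prevalence, remission, csmr, relative
#' risk), the degraded registry and mortality surveillance CSVs, and a
#' ground-truth JSON (reporting fractions and generator parameters) to a
#' directory.
#'
#' @param world A [make_world()] object.
#' @param dir Output directory (created if needed).
#' @param noise Coefficient of variation for input standard deviations.
#' @param seed Seed for the surveillance draws.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_inputs <- function(world, dir, noise = 0.05, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- emit_model_inputs(world, noise = noise)
  surv <- emit_surveillance(world, seed = seed)
  paths <- c()
  for (nm in names(inputs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_rate_table(inputs[[nm]], p)
    paths[nm] <- p
  }
  paths["observed_incidence"] <- file.path(dir, "observed_incidence.csv")
  write_rate_table(surv$incidence, paths["observed_incidence"])
  paths["mortality"] <- file.path(dir, "mortality.csv")
  write_rate_table(surv$mortality, paths["mortality"])
  truth <- list(preset = world$preset, seed = world$seed,
                survey_year = world$survey_year,
                reporting_fraction = true_completeness(world))
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
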