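test_that("forward solve reproduces the constant-hazard closed form", {
  h <- hazard_set(rep(0.02, 100), numeric(100), numeric(100), numeric(100))
  sol <- forward_solve(h)
  ## p(a) = 1 - exp(-i a) when r = f = m = 0 and p0 = 0
  expect_equal(sol$p[21], 1 - exp(-0.4), tolerance = 1e-9)
  expect_equal(sol$p, 1 - exp(-0.02 * (0:99)), tolerance = 1e-9)
})

test_that("degenerate hazard sets behave as forced", {
  ## no incidence, no birth prevalence: the disease state stays empty
  h0 <- hazard_set(numeric(100), runif(100, 0, 0.3), runif(100, 0, 0.2),
                   rep(0.01, 100))
  sol0 <- forward_solve(h0, p0 = 0)
  expect_equal(sol0$p, rep(0, 100))
  expect_equal(sol0$csmr, rep(0, 100))

  ## no case fatality: no cause-specific deaths accumulate
  h1 <- smooth_hazards(f0 = 0)
  sol1 <- forward_solve(h1)
  expect_equal(sol1$D_cause, rep(0, 100))

  expect_error(hazard_set(rep(-1e-4, 100), numeric(100), numeric(100),
                          numeric(100)), "negative")
})

test_that("forward solve conserves probability to 1e-9 at every age", {
  sol <- forward_solve(smooth_hazards(), p0 = 0.001)
  expect_lt(max(abs(sol$S + sol$C + sol$D_cause + sol$D_other - 1)), 1e-9)
  steep <- hazard_set(1.9e-5 * exp(0.086 * (0:99)), rep(0.3, 100),
                      0.1 * exp(0.015 * (0:99)), 2e-5 * exp(0.1 * (0:99)))
  sol2 <- forward_solve(steep)
  expect_lt(max(abs(sol2$S + sol2$C + sol2$D_cause + sol2$D_other - 1)), 1e-9)
})

test_that("matrix-exponential stepping agrees with a fine-step RK4 oracle", {
  h <- smooth_hazards(ki = 0.07, f0 = 0.08)
  sol <- forward_solve(h, p0 = 0.002)
  oracle <- rk4_solve(h, p0 = 0.002, nstep = 100L)
  expect_lt(max(abs(sol$S - oracle[, "S"])), 1e-6)
  expect_lt(max(abs(sol$C - oracle[, "C"])), 1e-6)
  expect_lt(max(abs(sol$D_cause - oracle[, "D_cause"])), 1e-6)
  expect_lt(max(abs(sol$D_other - oracle[, "D_other"])), 1e-6)
})

test_that("increasing incidence pointwise never decreases prevalence", {
  set.seed(5)
  for (k in 1:3) {
    h_lo <- smooth_hazards(i0 = 4e-5 * runif(1, 0.5, 1.5))
    h_hi <- hazard_set(h_lo$i * runif(100, 1, 2), h_lo$r, h_lo$f, h_lo$m)
    expect_true(all(forward_solve(h_hi)$p >= forward_solve(h_lo)$p - 1e-12))
  }
})

test_that("case fatality is recovered from csmr and prevalence", {
  expect_equal(case_fatality_from_csmr(numeric(100), runif(100, 0.01, 0.5)),
               numeric(100))
  expect_equal(case_fatality_from_csmr(rep(0.001, 100), rep(0.1, 100)),
               rep(0.01, 100), tolerance = 1e-15)

  ## round trip against the forward model where prevalence is material
  h <- smooth_hazards()
  sol <- forward_solve(h)
  f_rec <- case_fatality_from_csmr(sol$csmr_mid, sol$p_mid)
  ok <- sol$p_mid >= 1e-4
  expect_lt(max(abs(f_rec[ok] - h$f[ok]) / h$f[ok]), 1e-6)

  ## inconsistency: positive csmr with zero prevalence and no fallback
  expect_error(case_fatality_from_csmr(rep(0.001, 100), numeric(100)),
               "inconsistent")
  ## low prevalence with a fallback uses the fallback
  p <- rep(1e-9, 100)
  fb <- rep(0.33, 100)
  expect_equal(case_fatality_from_csmr(rep(1e-12, 100), p, fallback = fb),
               fb)
})

test_that("the relative-risk pathway solves the mixture identity", {
  ## rr = 1: no excess mortality
  out <- case_fatality_from_rr(rep(1, 100), rep(0.012, 100),
                               runif(100, 0, 0.5))
  expect_equal(out$f, numeric(100))
  expect_equal(out$m, rep(0.012, 100))

  ## worked example: p = 0.2, rr = 2, m_all = 0.012 -> m = 0.01, f = 0.01
  out2 <- case_fatality_from_rr(rep(2, 100), rep(0.012, 100), rep(0.2, 100))
  expect_equal(out2$m, rep(0.01, 100), tolerance = 1e-15)
  expect_equal(out2$f, rep(0.01, 100), tolerance = 1e-15)

  ## substitution reproduces the all-cause schedule exactly
  set.seed(8)
  rr <- runif(100, 1, 5); m_all <- runif(100, 0.001, 0.1)
  p <- runif(100, 0, 0.3)
  out3 <- case_fatality_from_rr(rr, m_all, p)
  expect_equal(out3$m * (1 - p) + (out3$m + out3$f) * p, m_all,
               tolerance = 1e-12)
  ## p -> 0 limit: m = m_all, f = m_all (rr - 1)
  out4 <- case_fatality_from_rr(rr, m_all, numeric(100))
  expect_equal(out4$m, m_all)
  expect_equal(out4$f, m_all * (rr - 1))
})

test_that("incidence inversion recovers closed-form prevalence curves", {
  ## empty world
  expect_equal(as.numeric(invert_incidence(numeric(100), numeric(100),
                                           numeric(100))),
               numeric(100))
  ## p(a) = 1 - exp(-0.01 a) at interval midpoints, r = f = 0 -> i = 0.01
  p <- 1 - exp(-0.01 * (0:99 + 0.5))
  i <- as.numeric(invert_incidence(p, numeric(100), numeric(100)))
  expect_lt(max(abs(i[2:99] - 0.01)), 1e-4)

  ## steady state: constant p with remission balances i = r p / (1 - p)
  p2 <- rep(0.05, 100)
  i2 <- as.numeric(invert_incidence(p2, rep(0.2, 100), numeric(100)))
  expect_equal(i2, rep(0.2 * 0.05 / 0.95, 100), tolerance = 1e-12)

  expect_error(invert_incidence(c(rep(0.1, 99), 1), numeric(100),
                                numeric(100)), "\\[0, 1\\)")
})

test_that("forward then invert round-trips the incidence schedule", {
  h <- smooth_hazards()
  sol <- forward_solve(h)
  i_rec <- as.numeric(invert_incidence(sol$p_mid, h$r, h$f))
  rel <- abs(i_rec - h$i) / h$i
  expect_lt(max(rel[3:98]), 1e-3)
})

test_that("negative inversion results are floored and flagged", {
  ## prevalence that collapses without remission or death forces i < 0
  p <- c(seq(0.2, 0.01, length.out = 50), rep(0.01, 50))
  i <- invert_incidence(p, numeric(100), numeric(100))
  expect_true(any(attr(i, "floored")))
  expect_true(all(as.numeric(i) >= 0))
})

test_that("trend machinery follows the cohort scaling rule", {
  tr <- trend_spec(-0.02, survey_year = 2015, base_year = 2000)
  ## lag 10 years: (0.98)^-10
  expect_equal(trend_multiplier(tr, 10), 0.98^-10, tolerance = 1e-12)
  expect_equal(trend_multiplier(tr, 10), 1.2240, tolerance = 1e-4)
  ## frozen before the base year: lag capped at survey - base
  expect_equal(trend_multiplier(tr, 40), 0.98^-15, tolerance = 1e-12)
  expect_error(trend_spec(-1, 2015), "> -1")
  expect_error(trend_spec(0.01, 2015, base_year = 2020), "base_year")

  ## hazard surface: delta = 0 leaves every cohort at the current rates
  i_cur <- 5e-5 * exp(0.05 * (0:99))
  surf0 <- apply_trend(i_cur, trend_spec(0, 2015))
  for (a in c(1, 50, 100))
    expect_equal(unname(surf0[a, 1:a]), i_cur[1:a])
  surf <- apply_trend(i_cur, tr)
  expect_equal(unname(surf[31, 21]), i_cur[21] * 0.98^-9.5, tolerance = 1e-12)
  expect_true(all(is.na(surf[1, 2:100])))
})

test_that("trended inversion is exact and reduces to untrended at delta 0", {
  h <- smooth_hazards()
  sol <- forward_solve(h)
  ## delta = 0: bit-for-bit identical to the untrended inversion
  i0 <- invert_incidence_trended(sol$p_mid, h$r, h$f, trend_spec(0, 2015))
  expect_identical(as.numeric(i0),
                   as.numeric(invert_incidence(sol$p_mid, h$r, h$f)))

  ## nonzero trend: sequential sweep recovers the generating schedule
  for (d in c(-0.02, 0.03)) {
    tr <- trend_spec(d, 2015)
    p_tr <- regcomplete:::.cohort_prevalence(h$i, h$r, h$f, tr)
    i_rec <- invert_incidence_trended(p_tr, h$r, h$f, tr)
    expect_true(attr(i_rec, "converged"))
    rel <- abs(as.numeric(i_rec) - h$i) / h$i
    expect_lt(max(rel), 1e-6)
  }
})

test_that("consistency residuals are near zero for self-consistent worlds", {
  h <- smooth_hazards()
  sol <- forward_solve(h)
  inputs <- list(p = sol$p_mid, csmr = sol$csmr_mid,
                 rr = (h$m + h$f) / h$m)
  res <- consistency_residuals(inputs, sol)
  expect_lt(max(abs(res$p_rel), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(res$csmr_rel), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(res$rr_rel), na.rm = TRUE), 1e-6)

  ## a local perturbation shows up as a local residual
  inputs2 <- inputs
  inputs2$p[41:45] <- inputs2$p[41:45] * 1.1
  res2 <- consistency_residuals(inputs2, sol)
  expect_gt(max(abs(res2$p_rel[41:45])), 0.05)
  expect_lt(max(abs(res2$p_rel[-(35:50)]), na.rm = TRUE), 1e-6)
})
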