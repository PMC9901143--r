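test_that("the completeness ratio reproduces identity and printed pairs", {
  expect_equal(completeness_ratio(0.001, 0.001)$irr, 1.0)

  ## published total-row pairs (observed / trended modelled, per 100,000)
  ## reproduce the published two-decimal ratios
  pairs <- data.frame(obs = c(69, 63, 34, 364, 458, 215, 278),
                      mod = c(146, 126, 109, 685, 708, 455, 458),
                      printed = c(0.47, 0.50, 0.31, 0.53, 0.65, 0.47, 0.61))
  got <- completeness_ratio(pairs$obs / 1e5, pairs$mod / 1e5)$irr
  expect_true(all(abs(round(got, 2) - pairs$printed) <= 0.01 + 1e-12))
})

test_that("the IRR and its interval are scale invariant", {
  e1 <- completeness_ratio(0.0004, 0.0009, var_obs = 1e-10, var_mod = 4e-10)
  e2 <- completeness_ratio(0.0004 * 1e5, 0.0009 * 1e5,
                           var_obs = 1e-10 * 1e10, var_mod = 4e-10 * 1e10)
  expect_equal(e1$irr, e2$irr, tolerance = 1e-12)
  expect_equal(e1$lo, e2$lo, tolerance = 1e-12)
  expect_equal(e1$hi, e2$hi, tolerance = 1e-12)
  expect_error(completeness_ratio(0.1, 0), "modeled")
})

test_that("the one-sided Z-test behaves at the null and under separation", {
  e_eq1 <- data.frame(irr = 0.5, se_log = 0.1)
  e_eq2 <- data.frame(irr = 0.5, se_log = 0.1)
  out <- ztest_irr_increase(e_eq1, e_eq2)
  expect_equal(out$p, 0.5, tolerance = 1e-12)
  expect_equal(out$z, 0)

  out2 <- ztest_irr_increase(data.frame(irr = 0.3, se_log = 1e-4),
                             data.frame(irr = 0.6, se_log = 1e-4))
  expect_lt(out2$p, 1e-10)

  ## se recovered from the CI when absent
  e_ci <- data.frame(irr = 0.5, lo = 0.5 * exp(-1.96 * 0.1),
                     hi = 0.5 * exp(1.96 * 0.1))
  out3 <- ztest_irr_increase(e_ci, e_eq2)
  expect_equal(out3$p, 0.5, tolerance = 1e-6)

  expect_error(ztest_irr_increase(data.frame(irr = 1, se_log = 0),
                                  data.frame(irr = 1, se_log = 0)),
               "zero combined")
})

test_that("one-sided decision agrees with the doubled-alpha two-sided test", {
  set.seed(21)
  for (k in 1:50) {
    irr1 <- runif(1, 0.2, 0.8); irr2 <- runif(1, 0.2, 0.8)
    se1 <- runif(1, 0.02, 0.2); se2 <- runif(1, 0.02, 0.2)
    one <- ztest_irr_increase(data.frame(irr = irr1, se_log = se1),
                              data.frame(irr = irr2, se_log = se2))
    two_p <- 2 * (1 - pnorm(abs(one$z)))
    if (irr2 > irr1)
      expect_equal(one$p < 0.05, two_p < 0.10)
  }
})

test_that("the Z-test is calibrated under the null", {
  ## equal true IRR in both periods; Poisson registry counts and a normal
  ## modelled-rate error; rejection rate should sit near alpha = 0.05
  set.seed(31)
  nsim <- 500
  py <- 2e5
  mod_true <- 500 / 1e5
  rho <- 0.45
  cv_mod <- 0.03
  rej <- logical(nsim)
  for (s in seq_len(nsim)) {
    mk <- function() {
      cnt <- rpois(1, rho * mod_true * py)
      mod <- rnorm(1, mod_true, cv_mod * mod_true)
      completeness_ratio(cnt / py, mod, var_obs = cnt / py^2,
                         var_mod = (cv_mod * mod_true)^2)
    }
    rej[s] <- ztest_irr_increase(mk(), mk())$p < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("incidence:mortality ratios follow the stated arithmetic", {
  bands <- data.frame(age_lo = c(35L, 65L), age_hi = c(65L, NA))
  inc <- mk_table(c(90, 90) / 1e5, "incidence", bands = bands)
  mor <- mk_table(c(90, 100) / 1e5, "csmr", bands = bands)
  out <- incidence_mortality_ratio(inc, mor)
  expect_equal(out$ratio, c(1.0, 0.9), tolerance = 1e-12)

  ## full reporting with case fatality < 1 forces a ratio above 1
  ## (restricted to ages 35+, where both event streams are material)
  w <- make_world("stroke_like", params = list(rho = 1, jitter = 0),
                  seed = 4)
  surv <- emit_surveillance(w, seed = 5)
  sub35 <- function(tab) {
    out <- tab[tab$age_lo >= 35 & tab$age_lo <= 80, ]
    rownames(out) <- NULL
    class(out) <- c("rate_table", "data.frame")
    out
  }
  imr <- incidence_mortality_ratio(sub35(surv$incidence),
                                   sub35(surv$mortality))
  expect_true(all(imr$ratio > 1))
})
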