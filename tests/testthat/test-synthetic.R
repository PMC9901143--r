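test_that("worlds are deterministic given preset and seed", {
  w1 <- make_world("ami_like", seed = 42)
  w2 <- make_world("ami_like", seed = 42)
  expect_identical(w1, w2)
  w3 <- make_world("ami_like", seed = 43)
  expect_false(identical(w1$sexes$male$hazards$i, w3$sexes$male$hazards$i))
})

test_that("preset magnitudes stay in plausible epidemiological ranges", {
  w <- make_world("ami_like", seed = 1)
  for (sex in c("male", "female"))
    expect_lt(max(w$sexes[[sex]]$truth$p), 0.2)

  ## a zero-incidence custom world has zero prevalence
  w0 <- make_world("custom", params = list(i0 = 0, jitter = 0), seed = 1)
  expect_equal(w0$sexes$male$truth$p, rep(0, 100))

  ## the default trends match the configured annual changes
  expect_equal(make_world("ami_like", seed = 1)$sexes$male$trend$delta, -0.02)
  expect_equal(make_world("ami_like", seed = 1)$sexes$female$trend$delta,
               -0.02)
  ws <- make_world("stroke_like", seed = 1)
  expect_equal(ws$sexes$male$trend$delta, 0.03)
  expect_equal(ws$sexes$female$trend$delta, 0.02)
  expect_equal(ws$sexes$male$trend$base_year, 2000L)
})

test_that("implied relative risk equals the hazard arithmetic before banding", {
  w <- make_world("stroke_like", seed = 9)
  for (sex in c("male", "female")) {
    h <- w$sexes[[sex]]$hazards
    expect_equal(implied_rr(w, sex), (h$m + h$f) / h$m, tolerance = 1e-9)
  }
})

test_that("emitted inputs are exact band averages at zero noise", {
  w <- make_world("ami_like", seed = 3)
  inputs <- emit_model_inputs(w, noise = 0)
  s <- w$sexes$male
  prev <- rt_stratum(inputs$prevalence, sex = "male")
  expect_equal(prev$value,
               unname(band_means(s$truth$p, w$bands,
                                 weights = w$population)),
               tolerance = 1e-12)
  expect_equal(prev$se, rep(0, 20))
  csm <- rt_stratum(inputs$csmr, sex = "male")
  expect_equal(csm$value,
               unname(band_means(s$truth$csmr, w$bands,
                                 weights = w$population)),
               tolerance = 1e-12)
})

test_that("emitted inputs round-trip to the world's incidence", {
  w <- make_world("ami_like", params = list(jitter = 0), seed = 2)
  inputs <- emit_model_inputs(w, noise = 0)
  for (sex in c("male", "female")) {
    s <- w$sexes[[sex]]
    fit <- fit_incidence(rt_stratum(inputs$prevalence, sex = sex),
                         rt_stratum(inputs$remission, sex = sex),
                         rt_stratum(inputs$csmr, sex = sex),
                         trend = s$trend, population = w$population)
    true_band <- band_means(as.numeric(s$hazards$i), w$bands,
                            weights = w$population)
    sel <- w$bands$age_lo >= 30 & w$bands$age_lo <= 80
    rel <- abs(fit$band_rates$hazard_trended - true_band) / true_band
    expect_lt(max(rel[sel]), 0.05)
  }
})

test_that("surveillance emission thins truly and deterministically", {
  ## zero reporting: no registry counts at all
  w0 <- make_world("ami_like", params = list(rho = 0), seed = 6)
  s0 <- emit_surveillance(w0, seed = 1)
  expect_equal(sum(s0$incidence$count), 0)

  ## full reporting at enormous person-years: the observed rate converges
  ## to the true population-scale incidence (law of large numbers)
  w1 <- make_world("ami_like",
                   params = list(rho = 1, population = rep(1e9 / 100, 100),
                                 jitter = 0), seed = 6)
  s1 <- emit_surveillance(w1, seed = 2)
  obs <- rt_stratum(s1$incidence, sex = "male")
  ## pooled over ages 40+ the event count is large enough for the 0.5% limit
  old <- obs$age_lo >= 40
  pooled_obs <- sum(obs$count[old]) / sum(obs$person_years[old])
  pop40 <- w1$population; pop40[1:40] <- 0
  pooled_truth <- sum(pop40 * w1$sexes$male$truth$rate) / sum(pop40)
  expect_lt(abs(pooled_obs - pooled_truth) / pooled_truth, 0.005)
  ## per band the agreement is looser but still tight where events abound
  truth <- band_means(w1$sexes$male$truth$rate, w1$bands,
                      weights = w1$population)
  sel <- truth > 1e-4
  expect_lt(max(abs(obs$value[sel] - truth[sel]) / truth[sel]), 0.05)

  ## deterministic draws
  expect_identical(emit_surveillance(w0, seed = 7),
                   emit_surveillance(w0, seed = 7))

  ## mortality is reported with full completeness
  mor <- rt_stratum(s1$mortality, sex = "male")
  pooled_mor <- sum(mor$count[old]) / sum(mor$person_years[old])
  pooled_truth_m <- sum(pop40 * w1$sexes$male$truth$csmr) / sum(pop40)
  expect_lt(abs(pooled_mor - pooled_truth_m) / pooled_truth_m, 0.005)
})

test_that("ground-truth reporting fractions are returned verbatim", {
  w <- make_world("ami_like",
                  params = list(male = list(rho = 0.42),
                                female = list(rho = 0.30)), seed = 1)
  tc <- true_completeness(w)
  expect_equal(unique(tc$rho[tc$sex == "male"]), 0.42)
  expect_equal(unique(tc$rho[tc$sex == "female"]), 0.30)
  expect_error(make_world("ami_like", params = list(rho = 1.2), seed = 1),
               "\\[0, 1\\]")
})

test_that("simulate_inputs writes a complete plain-text bundle", {
  dir <- withr::local_tempdir()
  w <- make_world("stroke_like", seed = 12)
  paths <- simulate_inputs(w, dir, noise = 0.05, seed = 3)
  expect_true(all(file.exists(paths)))
  back <- read_rate_table(paths[["prevalence"]], measure = "prevalence")
  expect_equal(nrow(back), 40)   # 20 bands x 2 sexes
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$preset, "stroke_like")
  expect_equal(nrow(truth$reporting_fraction), 40)
})
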