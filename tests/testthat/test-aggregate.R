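mk_subtype_lists <- function(prevs, rems, rrs, bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(age_lo = c(40L, 60L), age_hi = c(60L, NA))
  nsub <- ncol(prevs)
  subtypes <- paste0("sub", seq_len(nsub))
  one <- function(vals, measure, d)
    mk_table(vals, measure, bands = bands, disease = d)
  list(prevalence = setNames(lapply(seq_len(nsub), function(s)
         one(prevs[, s], "prevalence", subtypes[s])), subtypes),
       remission = setNames(lapply(seq_len(nsub), function(s)
         one(rems[, s], "remission", subtypes[s])), subtypes),
       relative_risk = setNames(lapply(seq_len(nsub), function(s)
         one(rrs[, s], "relative_risk", subtypes[s])), subtypes))
}

test_that("subtype aggregation follows the prevalence-weighted rule", {
  ## equal remission across subtypes is preserved
  ls <- mk_subtype_lists(prevs = cbind(c(0.01, 0.02), c(0.03, 0.05)),
                         rems = cbind(c(0.1, 0.1), c(0.1, 0.1)),
                         rrs = cbind(c(2, 2), c(2, 2)))
  out <- aggregate_stroke_subtypes(ls$prevalence, ls$remission,
                                   ls$relative_risk)
  expect_equal(out$remission$value, c(0.1, 0.1))

  ## worked two-subtype example: prevalences (0.01, 0.03),
  ## remissions (0.2, 0.4) -> prevalence 0.04, remission 0.35
  ls2 <- mk_subtype_lists(prevs = cbind(c(0.01, 0.01), c(0.03, 0.03)),
                          rems = cbind(c(0.2, 0.2), c(0.4, 0.4)),
                          rrs = cbind(c(1.5, 1.5), c(2.5, 2.5)))
  out2 <- aggregate_stroke_subtypes(ls2$prevalence, ls2$remission,
                                    ls2$relative_risk)
  expect_equal(out2$prevalence$value, c(0.04, 0.04), tolerance = 1e-15)
  expect_equal(out2$remission$value, c(0.35, 0.35), tolerance = 1e-15)
  expect_equal(out2$relative_risk$value, c(2.25, 2.25), tolerance = 1e-15)
})

test_that("aggregation of random subtypes matches a brute-force oracle", {
  set.seed(11)
  for (k in 1:3) {
    P <- matrix(runif(8, 0.001, 0.05), 2, 4)
    R <- matrix(runif(8, 0, 0.5), 2, 4)
    RR <- matrix(runif(8, 1, 4), 2, 4)
    ls <- mk_subtype_lists(P, R, RR)
    out <- aggregate_stroke_subtypes(ls$prevalence, ls$remission,
                                     ls$relative_risk)
    for (b in 1:2) {
      expect_equal(out$prevalence$value[b], sum(P[b, ]), tolerance = 1e-12)
      expect_equal(out$remission$value[b],
                   sum(P[b, ] * R[b, ]) / sum(P[b, ]), tolerance = 1e-12)
      ## convexity: combined value inside the subtype range
      expect_gte(out$remission$value[b], min(R[b, ]))
      expect_lte(out$remission$value[b], max(R[b, ]))
      expect_gte(out$relative_risk$value[b], min(RR[b, ]))
      expect_lte(out$relative_risk$value[b], max(RR[b, ]))
    }
  }
})

test_that("zero all-stroke prevalence with conflicting inputs errors", {
  ls <- mk_subtype_lists(prevs = cbind(c(0, 0.02), c(0, 0.05)),
                         rems = cbind(c(0.1, 0.1), c(0.3, 0.1)),
                         rrs = cbind(c(2, 2), c(2, 2)))
  expect_error(aggregate_stroke_subtypes(ls$prevalence, ls$remission,
                                         ls$relative_risk),
               "prevalence is 0")
})

test_that("survey-year approximation follows the mean/take rules", {
  bands <- data.frame(age_lo = c(40L, 60L), age_hi = c(60L, NA))
  a <- mk_table(c(10, 30) / 1e5, "incidence", bands = bands, year = 2005)
  b <- mk_table(c(20, 50) / 1e5, "incidence", bands = bands, year = 2010)

  ## mean of equal tables is the table itself
  same <- approximate_year_inputs(a, a, rule = "mean", year = 2007)
  expect_equal(same$value, a$value)
  expect_equal(unique(same$year), 2007L)

  ## band value 10 (2005) and 20 (2010) -> 15 for 2007
  got <- approximate_year_inputs(a, b, rule = "mean", year = 2007)
  expect_equal(got$value, c(15, 40) / 1e5, tolerance = 1e-15)

  ## take: pass-through relabelled
  took <- approximate_year_inputs(mk_table(c(1, 2) / 1e3, "incidence",
                                           bands = bands, year = 2016),
                                  rule = "take", year = 2015)
  expect_equal(took$value, c(1, 2) / 1e3)
  expect_equal(unique(took$year), 2015L)

  ## band mismatch errors
  c_tab <- mk_table(0.1, "incidence",
                    bands = data.frame(age_lo = 0L, age_hi = NA_integer_))
  expect_error(approximate_year_inputs(a, c_tab, rule = "mean", year = 2007),
               "need at least two|mismatch")
})
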