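#' Aggregate stroke subtypes into an all-stroke input set
#'
#' Combines per-subtype prevalence, remission and relative-risk tables into
#' all-stroke tables: prevalence is the sum over subtypes, while remission
#' and relative risk are prevalence-weighted means, each subtype's weight
#' being its fraction of all-stroke prevalence within the band.
#'
#' @param prevalence,remission,relative_risk Named lists of single-stratum
#'   [rate_table]s, one element per subtype; all tables must share bands,
#'   sex and year, and the three lists must name the same subtypes.
#' @param disease Label for the combined tables (default "stroke").
#' @return A list with elements `prevalence`, `remission` and
#'   `relative_risk`, each a [rate_table] for the combined disease.
#' @examples
#' base <- data.frame(sex = "male", year = 2015,
#'                    age_lo = c(40, 60), age_hi = c(60, NA))
#' prev <- list(
#'   isch = rate_table(cbind(base, disease = "isch", measure = "prevalence",
#'                           value = c(0.01, 0.03))),
#'   hem = rate_table(cbind(base, disease = "hem", measure = "prevalence",
#'                          value = c(0.005, 0.01))))
#' rem <- list(
#'   isch = rate_table(cbind(base, disease = "isch", measure = "remission",
#'                           value = c(0.2, 0.1))),
#'   hem = rate_table(cbind(base, disease = "hem", measure = "remission",
#'                          value = c(0.4, 0.2))))
#' rr <- list(
#'   isch = rate_table(cbind(base, disease = "isch",
#'                           measure = "relative_risk", value = c(2, 1.5))),
#'   hem = rate_table(cbind(base, disease = "hem",
#'                          measure = "relative_risk", value = c(3, 2))))
#' aggregate_stroke_subtypes(prev, rem, rr)
#' @export
aggregate_stroke_subtypes <- function(prevalence, remission, relative_risk,
                                      disease = "stroke") {
  subtypes <- names(prevalence)
  if (is.null(subtypes) || !identical(sort(subtypes), sort(names(remission))) ||
      !identical(sort(subtypes), sort(names(relative_risk))))
    stop("prevalence, remission and relative_risk must be named lists over ",
         "the same subtypes")
  ref <- prevalence[[1L]]
  rt_assert_single(ref)
  bands <- rt_bands(ref)
  check_one <- function(tab, measure, what) {
    rt_assert_single(tab)
    tab <- tab[order(tab$age_lo), ]
    if (!all(tab$measure == measure))
      stop(what, " table does not carry measure '", measure, "'")
    if (!identical(rt_bands(tab), bands) ||
        !identical(tab$sex, ref$sex) || !identical(tab$year, ref$year))
      stop(what, " table does not share bands/sex/year with the others")
    tab
  }
  P <- sapply(subtypes, function(s)
    check_one(prevalence[[s]], "prevalence", paste0("prevalence[", s, "]"))$value)
  R <- sapply(subtypes, function(s)
    check_one(remission[[s]], "remission", paste0("remission[", s, "]"))$value)
  RR <- sapply(subtypes, function(s)
    check_one(relative_risk[[s]], "relative_risk",
              paste0("relative_risk[", s, "]"))$value)
  P <- matrix(P, nrow = nrow(bands)); R <- matrix(R, nrow = nrow(bands))
  RR <- matrix(RR, nrow = nrow(bands))
  p_all <- rowSums(P)
  wmean <- function(V, what) {
    out <- numeric(nrow(bands))
    for (b in seq_len(nrow(bands))) {
      if (p_all[b] > 0) {
        out[b] <- sum(P[b, ] / p_all[b] * V[b, ])
      } else if (all(V[b, ] == V[b, 1L])) {
        out[b] <- V[b, 1L]     # degenerate band, all inputs agree
      } else {
        stop("band [", bands$age_lo[b], ",...): all-stroke prevalence is 0 ",
             "but subtype ", what, " values differ; weighted mean undefined")
      }
    }
    out
  }
  mk <- function(measure, value)
    rate_table(data.frame(disease = disease, sex = ref$sex[1L],
                          year = ref$year[1L], age_lo = bands$age_lo,
                          age_hi = bands$age_hi, measure = measure,
                          value = value))
  list(prevalence = mk("prevalence", p_all),
       remission = mk("remission", wmean(R, "remission")),
       relative_risk = mk("relative_risk", wmean(RR, "relative risk")))
}

#' Approximate a survey year's inputs from surrounding estimation years
#'
#' Burden-of-disease input estimates are produced only for selected years;
#' survey years in between are approximated either by the element-wise mean
#' of two estimates (`rule = "mean"`) or by relabelling a single nearby
#' estimate (`rule = "take"`).
#'
#' @param est_a A single-stratum [rate_table].
#' @param est_b A second table sharing bands, sex and measure (required for
#'   `rule = "mean"`, ignored otherwise).
#' @param rule `"mean"` or `"take"`.
#' @param year Target calendar year for the output table.
#' @return A [rate_table] labelled with `year`.
#' @export
approximate_year_inputs <- function(est_a, est_b = NULL,
                                    rule = c("mean", "take"), year) {
  rule <- match.arg(rule)
  rt_assert_single(est_a)
  est_a <- est_a[order(est_a$age_lo), ]
  out <- as.data.frame(est_a)
  if (rule == "mean") {
    if (is.null(est_b)) stop("rule 'mean' needs two tables")
    rt_assert_single(est_b)
    est_b <- est_b[order(est_b$age_lo), ]
    if (!identical(rt_bands(est_a), rt_bands(est_b)) ||
        !identical(est_a$sex, est_b$sex) ||
        !identical(est_a$measure, est_b$measure))
      stop("band/sex/measure mismatch between the two estimate tables")
    out$value <- (est_a$value + est_b$value) / 2
    for (col in c("se", "ci_lo", "ci_hi", "count", "person_years"))
      out[[col]] <- NA_real_
    ## the mean of two normals with sd_a, sd_b has sd sqrt(sa^2+sb^2)/2
    if (all(!is.na(est_a$se)) && all(!is.na(est_b$se)))
      out$se <- sqrt(est_a$se^2 + est_b$se^2) / 2
  }
  out$year <- as.integer(year)
  rate_table(out)
}
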