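screen_curves <- function(hrs = c(0.5, 0.8, 1, 1.3, 1.7, 2.2, 3),
                          tab = NULL) {
  spec <- pgs_group_spec()
  st <- strata_hr(spec$labels, spec$proportions, as.list(hrs),
                  reference = spec$reference)
  if (is.null(tab))
    tab <- data.frame(location = "x", sex = "female", age = seq(0, 75, 5),
                      incidence = 0.008, prevalence = 0,
                      cause_mortality = 0, all_cause_mortality = 0.01,
                      stringsAsFactors = FALSE)
  stratified_cumulative_incidence(tab, st)
}

# evaluate a stratum curve at an arbitrary age through the public API
.curve_value <- function(curves, stratum, age) {
  sub <- curves[curves$stratum == stratum, ]
  lt_like <- list(age = sub$age[-nrow(sub)],
                  hazard = sub$hazard[-nrow(sub)],
                  survival = sub$survival, cum_inc = sub$cumulative_incidence)
  class(lt_like) <- "life_table"
  ci_at_age(lt_like, age)
}

test_that("population threshold is the curve value at the index age", {
  curves <- screen_curves()
  thr <- population_threshold(curves, 45)
  pop <- curves[curves$stratum == "population", ]
  lt_equiv <- life_table(rep(0.008, 16), rep(0, 16),
                         all_cause_mortality = rep(0.01, 16))
  expect_equal(thr, ci_at_age(lt_equiv, 45), tolerance = 1e-12)
  expect_equal(population_threshold(curves, 0), 0)
  expect_error(population_threshold(curves, 81), "index age")
  zero <- screen_curves(tab = data.frame(
    location = "x", sex = "female", age = seq(0, 75, 5), incidence = 0,
    prevalence = 0, cause_mortality = 0, all_cause_mortality = 0))
  expect_equal(population_threshold(zero, 45), 0)
})

test_that("crossing age round-trips every grid age exactly", {
  curves <- screen_curves()
  for (s in c("population", "<20", ">95")) {
    sub <- curves[curves$stratum == s, ]
    for (a in seq(5, 80, 15)) {
      thr <- .curve_value(curves, s, a)
      expect_equal(crossing_age(curves, thr, s), a, tolerance = 1e-9)
    }
  }
  # population stratum vs its own index-age threshold: exactly the index
  thr45 <- population_threshold(curves, 45)
  expect_equal(crossing_age(curves, thr45, "population"), 45,
               tolerance = 1e-9)
})

test_that("analytic crossing age matches a bisection oracle", {
  h <- 0.009
  tab <- data.frame(location = "x", sex = "female", age = seq(0, 75, 5),
                    incidence = h, prevalence = 0, cause_mortality = 0,
                    all_cause_mortality = 0, stringsAsFactors = FALSE)
  curves <- screen_curves(tab = tab)
  for (thr in c(0.05, 0.2, 0.4)) {
    # zero mortality, constant hazard: age = -ln(1 - T) / h exactly
    a_closed <- -log(1 - thr) / h
    a_pkg <- crossing_age(curves, thr, "population")
    a_bis <- oracle_bisect_age(function(a)
      .curve_value(curves, "population", a), thr)
    expect_equal(a_pkg, a_closed, tolerance = 1e-9)
    expect_lt(abs(a_pkg - a_bis), 0.01)
  }
})

test_that("unreachable thresholds yield the sentinel, never an age > 80", {
  curves <- screen_curves()
  bottom <- curves[curves$stratum == "<20", ]
  too_high <- max(bottom$cumulative_incidence) + 0.05
  out <- crossing_age(curves, too_high, "<20")
  expect_true(is.na(out))
  expect_true(attr(out, "not_reached"))
  expect_error(crossing_age(curves, -0.1, "<20"), "threshold")
})

test_that("crossing age is monotone non-increasing in the stratum HR", {
  curves <- screen_curves(hrs = c(0.8, 0.9, 1, 1.1, 1.3, 1.5, 1.8))
  thr <- population_threshold(curves, 45)
  ages <- vapply(c("<20", "20-40", "40-60", "60-80", "80-90", "90-95",
                   ">95"),
                 function(s) crossing_age(curves, thr, s), numeric(1))
  expect_true(all(diff(ages) < 0))
})

test_that("screening report centres on the index age and supports CIs", {
  curves <- screen_curves()
  rep0 <- screening_report(curves, 45)
  expect_equal(rep0$crossing_age[rep0$stratum == "population"], 45,
               tolerance = 1e-9)
  expect_equal(rep0$diff_vs_index[rep0$stratum == "population"], 0,
               tolerance = 1e-9)
  expect_equal(rep0$diff_vs_reference[rep0$stratum == "40-60"], 0,
               tolerance = 1e-9)
  # unit HRs: every stratum crosses exactly at the index age
  flat <- screen_curves(hrs = rep(1, 7))
  rep1 <- screening_report(flat, 45)
  expect_equal(rep1$crossing_age, rep(45, nrow(rep1)), tolerance = 1e-9)

  # bootstrap CIs bracket the point estimates
  spec <- pgs_group_spec()
  st <- strata_hr(spec$labels, spec$proportions,
                  as.list(c(0.8, 0.9, 1, 1.1, 1.3, 1.5, 1.8)),
                  se = rep(0.05, 7), reference = spec$reference)
  tab <- data.frame(location = "x", sex = "female", age = seq(0, 75, 5),
                    incidence = 0.008, prevalence = 0, cause_mortality = 0,
                    all_cause_mortality = 0.01, stringsAsFactors = FALSE)
  curves2 <- stratified_cumulative_incidence(tab, st)
  repb <- screening_report(curves2, 45, rates = tab, strata = st,
                           boot = bootstrap_config(B = 60, seed = 6,
                                                   blocks = "hr"))
  grp <- repb$stratum != "population"
  expect_true(all(repb$lower[grp] <= repb$crossing_age[grp] + 1e-9))
  expect_true(all(repb$upper[grp] >= repb$crossing_age[grp] - 1e-9))

  # multi-report aggregation is the arithmetic mean
  agg <- aggregate_screening(list(rep0, rep0))
  expect_equal(agg$mean_crossing_age, rep0$crossing_age)
})
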