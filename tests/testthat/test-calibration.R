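default_strata <- function(hrs, se = NULL) {
  spec <- pgs_group_spec()
  strata_hr(spec$labels, spec$proportions, hrs, se, spec$reference)
}

flat_rates <- function(h = 0.01, mort = 0, prev = 0) {
  data.frame(location = "x", sex = "female", age = seq(0, 75, 5),
             incidence = h, prevalence = prev, cause_mortality = 0,
             all_cause_mortality = mort, stringsAsFactors = FALSE)
}

# ordering helper: pull scalar HRs back out of a strata_hr
resolve_hrs_for_test <- function(st) {
  vapply(st$hr, function(h) if (is.numeric(h)) h else NA_real_, numeric(1))
}

test_that("age-trend HR prediction clamps outside the fitted range", {
  tr <- structure(list(intercept = log(2), slope = -0.01,
                       vcov = diag(2) * 1e-4, range = c(20, 60),
                       data = NULL), class = "age_trend")
  expect_equal(predict_hr_by_age(tr, 40), 2 * exp(-0.4), tolerance = 1e-12)
  expect_equal(predict_hr_by_age(tr, 10), predict_hr_by_age(tr, 20))
  expect_equal(predict_hr_by_age(tr, 75), predict_hr_by_age(tr, 60))
  flat <- structure(list(intercept = 0.3, slope = 0, vcov = diag(2),
                         range = c(20, 60), data = NULL),
                    class = "age_trend")
  expect_equal(predict_hr_by_age(flat, c(0, 40, 80)), rep(exp(0.3), 3))
})

test_that("reference incidence inverts the population constraint", {
  spec_2 <- strata_hr(c("lo", "hi"), c(0.5, 0.5), c(1, 3), reference = "lo")
  i0 <- reference_incidence(0.02, spec_2)
  expect_equal(i0, 0.01, tolerance = 1e-12)
  ii <- group_incidences(i0, spec_2)
  expect_equal(unname(ii), c(0.01, 0.03), tolerance = 1e-12)
  expect_equal(sum(c(0.5, 0.5) * ii), 0.02, tolerance = 1e-12)

  # all HR = 1: reference equals population
  ones <- default_strata(rep(1, 7))
  expect_equal(reference_incidence(0.015, ones), 0.015, tolerance = 1e-12)

  # conservation against brute-force weighted averages
  set.seed(14)
  for (r in 1:25) {
    hrs <- exp(rnorm(7, 0, 0.5))
    st <- default_strata(as.list(hrs))
    i <- runif(1, 1e-4, 0.05)
    i0 <- reference_incidence(i, st)
    ii <- group_incidences(i0, st)
    expect_equal(sum(st$proportion * ii), i, tolerance = 1e-12)
    expect_equal(order(ii), order(resolve_hrs_for_test(st)))
  }
})

test_that("unit HRs collapse every stratum onto the population curve", {
  tab <- random_rate_table(3)
  curves <- stratified_cumulative_incidence(tab, default_strata(rep(1, 7)))
  pop <- curves[curves$stratum == "population", ]
  for (g in setdiff(unique(curves$stratum), "population")) {
    sub <- curves[curves$stratum == g, ]
    expect_equal(sub$cumulative_incidence, pop$cumulative_incidence,
                 tolerance = 1e-12)
  }
})

test_that("constant hazards without mortality telescope per stratum", {
  h <- 0.012
  hrs <- c(0.5, 0.8, 1, 1.3, 1.7, 2.2, 3)
  st <- default_strata(as.list(hrs))
  curves <- stratified_cumulative_incidence(flat_rates(h), st)
  denom <- sum(st$proportion * hrs)
  for (g in seq_along(st$group)) {
    h_g <- h * hrs[g] / denom
    sub <- curves[curves$stratum == st$group[g], ]
    expect_equal(sub$cumulative_incidence[17], 1 - exp(-80 * h_g),
                 tolerance = 1e-12)
  }
  # reference stratum equals the reference_incidence -> life table route
  i0 <- reference_incidence(h, st)
  lt0 <- life_table(rep(i0, 16), rep(0, 16))
  ref_curve <- curves[curves$stratum == "40-60", ]
  expect_equal(ref_curve$cumulative_incidence, lt0$cum_inc,
               tolerance = 1e-12)
})

test_that("curves are pointwise monotone in a group's HR", {
  tab <- random_rate_table(5)
  lo <- stratified_cumulative_incidence(tab, default_strata(c(0.5, 0.8, 1, 1.2, 1.5, 1.8, 2)))
  hi <- stratified_cumulative_incidence(tab, default_strata(c(0.5, 0.8, 1, 1.2, 1.5, 1.8, 3)))
  top_lo <- lo[lo$stratum == ">95", "cumulative_incidence"]
  top_hi <- hi[hi$stratum == ">95", "cumulative_incidence"]
  expect_true(all(top_hi[-1] > top_lo[-1]))
})

test_that("meta-HR transfer has its identity and bracketing properties", {
  tab <- random_rate_table(11)
  st1 <- default_strata(c(0.5, 0.8, 1, 1.3, 1.6, 2.0, 2.6),
                        se = c(rep(0.05, 7)))
  # single study: identical to the study-specific curves
  tr1 <- transfer_with_meta_hrs(tab, list(st1))
  own <- stratified_cumulative_incidence(tab, st1)
  expect_equal(tr1$cumulative_incidence, own$cumulative_incidence,
               tolerance = 1e-12)
  # two identical studies: still identical
  tr2 <- transfer_with_meta_hrs(tab, list(st1, st1))
  expect_equal(tr2$cumulative_incidence, own$cumulative_incidence,
               tolerance = 1e-12)
  # heterogeneous studies: pooled curve lies between the per-study curves
  st2 <- default_strata(c(0.7, 0.9, 1, 1.1, 1.3, 1.5, 1.8),
                        se = c(rep(0.05, 7)))
  tr <- transfer_with_meta_hrs(tab, list(st1, st2))
  a <- stratified_cumulative_incidence(tab, st1)
  b <- stratified_cumulative_incidence(tab, st2)
  for (g in c("<20", ">95")) {
    mid <- tr[tr$stratum == g, "cumulative_incidence"][-1]
    lo <- pmin(a[a$stratum == g, "cumulative_incidence"],
               b[b$stratum == g, "cumulative_incidence"])[-1]
    hi <- pmax(a[a$stratum == g, "cumulative_incidence"],
               b[b$stratum == g, "cumulative_incidence"])[-1]
    expect_true(all(mid >= lo - 1e-12 & mid <= hi + 1e-12))
  }
})

test_that("strata constructor enforces its invariants", {
  expect_error(strata_hr(c("a", "b"), c(0.6, 0.5), c(1, 2), reference = "a"),
               "sum to 1")
  expect_error(strata_hr(c("a", "b"), c(0.5, 0.5), c(1, 2), reference = "c"),
               "reference")
  expect_error(strata_hr(c("a", "b"), c(0.5, 0.5), c(1, -2), reference = "a"),
               "positive")
  st <- strata_hr(c("a", "b"), c(0.5, 0.5), c(5, 2), reference = "a")
  expect_identical(st$hr[[1]], 1)  # reference HR forced to exactly 1
})

test_that("fitted strata recover generator HRs end to end", {
  cfg <- quick_config(n = 50000, seed = 37, beta0 = 0.4)
  coh <- assign_pgs_groups(standardize_pgs(simulate_cohort(cfg)))
  st <- estimate_strata_hr(coh, "full")
  expect_identical(st$female, st$male)
  hrs <- vapply(st$female$hr, function(h) if (is.numeric(h)) h else NA_real_,
                numeric(1))
  names(hrs) <- st$female$group
  # monotone in the grouping, top/bottom on the expected side of 1
  ordering <- c("<20", "20-40", "40-60", "60-80", "80-90", "90-95", ">95")
  expect_true(all(diff(hrs[ordering]) > 0))
  expect_lt(hrs[["<20"]], 1)
  expect_gt(hrs[[">95"]], 1)
})
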