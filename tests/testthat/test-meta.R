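test_that("fixed-effects pooling matches inverse-variance arithmetic", {
  m <- meta_fixed(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m$log_hr, 0.2, tolerance = 1e-10)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-10)

  m2 <- meta_fixed(c(0.0, 0.2), c(0.1, 0.2))
  expect_equal(m2$log_hr, 0.04, tolerance = 1e-10)
  expect_equal(m2$se, sqrt(1 / 125), tolerance = 1e-10)

  # single study: identity
  m3 <- meta_fixed(0.17, 0.04)
  expect_equal(m3$log_hr, 0.17)
  expect_equal(m3$se, 0.04)

  # k copies: point unchanged, SE shrinks by sqrt(k)
  m4 <- meta_fixed(rep(0.3, 4), rep(0.1, 4))
  expect_equal(m4$log_hr, 0.3, tolerance = 1e-10)
  expect_equal(m4$se, 0.1 / 2, tolerance = 1e-10)

  expect_error(meta_fixed(numeric(0), numeric(0)), "no usable")
})

test_that("Cochran's Q matches the chi-square closed form", {
  q0 <- cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.1))
  expect_equal(q0$Q, 0, tolerance = 1e-12)
  expect_equal(q0$p, 1, tolerance = 1e-12)

  q1 <- cochran_q(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(q1$Q, 2, tolerance = 1e-10)
  expect_equal(q1$df, 1L)
  expect_equal(q1$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)

  # steep equal-SE gradient is strongly heterogeneous
  q2 <- cochran_q(c(0.9, 0.6, 0.3, 0.0), rep(0.05, 4))
  w <- rep(1 / 0.05^2, 4)
  b <- c(0.9, 0.6, 0.3, 0.0)
  q_hand <- sum(w * (b - weighted.mean(b, w))^2)
  expect_equal(q2$Q, q_hand, tolerance = 1e-8)
  expect_lt(q2$p, 2.8e-3)

  # invariance to a constant shift
  q3 <- cochran_q(b + 5, rep(0.05, 4))
  expect_equal(q3$Q, q2$Q, tolerance = 1e-8)
  expect_error(cochran_q(0.1, 0.1), "at least 2")
})

test_that("age-trend WLS agrees with least-squares oracles", {
  # equal estimates: flat line through the common value
  t0 <- age_trend_wls(rep(0.4, 4), rep(0.1, 4), c(10, 20, 30, 40))
  expect_equal(t0$slope, 0, tolerance = 1e-10)
  expect_equal(t0$intercept, 0.4, tolerance = 1e-10)

  # equal SEs: identical point estimates to ordinary least squares
  y <- c(0.94, 0.77, 0.63, 0.51)
  ages <- c(10, 20, 30, 40)
  tr <- age_trend_wls(y, rep(0.05, 4), ages)
  ols <- lm(y ~ ages)
  expect_equal(tr$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(tr$intercept, unname(coef(ols)[1]), tolerance = 1e-10)

  # unequal SEs: matches lm with 1/se^2 weights
  se <- c(0.05, 0.1, 0.07, 0.2)
  trw <- age_trend_wls(y, se, ages)
  wls <- lm(y ~ ages, weights = 1 / se^2)
  expect_equal(trw$slope, unname(coef(wls)[2]), tolerance = 1e-10)
  # fixed-variance covariance: (X' W X)^{-1}
  X <- cbind(1, ages)
  V <- solve(t(X) %*% diag(1 / se^2) %*% X)
  expect_equal(trw$vcov, unname(V), tolerance = 1e-8)

  # two points: exact interpolation
  t2 <- age_trend_wls(c(0.8, 0.6), c(0.1, 0.1), c(20, 60))
  expect_equal(t2$intercept + t2$slope * c(20, 60), c(0.8, 0.6),
               tolerance = 1e-10)
  expect_error(age_trend_wls(c(1, 2), c(0.1, 0.1), c(30, 30)), "duplicate")
})

test_that("sex slope comparison is a two-sided z-test and antisymmetric", {
  mk <- function(slope, se_slope) {
    structure(list(intercept = 0, slope = slope,
                   vcov = diag(c(1e-4, se_slope^2)), range = c(20, 60),
                   data = NULL), class = "age_trend")
  }
  same <- compare_sex_slopes(mk(-0.01, 0.002), mk(-0.01, 0.002))
  expect_equal(same$p, 1)
  cmp <- compare_sex_slopes(mk(-0.01, 0.002), mk(0, 0.002))
  expect_equal(cmp$z, -0.01 / (0.002 * sqrt(2)), tolerance = 1e-10)
  expect_equal(cmp$p, 2 * pnorm(-abs(cmp$z)), tolerance = 1e-12)
  expect_lt(abs(cmp$p - 4.0e-4), 1e-4)
  rev <- compare_sex_slopes(mk(0, 0.002), mk(-0.01, 0.002))
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p, cmp$p)
})

test_that("model selection follows the decision rules", {
  expect_equal(select_model(0.5, 0.5, 0.5, 0.5, 0.5)$choice, "full")
  expect_equal(select_model(1e-5, 0.5)$choice, "sex")
  expect_equal(select_model(0.9, 1e-6)$choice, "age")
  expect_equal(select_model(1e-5, 1e-6)$choice, "age_and_sex")
  # age signal in a single sex where not found overall
  expect_equal(select_model(0.9, 0.2, p_q_female = 0.5,
                            p_q_male = 1e-6)$choice, "age_and_sex")
  # both sexes heterogeneous and overall too: plain age (no sex evidence)
  expect_equal(select_model(0.9, 1e-6, p_q_female = 1e-6,
                            p_q_male = 1e-6, p_slope_diff = 0.8)$choice,
               "age")
  # slope difference upgrades an age signal to age_and_sex
  expect_equal(select_model(0.9, 1e-6, p_slope_diff = 0.01)$choice,
               "age_and_sex")
  # ... but is not consulted without any age-specific signal
  expect_equal(select_model(0.9, 0.5, p_slope_diff = 0.01)$choice, "full")
  # missing evidence is treated as non-significant
  expect_equal(select_model(NA, NA)$choice, "full")
  # thresholds are configurable
  expect_equal(select_model(0.01, 0.5, alpha_main = 0.05)$choice, "sex")
  # choice is reproducible from the stored evidence
  ch <- select_model(1e-5, 1e-6, 0.2, 0.3, 0.4)
  redo <- do.call(select_model, ch$evidence[1:5])
  expect_equal(redo$choice, ch$choice)
})

test_that("study completeness rule drops studies missing strata", {
  est <- rbind(
    .row <- data.frame(stratum = "age", study = "a", sex = NA,
                       age_interval = 1:4, pgs_group = NA,
                       log_hr = c(0.5, 0.4, 0.3, 0.2), se = 0.1,
                       n_cases = 100L, n_controls = 1000L, converged = TRUE),
    data.frame(stratum = "age", study = "b", sex = NA, age_interval = 1:4,
               pgs_group = NA, log_hr = c(0.5, 0.4, 0.3, NA), se = 0.1,
               n_cases = 100L, n_controls = 1000L,
               converged = c(TRUE, TRUE, TRUE, FALSE)))
  pooled <- meta_strata(est)
  expect_equal(attr(pooled, "dropped_studies"), "b")
  expect_equal(nrow(pooled), 4L)
  expect_equal(pooled$k, rep(1L, 4))
  expect_equal(pooled$log_hr, c(0.5, 0.4, 0.3, 0.2))
})
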