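test_that("config validation rejects broken inputs", {
  expect_error(sim_config(baseline_hazard = data.frame(age = 5, rate = 0.01)),
               "start at age 0")
  expect_error(sim_config(baseline_hazard = data.frame(age = 0, rate = -1)),
               ">= 0")
  expect_error(sim_config(sex_fraction_female = 1), "sex_fraction_female")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(study_sd = -0.1), "study_sd")
})

test_that("cohort draws are deterministic, partitioned and bounded", {
  cfg <- quick_config(n = 5000, seed = 42, beta0 = 0.3, beta_age = -0.01)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 5000)
  expect_setequal(unique(a$status), c("disease", "other_death", "censored"))
  expect_equal(sum(table(a$status)), 5000)
  expect_true(all(a$exit_age > 0 & a$exit_age <= 80))
  expect_true(all(is.finite(a$pgs)))
  # a different seed gives a different table
  expect_false(identical(a, simulate_cohort(cfg, seed = 43)))
})

test_that("null generator yields a null fitted log-HR", {
  cfg <- quick_config(n = 50000, seed = 7, beta0 = 0, beta_sex = 0,
                      beta_age = 0)
  est <- fit_cox_full(standardize_pgs(simulate_cohort(cfg)))
  expect_true(est$converged)
  expect_lt(abs(est$log_hr), 3 * est$se)
})

test_that("constant hazard without mortality matches exponential survival", {
  h <- 0.01
  cfg <- sim_config(n_individuals = 50000, seed = 3, beta0 = 0,
                    baseline_hazard = data.frame(age = 0, rate = h),
                    other_mortality = data.frame(age = 0, rate = 0))
  coh <- simulate_cohort(cfg)
  p_hat <- mean(coh$status == "disease")
  p_true <- 1 - exp(-80 * h)
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / 50000))
  # non-cases are administratively censored at 80 exactly
  expect_true(all(coh$exit_age[coh$status == "censored"] == 80))
})

test_that("multistudy reduces to single-cohort simulation and tracks truth", {
  cfg <- quick_config(n = 2000, seed = 9, n_studies = 3, study_sd = 0)
  multi <- simulate_multistudy(cfg)
  expect_length(multi, 3)
  expect_equal(attr(multi, "offsets"), c(0, 0, 0))
  one <- quick_config(n = 2000, seed = 9, n_studies = 1, study_sd = 0)
  single <- simulate_multistudy(one)
  direct <- simulate_cohort(one)
  expect_identical(single$study_1, direct)
  # offsets recorded and reproducible under study_sd > 0
  cfg2 <- quick_config(n = 100, seed = 9, n_studies = 4, study_sd = 0.2)
  m1 <- simulate_multistudy(cfg2)
  m2 <- simulate_multistudy(cfg2)
  expect_identical(attr(m1, "offsets"), attr(m2, "offsets"))
  expect_equal(sd(attr(m1, "offsets")) > 0, TRUE)
})

test_that("between-study heterogeneity inflates Cochran's Q across studies", {
  n_rep <- 5
  count_sig <- function(study_sd, seed0) {
    sum(vapply(seq_len(n_rep), function(r) {
      cfg <- sim_config(n_individuals = 10000, seed = seed0 + r,
                        n_studies = 5, study_sd = study_sd, beta0 = 0.3)
      multi <- simulate_multistudy(cfg)
      ests <- do.call(rbind, lapply(multi, function(coh)
        fit_cox_full(standardize_pgs(coh))))
      cochran_q(ests$log_hr, ests$se)$p < 0.05
    }, logical(1)))
  }
  expect_gt(count_sig(0.1, 100), count_sig(0, 200))
})

test_that("derived rate table matches closed forms and a microsimulation", {
  # zero disease hazard everywhere: incidence and prevalence identically 0
  cfg0 <- sim_config(n_individuals = 10, seed = 1, beta0 = 0.3,
                     baseline_hazard = data.frame(age = 0, rate = 0))
  r0 <- derive_population_rates(cfg0)
  expect_equal(r0$incidence, rep(0, 32))
  expect_equal(r0$prevalence, rep(0, 32))

  # constant hazard, no PGS effect, no mortality: first-bin incidence is
  # h times the disease-free fraction; empirical microsimulation agrees
  h <- 0.01
  cfg <- sim_config(n_individuals = 300000, seed = 21, beta0 = 0,
                    baseline_hazard = data.frame(age = 0, rate = h),
                    other_mortality = data.frame(age = 0, rate = 0))
  rates <- derive_population_rates(cfg)
  f <- rates[rates$sex == "female", ]
  coh <- simulate_cohort(cfg)
  for (m in c(0, 25, 75)) {
    new_cases <- sum(coh$status == "disease" & coh$exit_age >= m &
                       coh$exit_age < m + 5)
    emp <- new_cases / (5 * nrow(coh))   # no mortality: everyone alive
    expect_lt(abs(f$incidence[f$age == m] - emp),
              4 * sqrt(new_cases) / (5 * nrow(coh)))
  }
  # prevalence at midpoint has the exponential closed form
  expect_equal(f$prevalence, 1 - exp(-h * (f$age + 2.5)), tolerance = 1e-10)

  # a positive per-SD effect raises population incidence above the PGS=0
  # individual's rate in every bin (moderate-hazard regime)
  cfg_b <- quick_config(n = 10, seed = 1, beta0 = 0.3)
  cfg_0 <- quick_config(n = 10, seed = 1, beta0 = 0)
  rb <- derive_population_rates(cfg_b)
  rz <- derive_population_rates(cfg_0)
  expect_true(all(rb$incidence > rz$incidence))
})

test_that("analytic cumulative incidence matches the simulated cohort", {
  cfg <- quick_config(n = 50000, seed = 13, beta0 = 0.3, beta_sex = 0.1)
  coh <- simulate_cohort(cfg)
  for (sx in c("female", "male")) {
    truth <- analytic_cumulative_incidence(cfg, sx, ages = seq(0, 80, 10))
    sub <- coh[coh$sex == sx, ]
    emp <- vapply(truth$age, function(a)
      mean(sub$status == "disease" & sub$exit_age <= a), numeric(1))
    expect_lt(max(abs(emp - truth$cumulative_incidence)), 0.015)
  }
})
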