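#' Simulation configuration for synthetic biobank cohorts
#'
#' Bundles the generative parameters of the synthetic-data model: a
#' piecewise-constant baseline disease hazard, a competing piecewise-constant
#' other-cause mortality hazard, and a log hazard ratio per standard
#' deviation of PGS that may differ by sex and vary linearly with age.
#' The individual disease hazard at age \eqn{a} is
#' \deqn{\lambda(a \mid x) = h_0(a) \exp\{x\,(\beta_0 + \beta_{sex} 1[male]
#'   + \beta_{age}(a - a_{ref}) + u_s)\},}
#' where \eqn{x} is the standard-normal PGS, \eqn{h_0} the baseline hazard
#' and \eqn{u_s} a study-specific log-HR offset. Other-cause death competes
#' with its own hazard; follow-up is administratively censored at `max_age`.
#'
#' @param n_individuals cohort size per study.
#' @param n_studies number of studies for [simulate_multistudy()].
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param sex_fraction_female probability that an individual is female.
#' @param baseline_hazard two-column `data.frame` (`age`, `rate`): lower
#'   bounds of contiguous age bins starting at 0 and the disease hazard per
#'   person-year that applies from that age to the next bound (the last bin
#'   runs to `max_age`).
#' @param other_mortality same format, for the competing other-cause
#'   mortality hazard.
#' @param beta0 log hazard ratio per SD of PGS at the reference age.
#' @param beta_sex additive log-HR difference (male minus female).
#' @param beta_age change in log-HR per year of age, relative to `age_ref`.
#' @param age_ref reference age (years) at which the per-SD log-HR equals
#'   `beta0` (plus `beta_sex` for men).
#' @param study_sd between-study standard deviation of log-HR offsets.
#' @param max_age administrative censoring age in years.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 1000, seed = 1)
#' cfg$baseline_hazard
#' @export
sim_config <- function(n_individuals = 10000L,
                       n_studies = 1L,
                       seed = 1L,
                       sex_fraction_female = 0.5,
                       baseline_hazard = data.frame(
                         age = c(0, 20, 40, 60),
                         rate = c(1e-4, 1e-3, 4e-3, 8e-3)
                       ),
                       other_mortality = data.frame(
                         age = c(0, 40, 60),
                         rate = c(1e-3, 5e-3, 2e-2)
                       ),
                       beta0 = 0.3,
                       beta_sex = 0,
                       beta_age = 0,
                       age_ref = 40,
                       study_sd = 0,
                       max_age = 80) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_studies = as.integer(n_studies),
    seed = as.integer(seed), sex_fraction_female = sex_fraction_female,
    baseline_hazard = as.data.frame(baseline_hazard),
    other_mortality = as.data.frame(other_mortality),
    beta0 = beta0, beta_sex = beta_sex, beta_age = beta_age,
    age_ref = age_ref, study_sd = study_sd, max_age = max_age
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of [sim_config()]: non-negative rates, contiguous
#' increasing age bins starting at 0 that cover `[0, max_age)`, a sex
#' fraction strictly inside (0, 1), at least one individual and a
#' non-negative between-study SD.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly; errors describe every violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  problems <- character(0)
  for (nm in c("baseline_hazard", "other_mortality")) {
    tab <- cfg[[nm]]
    if (!is.data.frame(tab) || !all(c("age", "rate") %in% names(tab)) ||
        nrow(tab) == 0) {
      problems <- c(problems, sprintf("%s must be a data.frame with columns age, rate", nm))
      next
    }
    if (tab$age[1] != 0) problems <- c(problems, sprintf("%s bins must start at age 0", nm))
    if (any(diff(tab$age) <= 0)) problems <- c(problems, sprintf("%s ages must be strictly increasing", nm))
    if (any(tab$rate < 0)) problems <- c(problems, sprintf("%s rates must be >= 0", nm))
    if (max(tab$age) >= cfg$max_age) problems <- c(problems, sprintf("%s last bin must begin before max_age", nm))
  }
  if (!(cfg$sex_fraction_female > 0 && cfg$sex_fraction_female < 1))
    problems <- c(problems, "sex_fraction_female must be in (0, 1)")
  if (cfg$n_individuals < 1L) problems <- c(problems, "n_individuals must be >= 1")
  if (cfg$n_studies < 1L) problems <- c(problems, "n_studies must be >= 1")
  if (cfg$study_sd < 0) problems <- c(problems, "study_sd must be >= 0")
  if (cfg$max_age <= 0) problems <- c(problems, "max_age must be > 0")
  if (length(problems))
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

# Internal piecewise-constant hazard helpers -------------------------------
#
# A piecewise hazard is a list(breaks, rates) with breaks = c(lower bounds,
# max_age), so rates[j] applies on [breaks[j], breaks[j + 1]).

.pw <- function(tab, max_age) {
  list(breaks = c(tab$age, max_age), rates = tab$rate)
}

# rate at given ages (vectorized); ages in [0, max_age)
.pw_rate <- function(pw, age) {
  j <- findInterval(age, pw$breaks, rightmost.closed = TRUE)
  j[j < 1L] <- 1L
  j[j > length(pw$rates)] <- length(pw$rates)
  pw$rates[j]
}

# cumulative integral of the rate from 0 to age (vectorized)
.pw_cumhaz <- function(pw, age) {
  widths <- diff(pw$breaks)
  cum <- c(0, cumsum(pw$rates * widths))
  j <- findInterval(pmin(age, pw$breaks[length(pw$breaks)]), pw$breaks,
                    rightmost.closed = TRUE)
  j[j < 1L] <- 1L
  j[j > length(pw$rates)] <- length(pw$rates)
  cum[j] + pw$rates[j] * (pmin(age, max(pw$breaks)) - pw$breaks[j])
}

# Merge the break grid of two piecewise hazards (used by analytic rates)
.pw_union_breaks <- function(pw1, pw2) {
  sort(unique(c(pw1$breaks, pw2$breaks)))
}
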