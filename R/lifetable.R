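#' Read and validate a GBD-style rate table
#'
#' Reads a delimited rate extract with one row per (location, sex,
#' five-year age group): columns `location`, `sex`, `age` (bin lower
#' bound, 0 to 75 by 5), `incidence` (new cases per person-year),
#' `prevalence` (point prevalence proportion), `cause_mortality` and
#' `all_cause_mortality` (rates per person-year), plus optional 95%
#' uncertainty bounds named `<measure>_lower` / `<measure>_upper`.
#'
#' @param path path to a CSV file.
#' @return Validated rate table `data.frame`.
#' @seealso [validate_rate_table()]
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rate_table(tab)
}

#' Validate a rate table
#'
#' Checks the rate-table invariants: required columns present, rates
#' non-negative, prevalence in `[0, 1)`, cause-specific mortality not
#' exceeding all-cause mortality, and for every (location, sex) a
#' complete, duplicate-free set of 5-year bins covering `[0, 80)`. All
#' violations are reported together.
#'
#' @param tab a rate table `data.frame`.
#' @return `tab`, invisibly typed, or an error listing each violation.
#' @export
validate_rate_table <- function(tab) {
  need <- c("location", "sex", "age", "incidence", "prevalence",
            "cause_mortality", "all_cause_mortality")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("rate table is missing columns: ", paste(miss, collapse = ", "))
  problems <- character(0)
  rowid <- function(i) paste0("(", tab$location[i], ", ", tab$sex[i],
                              ", age ", tab$age[i], ")")
  bad <- which(tab$prevalence < 0 | tab$prevalence >= 1)
  for (i in bad) problems <- c(problems, paste0("prevalence outside [0,1) in row ", rowid(i)))
  for (col in c("incidence", "cause_mortality", "all_cause_mortality")) {
    bad <- which(tab[[col]] < 0 | !is.finite(tab[[col]]))
    for (i in bad) problems <- c(problems, paste0(col, " negative or non-finite in row ", rowid(i)))
  }
  bad <- which(tab$cause_mortality > tab$all_cause_mortality + 1e-12)
  for (i in bad) problems <- c(problems, paste0("cause mortality exceeds all-cause in row ", rowid(i)))
  expected <- seq(0, 75, by = 5)
  for (key in split(tab, paste(tab$location, tab$sex, sep = " / "))) {
    lab <- paste0(key$location[1], ", ", key$sex[1])
    gap <- setdiff(expected, key$age)
    if (length(gap))
      problems <- c(problems, paste0("missing age bins for (", lab, "): ",
                                     paste(gap, collapse = ", ")))
    dup <- key$age[duplicated(key$age)]
    if (length(dup))
      problems <- c(problems, paste0("duplicate age bins for (", lab, "): ",
                                     paste(unique(dup), collapse = ", ")))
  }
  if (length(problems))
    stop("invalid rate table:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  tab
}

#' Disease hazard from incidence and prevalence
#'
#' Converts a population incidence rate into the hazard among those still
#' disease-free: `hazard = incidence / (1 - prevalence)`. The hazard is
#' treated as constant within its five-year age group.
#'
#' @param incidence incidence rate (new cases per person-year), >= 0.
#' @param prevalence point prevalence proportion in `[0, 1)`.
#' @return Hazard per person-year.
#' @examples
#' hazard_from_rates(0.01, 0.5)  # 0.02
#' @export
hazard_from_rates <- function(incidence, prevalence) {
  if (any(prevalence >= 1)) stop("prevalence must be < 1")
  if (any(incidence < 0)) stop("incidence must be >= 0")
  incidence / (1 - prevalence)
}

#' Other-cause mortality rate
#'
#' All-cause minus cause-specific mortality. Tiny negative differences
#' (within 1e-12) are clamped to zero with a warning; larger ones are an
#' error.
#'
#' @param all_cause,cause_specific mortality rates per person-year.
#' @return Other-cause mortality rate.
#' @export
other_cause_mortality <- function(all_cause, cause_specific) {
  if (any(cause_specific < 0)) stop("cause-specific mortality must be >= 0")
  d <- all_cause - cause_specific
  if (any(d < -1e-12))
    stop("cause-specific mortality exceeds all-cause mortality")
  if (any(d < 0)) {
    warning("clamping other-cause mortality to 0 (within tolerance)")
    d <- pmax(d, 0)
  }
  d
}

#' Build a competing-risk life table from bin-wise rates
#'
#' Assembles the discrete life table on five-year age groups: disease
#' hazard via [hazard_from_rates()], other-cause mortality via
#' [other_cause_mortality()], the survival function
#' \deqn{survival_k = \exp\{-5 \sum_{m < k} (mortality_m + hazard_m)\}}
#' at bin lower bounds \eqn{k \in \{0, 5, \ldots, 80\}} (survival is 1 at
#' age 0), the per-bin disease probability
#' \eqn{risk_k = 1 - e^{-5\, hazard_k}}, and the cumulative incidence as
#' the partial sums of `survival * risk`.
#'
#' @param incidence,prevalence,cause_mortality,all_cause_mortality
#'   vectors of length 16, one value per bin `[m, m + 5)`,
#'   `m = 0, 5, ..., 75`.
#' @return Object of class `life_table`: list with `age` (0:75 by 5),
#'   `hazard`, `other_mortality`, `risk`, `survival` (length 17, at ages
#'   0:80 by 5) and `cum_inc` (length 17).
#' @export
life_table <- function(incidence, prevalence, cause_mortality = 0,
                       all_cause_mortality = 0) {
  nbin <- length(incidence)
  stopifnot(length(prevalence) == nbin)
  cause_mortality <- rep_len(cause_mortality, nbin)
  all_cause_mortality <- rep_len(all_cause_mortality, nbin)
  hazard <- hazard_from_rates(incidence, prevalence)
  other <- other_cause_mortality(all_cause_mortality, cause_mortality)
  survival <- exp(-5 * c(0, cumsum(other + hazard)))
  risk <- 1 - exp(-5 * hazard)
  cum_inc <- c(0, cumsum(survival[seq_len(nbin)] * risk))
  structure(list(age = seq(0, by = 5, length.out = nbin),
                 hazard = hazard, other_mortality = other, risk = risk,
                 survival = survival, cum_inc = cum_inc),
            class = "life_table")
}

#' Survival at five-year bin boundaries
#'
#' @param lt a [life_table()].
#' @return Named vector of survival probabilities at ages 0, 5, ..., 80.
#' @export
survival_curve <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  stats::setNames(lt$survival, c(lt$age, max(lt$age) + 5))
}

#' Five-year disease probability for a constant bin hazard
#'
#' `risk = 1 - exp(-5 * hazard)`, the probability of onset during a
#' five-year age group with constant hazard, ignoring within-bin death.
#'
#' @param hazard hazard per person-year, >= 0.
#' @return Probability in `[0, 1)`.
#' @export
interval_risk <- function(hazard) {
  if (any(hazard < 0)) stop("hazard must be >= 0")
  1 - exp(-5 * hazard)
}

#' Cumulative incidence at bin boundaries
#'
#' Partial sums `CI(A) = sum_{k < A} survival_k * risk_k` at
#' `A = 0, 5, ..., 80`; `CI(0) = 0`.
#'
#' @param lt a [life_table()].
#' @return `data.frame` with columns `age` and `cumulative_incidence`.
#' @export
cumulative_incidence <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  data.frame(age = c(lt$age, max(lt$age) + 5),
             cumulative_incidence = lt$cum_inc)
}

#' Cumulative incidence at arbitrary ages (within-bin closed form)
#'
#' Evaluates the cumulative incidence curve at sub-bin resolution using
#' the exact constant-hazard solution within each five-year bin:
#' `CI(k + t) = CI(k) + survival_k * (1 - exp(-t * hazard_k))` for
#' `t` in `[0, 5)`. At five-year boundaries this reproduces the discrete
#' computation exactly.
#'
#' @param lt a [life_table()].
#' @param age ages in `[0, 80]` (vectorized).
#' @return Cumulative incidence at `age`.
#' @export
ci_at_age <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  max_age <- max(lt$age) + 5
  if (any(age < 0 | age > max_age))
    stop("age must be within [0, ", max_age, "]")
  k <- pmin(floor(age / 5) * 5, max(lt$age))
  j <- k / 5 + 1
  t <- age - k
  lt$cum_inc[j] + lt$survival[j] * (1 - exp(-t * lt$hazard[j]))
}

#' @export
print.life_table <- function(x, ...) {
  cat("Competing-risk life table (", length(x$age), " bins of 5 years)\n",
      sep = "")
  cat(sprintf("  CI(80) = %.4f, survival(80) = %.4f\n",
              x$cum_inc[length(x$cum_inc)], x$survival[length(x$survival)]))
  invisible(x)
}
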