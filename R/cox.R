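#' Standardize PGS within each study
#'
#' Scales the `pgs` column to mean 0 and variance 1 (unbiased, n-1
#' denominator) separately within every study label, the convention under
#' which all hazard ratios in this package are per standard deviation of
#' PGS.
#'
#' @param cohort a cohort `data.frame` with columns `study` and `pgs`.
#' @return The cohort with `pgs` standardized per study.
#' @examples
#' coh <- data.frame(study = "a", pgs = c(1, 2, 3))
#' standardize_pgs(coh)$pgs
#' @export
standardize_pgs <- function(cohort) {
  stopifnot(all(c("study", "pgs") %in% names(cohort)))
  for (s in unique(cohort$study)) {
    i <- cohort$study == s
    if (sum(i) < 2L)
      stop("study '", s, "' has fewer than 2 individuals; cannot standardize")
    sdev <- stats::sd(cohort$pgs[i])
    if (!is.finite(sdev) || sdev == 0)
      stop("study '", s, "' has zero PGS variance; cannot standardize")
    cohort$pgs[i] <- (cohort$pgs[i] - mean(cohort$pgs[i])) / sdev
  }
  cohort
}

# One-row hazard-ratio estimate record. All fit_cox_* functions return
# data.frames of these rows so they can be stacked and meta-analyzed.
.hr_row <- function(stratum, study, log_hr = NA_real_, se = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    converged = FALSE, sex = NA_character_,
                    age_interval = NA_integer_, pgs_group = NA_character_) {
  data.frame(stratum = stratum, study = study, sex = sex,
             age_interval = age_interval, pgs_group = pgs_group,
             log_hr = log_hr, se = se, n_cases = n_cases,
             n_controls = n_controls, converged = converged,
             stringsAsFactors = FALSE)
}

# Fit a Cox model with age as timescale and return coefficient `term`.
# `entry`/`exit`/`event` are vectors aligned with `data`. Convergence
# warnings (infinite coefficients, iteration limit) mark the estimate
# unconverged rather than erroring, per the downstream exclusion rule.
.fit_cox <- function(data, rhs, entry, exit, event, term) {
  ok <- TRUE
  fml <- stats::as.formula(paste("survival::Surv(entry, exit, event) ~", rhs))
  data$entry <- entry; data$exit <- exit; data$event <- event
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = data, ties = "efron"),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("infinite|Ran out of iterations|did not converge",
                conditionMessage(w))) ok <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit)) return(list(ok = FALSE))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (is.null(term)) {
    return(list(ok = ok, fit = fit, coef = co, se_all = se,
                vcov = stats::vcov(fit)))
  }
  if (!(term %in% names(co)) || is.na(co[term]) || !is.finite(se[term]))
    ok <- FALSE
  list(ok = ok, log_hr = unname(co[term]), se = unname(se[term]), fit = fit,
       coef = co, se_all = se, vcov = stats::vcov(fit))
}

.cohort_rhs <- function(cohort, covariates = NULL, base = "pgs") {
  rhs <- base
  if (length(unique(cohort$sex)) > 1L && base != "pgs * sex")
    rhs <- paste(rhs, "+ sex")
  if (length(covariates)) rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  rhs
}

.study_label <- function(cohort) paste(sort(unique(cohort$study)), collapse = "+")

#' Cox proportional-hazards fit of PGS on the full sample
#'
#' Fits a proportional-hazards model with age as the timescale (entry at
#' birth, exit at the disease/death/censoring age) and the standardized
#' PGS as exposure. Sex is included as a covariate when both sexes are
#' present; additional technical covariates (principal components, batch)
#' can be passed through by column name. Ties are handled with the Efron
#' approximation.
#'
#' @param cohort cohort `data.frame` (columns `study`, `sex`, `pgs`,
#'   `status`, `exit_age`).
#' @param covariates optional character vector of extra covariate columns.
#' @return One-row `data.frame` with `stratum = "full"`, `log_hr` (per SD
#'   of PGS), `se`, case/control counts and a `converged` flag.
#' @export
fit_cox_full <- function(cohort, covariates = NULL) {
  .check_cohort(cohort)
  event <- cohort$status == "disease"
  if (!any(event)) stop("cohort contains no disease cases")
  f <- .fit_cox(cohort, .cohort_rhs(cohort, covariates),
                entry = rep(0, nrow(cohort)), exit = cohort$exit_age,
                event = event, term = "pgs")
  .hr_row("full", .study_label(cohort), f$log_hr, f$se,
          sum(event), sum(!event), f$ok)
}

#' Sex-stratified Cox fits
#'
#' Repeats [fit_cox_full()] separately within each sex.
#'
#' @inheritParams fit_cox_full
#' @return Two-row `data.frame` (`stratum = "sex"`, `sex` column filled).
#'   A cohort missing one sex is an error.
#' @export
fit_cox_by_sex <- function(cohort, covariates = NULL) {
  .check_cohort(cohort)
  rows <- lapply(c("female", "male"), function(sx) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0L) stop("cohort contains no individuals of sex '", sx, "'")
    event <- sub$status == "disease"
    if (!any(event)) stop("no disease cases of sex '", sx, "'")
    f <- .fit_cox(sub, .cohort_rhs(sub, covariates),
                  entry = rep(0, nrow(sub)), exit = sub$exit_age,
                  event = event, term = "pgs")
    .hr_row("sex", .study_label(sub), f$log_hr, f$se, sum(event),
            sum(!event), f$ok, sex = sx)
  })
  do.call(rbind, rows)
}

#' PGS-by-sex interaction test
#'
#' Adds a PGS-by-sex interaction term to the full-sample model and returns
#' the interaction log-HR (male minus female, per SD of PGS), its standard
#' error and a two-sided Wald p-value.
#'
#' @inheritParams fit_cox_full
#' @return A list with `log_hr`, `se`, `z`, `p` and `converged`.
#' @export
fit_sex_interaction <- function(cohort, covariates = NULL) {
  .check_cohort(cohort)
  if (length(unique(cohort$sex)) < 2L)
    stop("interaction test requires both sexes")
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  event <- cohort$status == "disease"
  rhs <- "pgs * sex"
  if (length(covariates)) rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  f <- .fit_cox(cohort, rhs, entry = rep(0, nrow(cohort)),
                exit = cohort$exit_age, event = event, term = "pgs:sexmale")
  z <- if (f$ok) f$log_hr / f$se else NA_real_
  list(log_hr = f$log_hr, se = f$se, z = z,
       p = if (f$ok) 2 * stats::pnorm(-abs(z)) else NA_real_,
       converged = f$ok)
}

#' Age-at-onset quartile boundaries across studies
#'
#' Computes onset-age quartiles (type-7 quantiles of case onset ages)
#' within each study, averages them arithmetically across studies to give
#' three boundaries, and records the median onset age of pooled cases
#' within each of the four resulting intervals (the x-coordinates used by
#' the age-trend regression).
#'
#' @param cohorts a cohort `data.frame` or a list of them.
#' @return An object of class `age_quartiles`: list with `boundaries`
#'   (three increasing ages) and `median_onset` (four ages).
#' @export
compute_age_quartiles <- function(cohorts) {
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  qs <- lapply(cohorts, function(coh) {
    onset <- coh$exit_age[coh$status == "disease"]
    if (length(onset) < 4L)
      stop("study '", .study_label(coh), "' has fewer than 4 cases")
    stats::quantile(onset, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  })
  boundaries <- colMeans(do.call(rbind, qs))
  if (any(diff(boundaries) <= 0))
    stop("degenerate onset-age quartiles (boundaries not strictly increasing)")
  onset_all <- unlist(lapply(cohorts, function(coh)
    coh$exit_age[coh$status == "disease"]))
  grp <- findInterval(onset_all, boundaries) + 1L
  med <- vapply(1:4, function(i) {
    if (!any(grp == i)) stop("no cases in onset-age interval ", i)
    stats::median(onset_all[grp == i])
  }, numeric(1))
  structure(list(boundaries = boundaries, median_onset = med),
            class = "age_quartiles")
}

#' Age-interval Cox fits with delayed entry
#'
#' Fits one Cox model per onset-age quartile interval. For interval
#' `[L, U)`: individuals whose disease onset precedes `L` are excluded
#' entirely; the rest enter the risk set at `L` (left truncation) provided
#' they are still under follow-up, and are censored at `U` if event-free.
#' Individuals whose follow-up ended before `L` contribute nothing.
#'
#' @inheritParams fit_cox_full
#' @param quartiles an [compute_age_quartiles()] object.
#' @return Four-row `data.frame` (`stratum = "age"`, `age_interval`
#'   1 to 4). Intervals without cases yield `converged = FALSE` rows.
#' @export
fit_cox_age_intervals <- function(cohort, quartiles, covariates = NULL) {
  .check_cohort(cohort)
  stopifnot(inherits(quartiles, "age_quartiles"))
  b <- quartiles$boundaries
  lower <- c(0, b)
  upper <- c(b, Inf)
  rows <- lapply(1:4, function(i) {
    L <- lower[i]; U <- upper[i]
    onset_before <- cohort$status == "disease" & cohort$exit_age < L
    at_risk <- !onset_before & cohort$exit_age > L
    sub <- cohort[at_risk, , drop = FALSE]
    event <- sub$status == "disease" & sub$exit_age < U
    if (!any(event))
      return(.hr_row("age", .study_label(cohort), n_cases = 0L,
                     n_controls = nrow(sub), converged = FALSE,
                     age_interval = i))
    f <- .fit_cox(sub, .cohort_rhs(sub, covariates),
                  entry = rep(L, nrow(sub)), exit = pmin(sub$exit_age, U),
                  event = event, term = "pgs")
    .hr_row("age", .study_label(sub), f$log_hr, f$se, sum(event),
            sum(!event), f$ok, age_interval = i)
  })
  out <- do.call(rbind, rows)
  attr(out, "median_onset") <- quartiles$median_onset
  out
}

.check_cohort <- function(cohort) {
  need <- c("study", "sex", "pgs", "status", "exit_age")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(cohort$status), c("disease", "other_death", "censored"))
  if (length(bad))
    stop("unknown status values: ", paste(bad, collapse = ", "))
  invisible(cohort)
}
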