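#' Predict hazard ratios from a fitted age trend
#'
#' Evaluates `exp(intercept + slope * age)` inside the age span of the
#' estimates that support the trend; outside that span the prediction is
#' held constant at the nearest endpoint (the HR closest in age), so
#' extrapolation never amplifies the trend.
#'
#' @param trend an [age_trend_wls()] object.
#' @param age ages in years (vectorized).
#' @return Hazard ratios at `age`.
#' @export
predict_hr_by_age <- function(trend, age) {
  stopifnot(inherits(trend, "age_trend"))
  a <- pmin(pmax(age, trend$range[1]), trend$range[2])
  exp(trend$intercept + trend$slope * a)
}

#' Per-group hazard-ratio specification for recalibration
#'
#' Bundles, for each PGS group, its population proportion and its hazard
#' ratio versus the reference group. An HR entry may be a positive scalar
#' (constant over age) or an [age_trend_wls()] object (age-varying). The
#' reference group's HR is identically 1.
#'
#' @param group group labels.
#' @param proportion population proportions (must sum to 1).
#' @param hr numeric vector of HRs, or a list mixing scalars and
#'   `age_trend` objects, aligned with `group`.
#' @param se standard errors of the log-HRs (NA where unknown or where
#'   the entry is an age trend carrying its own covariance).
#' @param reference label of the reference group.
#' @return Object of class `strata_hr`.
#' @export
strata_hr <- function(group, proportion, hr, se = NULL, reference) {
  stopifnot(length(group) == length(proportion))
  if (abs(sum(proportion) - 1) > 1e-8) stop("proportions must sum to 1")
  if (!reference %in% group) stop("reference group missing")
  if (!is.list(hr)) hr <- as.list(hr)
  if (length(hr) != length(group)) stop("hr must align with group")
  if (is.null(se)) se <- rep(NA_real_, length(group))
  ref_i <- match(reference, group)
  hr[[ref_i]] <- 1
  se[ref_i] <- 0
  for (i in seq_along(hr)) {
    if (is.numeric(hr[[i]]) && (length(hr[[i]]) != 1L || hr[[i]] <= 0))
      stop("scalar HR entries must be single positive numbers")
    if (!is.numeric(hr[[i]]) && !inherits(hr[[i]], "age_trend"))
      stop("hr entries must be scalars or age_trend objects")
  }
  structure(list(group = as.character(group), proportion = proportion,
                 hr = hr, se = se, reference = reference),
            class = "strata_hr")
}

# HRs of every group at one age (reference = 1 by construction)
resolve_hrs <- function(strata, age) {
  vapply(strata$hr, function(h) {
    if (inherits(h, "age_trend")) predict_hr_by_age(h, age) else h
  }, numeric(1))
}

#' Reference-group incidence from the population incidence
#'
#' Inverts the population constraint "total incidence is the
#' proportion-weighted average of group incidences":
#' \deqn{I_0 = \frac{n I}{n_0 + \sum_{i \ne 0} HR_i\, n_i},}
#' i.e. `I / sum(proportion * HR)` with the reference HR equal to 1.
#'
#' @param incidence population incidence rate `I` (vectorized).
#' @param strata a [strata_hr()].
#' @param age age (years) at which age-varying HRs are evaluated.
#' @return Reference-group incidence `I_0`.
#' @export
reference_incidence <- function(incidence, strata, age = NA) {
  hrv <- resolve_hrs(strata, age)
  denom <- sum(strata$proportion * hrv)
  if (!is.finite(denom) || denom <= 0) stop("zero or invalid denominator")
  incidence / denom
}

#' Per-group incidences from the reference incidence
#'
#' `I_i = I_0 * HR_i`; the reference group returns `I_0` itself.
#'
#' @param i0 reference-group incidence.
#' @param strata a [strata_hr()].
#' @param age age at which age-varying HRs are evaluated.
#' @return Named vector of group incidences.
#' @export
group_incidences <- function(i0, strata, age = NA) {
  if (any(i0 < 0)) stop("reference incidence must be >= 0")
  stats::setNames(i0 * resolve_hrs(strata, age), strata$group)
}

#' PGS-stratified cumulative incidence curves
#'
#' The absolute-risk recalibration: for every five-year age bin the
#' population incidence is split into per-group incidences through
#' [reference_incidence()] and [group_incidences()] (age-varying HRs are
#' evaluated at the bin midpoint), each group's incidence is converted to
#' a hazard with the *population* prevalence, and a competing-risk
#' [life_table()] is built per group with the shared other-cause
#' mortality. The unstratified population curve is included as stratum
#' `"population"`.
#'
#' @param rates a validated rate table (see [read_rate_table()]).
#' @param strata a [strata_hr()], or a named list
#'   `list(female = , male = )` of them.
#' @param location,sex select one (location, sex) slice of `rates`;
#'   may be omitted when the table contains a single one.
#' @return Object of class `risk_curves`: `data.frame` with columns
#'   `location`, `sex`, `stratum`, `age` (0 to 80 by 5),
#'   `cumulative_incidence`, `survival` (at `age`) and `hazard` (of the
#'   bin starting at `age`; NA at 80), ready for [crossing_age()] and
#'   [ci_at_age()]-style interpolation.
#' @export
stratified_cumulative_incidence <- function(rates, strata,
                                            location = NULL, sex = NULL) {
  rates <- validate_rate_table(rates)
  if (is.null(location)) {
    location <- unique(rates$location)
    if (length(location) > 1L) stop("specify `location`")
  }
  if (is.null(sex)) {
    sex <- unique(rates$sex)
    if (length(sex) > 1L) stop("specify `sex`")
  }
  if (!inherits(strata, "strata_hr")) {
    if (!is.list(strata) || is.null(strata[[sex]]))
      stop("strata must be a strata_hr or a per-sex named list of them")
    strata <- strata[[sex]]
  }
  sub <- rates[rates$location == location & rates$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rates for (", location, ", ", sex, ")")
  sub <- sub[order(sub$age), , drop = FALSE]

  ngrp <- length(strata$group)
  mids <- sub$age + 2.5
  hr_mat <- t(vapply(mids, function(a) resolve_hrs(strata, a),
                     numeric(ngrp)))                       # bins x groups
  i0 <- sub$incidence / as.vector(hr_mat %*% strata$proportion)
  inc_mat <- i0 * hr_mat

  build <- function(inc, label) {
    lt <- life_table(inc, sub$prevalence, sub$cause_mortality,
                     sub$all_cause_mortality)
    data.frame(location = location, sex = sex, stratum = label,
               age = c(lt$age, 80),
               cumulative_incidence = lt$cum_inc,
               survival = lt$survival,
               hazard = c(lt$hazard, NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    build(sub$incidence, "population"),
    do.call(rbind, lapply(seq_len(ngrp), function(g)
      build(inc_mat[, g], strata$group[g])))
  )
  class(out) <- c("risk_curves", "data.frame")
  attr(out, "strata_hr") <- strata
  out
}

#' Transfer meta-analyzed hazard ratios to another country's baseline
#'
#' Pools per-group hazard ratios across studies by inverse-variance
#' fixed-effects meta-analysis on the log scale (age trends are pooled
#' coefficient-wise with their WLS variances) and recomputes the
#' stratified curves on the supplied country's rate table.
#'
#' @param rates rate table of the target country.
#' @param strata_list list of [strata_hr()] objects, one per study, with
#'   identical groups and reference.
#' @param location,sex passed to [stratified_cumulative_incidence()].
#' @return A `risk_curves` object based on the pooled HRs.
#' @export
transfer_with_meta_hrs <- function(rates, strata_list, location = NULL,
                                   sex = NULL) {
  strata <- pool_strata_hr(strata_list)
  stratified_cumulative_incidence(rates, strata, location, sex)
}

#' Pool per-study strata HRs by fixed-effects meta-analysis
#'
#' Inverse-variance pooling of each group's log-HR across studies (age
#' trends are pooled coefficient-wise). Used by
#' [transfer_with_meta_hrs()] and by multi-study pipelines that
#' meta-analyze HRs before computing cumulative incidence.
#'
#' @param strata_list list of [strata_hr()] objects with identical
#'   groups and reference.
#' @return A pooled [strata_hr()].
#' @export
pool_strata_hr <- function(strata_list) {
  stopifnot(length(strata_list) >= 1L,
            all(vapply(strata_list, inherits, logical(1), "strata_hr")))
  ref <- strata_list[[1]]
  for (s in strata_list[-1]) {
    if (!identical(s$group, ref$group) || !identical(s$reference, ref$reference))
      stop("all studies must share the same grouping and reference")
  }
  pooled_hr <- vector("list", length(ref$group))
  pooled_se <- rep(NA_real_, length(ref$group))
  for (i in seq_along(ref$group)) {
    entries <- lapply(strata_list, function(s) s$hr[[i]])
    if (ref$group[i] == ref$reference) {
      pooled_hr[[i]] <- 1
      pooled_se[i] <- 0
    } else if (all(vapply(entries, is.numeric, logical(1)))) {
      lh <- log(unlist(entries))
      se <- vapply(strata_list, function(s) s$se[i], numeric(1))
      if (length(lh) == 1L) {
        pooled_hr[[i]] <- exp(lh)
        pooled_se[i] <- se
      } else {
        if (any(!is.finite(se)))
          stop("missing SEs prevent pooling group '", ref$group[i], "'")
        m <- meta_fixed(lh, se)
        pooled_hr[[i]] <- exp(m$log_hr)
        pooled_se[i] <- m$se
      }
    } else if (all(vapply(entries, inherits, logical(1), "age_trend"))) {
      pooled_hr[[i]] <- .pool_age_trends(entries)
    } else {
      stop("group '", ref$group[i],
           "' mixes scalar and age-trend HRs across studies")
    }
  }
  strata_hr(ref$group, ref$proportion, pooled_hr, pooled_se, ref$reference)
}

# Coefficient-wise inverse-variance pooling of age trends; the pooled
# covariance keeps only the per-coefficient variances (off-diagonals from
# different studies are not combinable from summaries).
.pool_age_trends <- function(trends) {
  if (length(trends) == 1L) return(trends[[1]])
  ints <- vapply(trends, `[[`, numeric(1), "intercept")
  slps <- vapply(trends, `[[`, numeric(1), "slope")
  v_int <- vapply(trends, function(t) t$vcov[1, 1], numeric(1))
  v_slp <- vapply(trends, function(t) t$vcov[2, 2], numeric(1))
  w_i <- 1 / v_int; w_s <- 1 / v_slp
  rng <- range(unlist(lapply(trends, `[[`, "range")))
  structure(list(intercept = sum(w_i * ints) / sum(w_i),
                 slope = sum(w_s * slps) / sum(w_s),
                 vcov = diag(c(1 / sum(w_i), 1 / sum(w_s))),
                 range = rng, data = NULL),
            class = "age_trend")
}

#' Estimate per-group hazard ratios under a chosen stratification model
#'
#' Fits the PGS-group Cox models matching a model choice and packages the
#' result as per-sex [strata_hr()] objects ready for
#' [stratified_cumulative_incidence()]:
#' * `"full"`: one pooled fit; the same HRs apply to both sexes;
#' * `"sex"`: separate fits per sex;
#' * `"age"`: group HRs fitted within each onset-age quartile interval
#'   (delayed entry, as in [fit_cox_age_intervals()]) and summarized per
#'   group by a weighted log-HR-on-age regression evaluated at the median
#'   onset ages;
#' * `"age_and_sex"`: the age procedure within each sex.
#'
#' Groups with fewer than two converged quartile estimates fall back to
#' the group's constant (full-fit) HR.
#'
#' @param cohort cohort with a `pgs_group` column ([assign_pgs_groups()]).
#' @param model a [select_model()] object or one of `"full"`, `"sex"`,
#'   `"age"`, `"age_and_sex"`.
#' @param quartiles an [compute_age_quartiles()] object; required for the
#'   age-varying models.
#' @param covariates optional extra covariate columns.
#' @return Named list `list(female = strata_hr, male = strata_hr)`.
#' @export
estimate_strata_hr <- function(cohort, model = "full", quartiles = NULL,
                               covariates = NULL) {
  if (inherits(model, "model_choice")) model <- model$choice
  model <- match.arg(model, c("full", "sex", "age", "age_and_sex"))
  spec <- attr(cohort, "pgs_group_spec")
  if (is.null(spec)) stop("cohort lacks PGS group assignment")
  if (model %in% c("age", "age_and_sex") && is.null(quartiles))
    stop("age-varying models require onset-age quartiles")

  scalar_strata <- function(coh) {
    est <- fit_cox_pgs_groups(coh, covariates)
    .strata_from_groups(spec, est)
  }
  trend_strata <- function(coh) {
    est_full <- fit_cox_pgs_groups(coh, covariates)
    ints <- .fit_groups_by_interval(coh, quartiles, covariates)
    .strata_from_trends(spec, ints, quartiles$median_onset, est_full)
  }
  per_sex <- function(fun) {
    out <- lapply(c("female", "male"), function(sx) {
      sub <- cohort[cohort$sex == sx, , drop = FALSE]
      attr(sub, "pgs_group_spec") <- spec
      fun(sub)
    })
    names(out) <- c("female", "male")
    out
  }
  switch(model,
         full = { s <- scalar_strata(cohort); list(female = s, male = s) },
         sex = per_sex(scalar_strata),
         age = { s <- trend_strata(cohort); list(female = s, male = s) },
         age_and_sex = per_sex(trend_strata))
}

.strata_from_groups <- function(spec, est) {
  hr <- as.list(rep(1, length(spec$labels)))
  se <- rep(NA_real_, length(spec$labels))
  for (i in seq_along(spec$labels)) {
    g <- spec$labels[i]
    if (g == spec$reference) { se[i] <- 0; next }
    row <- est[est$pgs_group == g, , drop = FALSE]
    if (nrow(row) == 1L && row$converged) {
      hr[[i]] <- exp(row$log_hr)
      se[i] <- row$se
    } else {
      stop("no converged HR for group '", g, "'")
    }
  }
  strata_hr(spec$labels, spec$proportions, hr, se, spec$reference)
}

# Group-coded Cox fits within each onset-age quartile interval
.fit_groups_by_interval <- function(cohort, quartiles, covariates = NULL) {
  spec <- attr(cohort, "pgs_group_spec")
  b <- quartiles$boundaries
  lower <- c(0, b); upper <- c(b, Inf)
  lapply(1:4, function(i) {
    L <- lower[i]; U <- upper[i]
    keep <- !(cohort$status == "disease" & cohort$exit_age < L) &
      cohort$exit_age > L
    sub <- cohort[keep, , drop = FALSE]
    attr(sub, "pgs_group_spec") <- spec
    sub$status[sub$status == "disease" & sub$exit_age >= U] <- "censored"
    sub$exit_age <- pmin(sub$exit_age, U)
    tryCatch(.fit_groups_entry(sub, L, covariates),
             error = function(e) NULL)
  })
}

.fit_groups_entry <- function(cohort, entry_age, covariates = NULL) {
  spec <- attr(cohort, "pgs_group_spec")
  cohort$pgs_group <- stats::relevel(cohort$pgs_group, ref = spec$reference)
  event <- cohort$status == "disease"
  rhs <- .cohort_rhs(cohort, covariates, base = "pgs_group")
  f <- .fit_cox(cohort, rhs, entry = rep(entry_age, nrow(cohort)),
                exit = cohort$exit_age, event = event, term = NULL)
  groups <- setdiff(spec$labels, spec$reference)
  rows <- lapply(groups, function(g) {
    term <- paste0("pgs_group", g)
    ncase <- sum(event & cohort$pgs_group == g)
    if (is.null(f$coef) || !(term %in% names(f$coef)) ||
        is.na(f$coef[term]) || !is.finite(f$se_all[term]) || ncase == 0L)
      return(.hr_row("pgs_group", .study_label(cohort), n_cases = ncase,
                     converged = FALSE, pgs_group = g))
    .hr_row("pgs_group", .study_label(cohort), unname(f$coef[term]),
            unname(f$se_all[term]), ncase,
            sum(!event & cohort$pgs_group == g), f$ok, pgs_group = g)
  })
  do.call(rbind, rows)
}

.strata_from_trends <- function(spec, interval_ests, median_onset, est_full) {
  hr <- as.list(rep(1, length(spec$labels)))
  se <- rep(NA_real_, length(spec$labels))
  for (i in seq_along(spec$labels)) {
    g <- spec$labels[i]
    if (g == spec$reference) { se[i] <- 0; next }
    pts <- do.call(rbind, lapply(seq_along(interval_ests), function(j) {
      e <- interval_ests[[j]]
      if (is.null(e)) return(NULL)
      row <- e[e$pgs_group == g & e$converged, , drop = FALSE]
      if (nrow(row) != 1L) return(NULL)
      data.frame(log_hr = row$log_hr, se = row$se, age = median_onset[j])
    }))
    if (!is.null(pts) && nrow(pts) >= 2L) {
      hr[[i]] <- age_trend_wls(pts$log_hr, pts$se, pts$age)
    } else {
      row <- est_full[est_full$pgs_group == g, , drop = FALSE]
      if (nrow(row) != 1L || !row$converged)
        stop("no usable HR (trend or constant) for group '", g, "'")
      hr[[i]] <- exp(row$log_hr)
      se[i] <- row$se
    }
  }
  strata_hr(spec$labels, spec$proportions, hr, se, spec$reference)
}
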