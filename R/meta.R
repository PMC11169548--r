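#' Fixed-effects meta-analysis of log hazard ratios
#'
#' Inverse-variance fixed-effects pooling of log-HR estimates across
#' studies (weights `1/se^2`), computed with [metafor::rma()]. Rows with
#' `converged = FALSE` (when a `converged` column is present) are dropped;
#' pooling a single estimate returns it unchanged.
#'
#' @param log_hr numeric vector of log hazard ratios, or a `data.frame`
#'   of HR estimates with columns `log_hr`, `se` (and optionally
#'   `converged`).
#' @param se standard errors (ignored when `log_hr` is a `data.frame`).
#' @return List with `log_hr`, `se` (`= (sum of weights)^{-1/2}`), `Q`,
#'   `df`, `Q_p` and `k`.
#' @examples
#' meta_fixed(c(0.1, 0.3), c(0.1, 0.1))  # pooled 0.2, se ~ 0.0707
#' @export
meta_fixed <- function(log_hr, se = NULL) {
  if (is.data.frame(log_hr)) {
    est <- log_hr
    if ("converged" %in% names(est)) est <- est[est$converged, , drop = FALSE]
    log_hr <- est$log_hr
    se <- est$se
  }
  keep <- is.finite(log_hr) & is.finite(se) & se > 0
  log_hr <- log_hr[keep]; se <- se[keep]
  if (length(log_hr) == 0L) stop("no usable estimates to meta-analyze")
  fit <- metafor::rma(yi = log_hr, sei = se, method = "FE")
  list(log_hr = as.numeric(fit$beta), se = as.numeric(fit$se),
       Q = as.numeric(fit$QE), df = length(log_hr) - 1L,
       Q_p = as.numeric(fit$QEp), k = length(log_hr))
}

#' Cochran's Q heterogeneity test
#'
#' Tests homogeneity of a set of estimates against their inverse-variance
#' weighted mean: `Q = sum w (b - b_pooled)^2`, referred to a chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams meta_fixed
#' @return List with `Q`, `df` and `p`. Fewer than two usable estimates
#'   is an error.
#' @export
cochran_q <- function(log_hr, se = NULL) {
  if (is.data.frame(log_hr)) {
    est <- log_hr
    if ("converged" %in% names(est)) est <- est[est$converged, , drop = FALSE]
    log_hr <- est$log_hr
    se <- est$se
  }
  keep <- is.finite(log_hr) & is.finite(se) & se > 0
  log_hr <- log_hr[keep]; se <- se[keep]
  if (length(log_hr) < 2L) stop("Cochran's Q requires at least 2 estimates")
  m <- meta_fixed(log_hr, se)
  list(Q = m$Q, df = m$df, p = m$Q_p)
}

#' Weighted linear regression of log-HR on age
#'
#' Fits the age trend of the PGS effect: weighted least squares of the
#' quartile log-HR estimates on the median onset age of each quartile,
#' with inverse-variance weights (`1/se^2`) and a fixed-effects
#' meta-regression covariance (no residual variance inflation), via
#' [metafor::rma()] with an age moderator. With exactly two points the
#' line interpolates them and the covariance is propagated from the two
#' SEs.
#'
#' @param log_hr quartile log-HR estimates, or a `data.frame` of HR
#'   estimates (columns `log_hr`, `se`, optionally `converged`).
#' @param se standard errors.
#' @param age ages (years) at which the estimates are placed, typically
#'   the median onset age per quartile.
#' @return Object of class `age_trend`: list with `intercept`, `slope`,
#'   `vcov` (2x2), `range` (age span of the supporting estimates, used
#'   for constant extrapolation) and `data` (the points used).
#' @export
age_trend_wls <- function(log_hr, se = NULL, age = NULL) {
  if (is.data.frame(log_hr)) {
    est <- log_hr
    if (is.null(age)) age <- attr(est, "median_onset")
    if ("converged" %in% names(est)) {
      keep <- est$converged
      est <- est[keep, , drop = FALSE]
      age <- age[keep]
    }
    log_hr <- est$log_hr
    se <- est$se
  }
  keep <- is.finite(log_hr) & is.finite(se) & se > 0 & is.finite(age)
  log_hr <- log_hr[keep]; se <- se[keep]; age <- age[keep]
  if (length(log_hr) < 2L) stop("age trend requires at least 2 estimates")
  if (any(duplicated(age))) stop("duplicate ages; trend is not identifiable")
  fit <- metafor::rma(yi = log_hr, sei = se, mods = ~age, method = "FE")
  structure(list(intercept = as.numeric(fit$beta[1]),
                 slope = as.numeric(fit$beta[2]),
                 vcov = unname(as.matrix(stats::vcov(fit))),
                 range = range(age),
                 data = data.frame(log_hr = log_hr, se = se, age = age)),
            class = "age_trend")
}

#' Compare age-trend slopes between sexes
#'
#' Two-sided z-test of equal slopes for the female and male age trends,
#' using the sum of the slope variances (the two sexes are disjoint
#' samples, so independence is assumed).
#'
#' @param trend_f,trend_m [age_trend_wls()] objects for females and males.
#' @return List with `z` (female minus male, standardized) and `p`.
#' @export
compare_sex_slopes <- function(trend_f, trend_m) {
  stopifnot(inherits(trend_f, "age_trend"), inherits(trend_m, "age_trend"))
  v <- trend_f$vcov[2, 2] + trend_m$vcov[2, 2]
  if (!is.finite(v) || v <= 0) stop("missing or invalid slope covariance")
  z <- (trend_f$slope - trend_m$slope) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select the stratification model from the evidence record
#'
#' Deterministic decision rules choosing between the four candidate model
#' families given the heterogeneity evidence:
#' * **sex** if the meta-analyzed PGS-by-sex interaction is significant at
#'   `alpha_main`;
#' * **age** if Cochran's Q across the four onset-age quartiles is
#'   significant at `alpha_main`;
#' * **age_and_sex** if both of the above hold, or if quartile
#'   heterogeneity is significant within exactly one sex where it was not
#'   found overall, or if (given age-specific evidence in at least one of
#'   the overall or per-sex tests) the age-trend slopes differ between
#'   sexes at `alpha_slope`;
#' * **full** otherwise.
#'
#' Missing evidence entries (`NA` or `NULL`) are treated as
#' non-significant and recorded in the returned evidence. The slope
#' comparison is only consulted when some age-specific signal exists,
#' since it is a nominal-level test of a trend that is undefined without
#' one.
#'
#' @param p_interaction meta-analyzed PGS-by-sex interaction p-value.
#' @param p_q_overall Cochran's Q p-value across age quartiles, overall.
#' @param p_q_female,p_q_male per-sex quartile Q p-values.
#' @param p_slope_diff p-value of the sex difference in age-trend slopes.
#' @param alpha_main significance threshold for interaction and Q tests
#'   (default 0.05/18, a Bonferroni correction over 18 phenotypes).
#' @param alpha_slope nominal threshold for the slope comparison.
#' @return Object of class `model_choice`: list with `choice` (one of
#'   `"full"`, `"sex"`, `"age"`, `"age_and_sex"`) and the `evidence`
#'   record the choice is reproducible from.
#' @export
select_model <- function(p_interaction = NA, p_q_overall = NA,
                         p_q_female = NA, p_q_male = NA,
                         p_slope_diff = NA,
                         alpha_main = 0.05 / 18, alpha_slope = 0.05) {
  val <- function(p) if (is.null(p) || !is.finite(p)) NA_real_ else p
  ev <- list(p_interaction = val(p_interaction),
             p_q_overall = val(p_q_overall),
             p_q_female = val(p_q_female), p_q_male = val(p_q_male),
             p_slope_diff = val(p_slope_diff),
             alpha_main = alpha_main, alpha_slope = alpha_slope)
  sig <- function(p, a) !is.na(p) && p < a
  sex_sig <- sig(ev$p_interaction, alpha_main)
  age_sig <- sig(ev$p_q_overall, alpha_main)
  q_f <- sig(ev$p_q_female, alpha_main)
  q_m <- sig(ev$p_q_male, alpha_main)
  single_sex_age <- !age_sig && xor(q_f, q_m)
  any_age_signal <- age_sig || q_f || q_m
  slope_diff <- any_age_signal && sig(ev$p_slope_diff, alpha_slope)
  choice <- if ((sex_sig && age_sig) || single_sex_age || slope_diff) {
    "age_and_sex"
  } else if (sex_sig) {
    "sex"
  } else if (age_sig) {
    "age"
  } else {
    "full"
  }
  structure(list(choice = choice, evidence = ev), class = "model_choice")
}

#' Meta-analyze stratum estimates across studies
#'
#' Pools a stacked HR-estimate table across studies, separately within
#' each stratum descriptor (`stratum`, `sex`, `age_interval`,
#' `pgs_group`). Following the completeness rule for stratified schemes,
#' a study enters a scheme's meta-analysis only if it contributes a
#' converged estimate in *every* stratum of that scheme; dropped studies
#' are reported in the `dropped_studies` attribute.
#'
#' @param estimates stacked rows from the `fit_cox_*` functions, with a
#'   `study` column.
#' @return `data.frame` with one pooled row per stratum, carrying
#'   `log_hr`, `se`, `Q`, `df`, `Q_p` and `k`.
#' @export
meta_strata <- function(estimates) {
  stopifnot(all(c("study", "stratum", "log_hr", "se") %in% names(estimates)))
  dropped <- character(0)
  out <- lapply(split(estimates, estimates$stratum), function(scheme) {
    strata_key <- paste(scheme$sex, scheme$age_interval, scheme$pgs_group,
                        sep = "|")
    n_strata <- length(unique(strata_key))
    ok_by_study <- tapply(scheme$converged, scheme$study, function(x)
      sum(x) == n_strata)
    complete <- names(ok_by_study)[ok_by_study]
    dropped <<- union(dropped, names(ok_by_study)[!ok_by_study])
    scheme <- scheme[scheme$study %in% complete, , drop = FALSE]
    if (nrow(scheme) == 0L) return(NULL)
    strata_key <- paste(scheme$sex, scheme$age_interval, scheme$pgs_group,
                        sep = "|")
    res <- lapply(split(scheme, strata_key, drop = TRUE), function(g) {
      m <- meta_fixed(g)
      cbind(g[1, c("stratum", "sex", "age_interval", "pgs_group")],
            data.frame(log_hr = m$log_hr, se = m$se, Q = m$Q, df = m$df,
                       Q_p = m$Q_p, k = m$k))
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "dropped_studies") <- dropped
  out
}
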