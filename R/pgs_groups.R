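#' PGS percentile grouping specification
#'
#' Defines the cut points, labels, expected proportions and reference
#' group of a PGS percentile grouping. The default follows the common
#' screening-oriented scheme `<20%`, `20-40%`, `40-60%` (reference),
#' `60-80%`, `80-90%`, `90-95%`, `>95%`; an extended tails scheme adds
#' `<1%` and `>99%` groups.
#'
#' @param cuts strictly increasing percentile cut points in (0, 100).
#' @param reference label of the reference group (must match one of the
#'   generated labels).
#' @return Object of class `pgs_group_spec` with elements `cuts`,
#'   `labels`, `proportions` (summing to 1) and `reference`.
#' @examples
#' pgs_group_spec()$labels
#' pgs_group_spec(cuts = c(1, 20, 40, 60, 80, 90, 95, 99))$labels
#' @export
pgs_group_spec <- function(cuts = c(20, 40, 60, 80, 90, 95),
                           reference = "40-60") {
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 100))
    stop("cut points must be strictly increasing and inside (0, 100)")
  k <- length(cuts)
  labels <- c(paste0("<", cuts[1]),
              if (k > 1) paste0(cuts[-k], "-", cuts[-1]),
              paste0(">", cuts[k]))
  proportions <- diff(c(0, cuts, 100)) / 100
  stopifnot(abs(sum(proportions) - 1) < 1e-12)
  if (!reference %in% labels)
    stop("reference group '", reference, "' is not one of: ",
         paste(labels, collapse = ", "))
  structure(list(cuts = cuts, labels = labels, proportions = proportions,
                 reference = reference),
            class = "pgs_group_spec")
}

#' Assign individuals to PGS percentile groups
#'
#' Computes percentile ranks within each study by linear interpolation of
#' the empirical distribution (rank scaled as `(r - 1) / (n - 1) * 100`,
#' the type-7 convention) and bins them into the half-open intervals
#' `[lower, upper)` of the spec, with the top group closed at 100. With
#' distinct PGS values the group sizes match the spec proportions up to
#' integer rounding.
#'
#' @param cohort cohort `data.frame`.
#' @param spec a [pgs_group_spec()].
#' @return The cohort with a `pgs_group` factor column (levels in spec
#'   order) and the spec attached as `attr(, "pgs_group_spec")`.
#' @export
assign_pgs_groups <- function(cohort, spec = pgs_group_spec()) {
  stopifnot(inherits(spec, "pgs_group_spec"))
  .check_cohort(cohort)
  cohort$pgs_group <- factor(NA_character_, levels = spec$labels)
  for (s in unique(cohort$study)) {
    i <- which(cohort$study == s)
    n <- length(i)
    if (n < 2L || stats::sd(cohort$pgs[i]) == 0 || !all(is.finite(cohort$pgs[i])))
      stop("PGS ranks undefined in study '", s,
           "' (need >= 2 finite, non-identical values)")
    pct <- (rank(cohort$pgs[i], ties.method = "average") - 1) / (n - 1) * 100
    cohort$pgs_group[i] <- spec$labels[findInterval(pct, spec$cuts) + 1L]
  }
  attr(cohort, "pgs_group_spec") <- spec
  cohort
}

#' Cox fits per PGS group versus the reference group
#'
#' Fits a single Cox model with categorical PGS-group coding (reference
#' level fixed by the spec), age as the timescale and sex as a covariate
#' when both sexes are present. Composable with sex and age
#' stratification by calling it on the corresponding cohort subsets.
#'
#' @param cohort cohort carrying a `pgs_group` column from
#'   [assign_pgs_groups()].
#' @param covariates optional extra covariate columns.
#' @return `data.frame` with one row per non-reference group
#'   (`stratum = "pgs_group"`). Groups that are empty or have no cases are
#'   flagged `converged = FALSE`.
#' @export
fit_cox_pgs_groups <- function(cohort, covariates = NULL) {
  .check_cohort(cohort)
  spec <- attr(cohort, "pgs_group_spec")
  if (is.null(cohort$pgs_group) || is.null(spec))
    stop("cohort lacks PGS group assignment; run assign_pgs_groups() first")
  if (sum(cohort$pgs_group == spec$reference &
            cohort$status == "disease", na.rm = TRUE) == 0L)
    stop("reference group '", spec$reference, "' has no cases")
  cohort$pgs_group <- stats::relevel(cohort$pgs_group, ref = spec$reference)
  event <- cohort$status == "disease"
  rhs <- .cohort_rhs(cohort, covariates, base = "pgs_group")
  f <- .fit_cox(cohort, rhs, entry = rep(0, nrow(cohort)),
                exit = cohort$exit_age, event = event, term = NULL)
  groups <- setdiff(spec$labels, spec$reference)
  rows <- lapply(groups, function(g) {
    term <- paste0("pgs_group", g)
    ncase <- sum(event & cohort$pgs_group == g)
    nctrl <- sum(!event & cohort$pgs_group == g)
    if (is.null(f$coef) || !(term %in% names(f$coef)) ||
        is.na(f$coef[term]) || !is.finite(f$se_all[term]) || ncase == 0L)
      return(.hr_row("pgs_group", .study_label(cohort), n_cases = ncase,
                     n_controls = nctrl, converged = FALSE, pgs_group = g))
    .hr_row("pgs_group", .study_label(cohort), unname(f$coef[term]),
            unname(f$se_all[term]), ncase, nctrl, f$ok, pgs_group = g)
  })
  out <- do.call(rbind, rows)
  attr(out, "pgs_group_spec") <- spec
  out
}
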