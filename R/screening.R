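# Evaluate one stratum's cumulative incidence at an arbitrary age using
# the constant-hazard within-bin closed form (see ci_at_age()).
.curve_ci_at <- function(sub, age) {
  sub <- sub[order(sub$age), , drop = FALSE]
  max_age <- max(sub$age)
  if (any(age < 0 | age > max_age))
    stop("age must be within [0, ", max_age, "]")
  k <- pmin(floor(age / 5) * 5, max_age - 5)
  j <- match(k, sub$age)
  t <- age - k
  sub$cumulative_incidence[j] + sub$survival[j] * (1 - exp(-t * sub$hazard[j]))
}

.one_stratum <- function(curves, stratum) {
  sub <- curves[curves$stratum == stratum, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no curve for stratum '", stratum, "'")
  sub[order(sub$age), , drop = FALSE]
}

#' Population risk threshold at an index age
#'
#' The cumulative incidence of the unstratified population at the
#' screening index age (for instance age 45 for type 2 diabetes or 50
#' for breast cancer), evaluated at annual (sub-bin) resolution. This is
#' the clinical threshold against which the PGS strata are compared.
#'
#' @param curves a `risk_curves` object containing a `"population"`
#'   stratum.
#' @param index_age guideline screening age in `[0, 80]`.
#' @return Threshold cumulative incidence.
#' @export
population_threshold <- function(curves, index_age) {
  if (index_age < 0 || index_age > 80)
    stop("index age must be within [0, 80]")
  .curve_ci_at(.one_stratum(curves, "population"), index_age)
}

#' Age at which a stratum's curve reaches a risk threshold
#'
#' The smallest age `a` with `CI(a) >= threshold`, solved exactly within
#' the five-year bin under the piecewise-constant hazard (no linear
#' interpolation of the curve). If the threshold is not reached by age
#' 80 the sentinel `NA` is returned with attribute `not_reached = TRUE`;
#' no crossing age is ever fabricated beyond 80.
#'
#' @param curves a `risk_curves` object (or one stratum of it).
#' @param threshold cumulative-incidence threshold, >= 0.
#' @param stratum stratum label; may be omitted when `curves` holds a
#'   single stratum.
#' @return Crossing age in years, or `NA` if not reached by 80.
#' @export
crossing_age <- function(curves, threshold, stratum = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(stratum)) {
    stratum <- unique(curves$stratum)
    if (length(stratum) > 1L) stop("specify `stratum`")
  }
  sub <- .one_stratum(curves, stratum)
  ci <- sub$cumulative_incidence
  if (threshold <= 0) return(0)
  hit <- which(ci >= threshold)
  if (!length(hit))
    return(structure(NA_real_, not_reached = TRUE))
  j <- hit[1]
  if (j == 1L) return(sub$age[1])
  jp <- j - 1L
  frac <- (threshold - ci[jp]) / sub$survival[jp]
  t <- -log(1 - frac) / sub$hazard[jp]
  unname(sub$age[jp] + pmin(t, sub$age[j] - sub$age[jp]))
}

#' Screening report: threshold-crossing ages by PGS stratum
#'
#' Derives the population risk threshold at the index age and, for every
#' stratum, the age at which its cumulative incidence reaches that
#' threshold, with differences versus the index age and versus the
#' reference stratum. When a [bootstrap_config()] plus the underlying
#' rate table and strata HRs are supplied, percentile confidence
#' intervals for the crossing ages are computed by re-deriving the curves
#' over perturbed replicates (the clinical threshold itself is held fixed
#' at its point estimate).
#'
#' @param curves a `risk_curves` object with a `"population"` stratum.
#' @param index_age guideline screening age.
#' @param rates,strata inputs used to rebuild the curves during the
#'   bootstrap (optional).
#' @param boot a [bootstrap_config()] (optional).
#' @return Object of class `screening_report`: `data.frame` with columns
#'   `stratum`, `crossing_age`, `reached`, `diff_vs_index`,
#'   `diff_vs_reference` (and `lower`/`upper`/`n_undefined` under the
#'   bootstrap), with the threshold and index age as attributes.
#' @export
screening_report <- function(curves, index_age, rates = NULL,
                             strata = NULL, boot = NULL) {
  threshold <- population_threshold(curves, index_age)
  strata_labels <- unique(curves$stratum)
  cross <- vapply(strata_labels, function(s)
    as.numeric(crossing_age(curves, threshold, s)), numeric(1))
  sh <- attr(curves, "strata_hr")
  ref_label <- if (!is.null(sh)) sh$reference else NA_character_
  ref_age <- if (!is.na(ref_label) && ref_label %in% strata_labels)
    cross[ref_label] else NA_real_
  out <- data.frame(stratum = strata_labels,
                    crossing_age = unname(cross),
                    reached = is.finite(cross),
                    diff_vs_index = unname(cross - index_age),
                    diff_vs_reference = unname(cross - ref_age),
                    stringsAsFactors = FALSE)
  if (!is.null(boot)) {
    if (is.null(rates) || is.null(strata))
      stop("bootstrap CIs require the rate table and strata HRs")
    if (!inherits(strata, "strata_hr")) strata <- strata[[curves$sex[1]]]
    set.seed(boot$seed)
    draws <- matrix(NA_real_, boot$B, length(strata_labels))
    colnames(draws) <- strata_labels
    for (b in seq_len(boot$B)) {
      p <- .perturb_inputs(rates, strata, boot)
      cb <- stratified_cumulative_incidence(p$rates, p$strata,
                                            curves$location[1],
                                            curves$sex[1])
      draws[b, ] <- vapply(strata_labels, function(s)
        as.numeric(crossing_age(cb, threshold, s)), numeric(1))
    }
    qs <- apply(draws, 2L, function(v) {
      ok <- v[is.finite(v)]
      if (!length(ok)) return(c(NA_real_, NA_real_))
      stats::quantile(ok, boot$percentiles / 100, names = FALSE, type = 7)
    })
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
    out$n_undefined <- colSums(!is.finite(draws))
    out$reliable <- out$n_undefined <= boot$B / 2
  }
  structure(out, class = c("screening_report", "data.frame"),
            threshold = threshold, index_age = index_age)
}

#' Average screening reports across studies or countries
#'
#' Unweighted arithmetic mean of crossing ages per stratum across a list
#' of [screening_report()]s (strata reaching the threshold in every
#' report only).
#'
#' @param reports list of `screening_report` objects with common strata.
#' @return `data.frame` with `stratum`, `mean_crossing_age` and
#'   `n_reports`.
#' @export
aggregate_screening <- function(reports) {
  stopifnot(length(reports) >= 1L)
  strata <- reports[[1]]$stratum
  ages <- sapply(reports, function(r) r$crossing_age[match(strata, r$stratum)])
  ages <- matrix(ages, nrow = length(strata))
  data.frame(stratum = strata,
             mean_crossing_age = rowMeans(ages),
             n_reports = length(reports))
}
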