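#' Bootstrap configuration
#'
#' Settings for the parametric bootstrap: number of replicates, seed,
#' band percentiles, which parameter blocks to perturb, and how
#' age-trend uncertainty is propagated (`"sample"` draws (intercept,
#' slope) from their joint normal; `"refit"` resamples the quartile
#' log-HRs and refits the weighted regression in every replicate).
#'
#' @param B number of replicates (>= 2; 1000 reproduces conventional
#'   95% bands).
#' @param seed integer seed.
#' @param percentiles lower/upper band percentiles (default 2.5 / 97.5).
#' @param blocks parameter blocks to perturb: any of `"rates"` (baseline
#'   rates, log-normal within their 95% uncertainty bounds; prevalence on
#'   the logit scale), `"hr"` (scalar log-HRs, normal with their SEs),
#'   `"trend"` (age-trend coefficients).
#' @param trend_mode `"sample"` or `"refit"`.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000L, seed = 1L,
                             percentiles = c(2.5, 97.5),
                             blocks = c("rates", "hr", "trend"),
                             trend_mode = c("sample", "refit")) {
  stopifnot(B >= 2, length(percentiles) == 2,
            percentiles[1] > 0, percentiles[1] < percentiles[2],
            percentiles[2] < 100)
  blocks <- match.arg(blocks, c("rates", "hr", "trend"), several.ok = TRUE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 percentiles = percentiles, blocks = blocks,
                 trend_mode = match.arg(trend_mode)),
            class = "bootstrap_config")
}

# Draw one perturbed copy of (rates, strata) according to the blocks.
.perturb_inputs <- function(rates, strata, config) {
  if ("rates" %in% config$blocks) {
    for (m in c("incidence", "cause_mortality", "all_cause_mortality")) {
      lo <- rates[[paste0(m, "_lower")]]; up <- rates[[paste0(m, "_upper")]]
      if (is.null(lo) || is.null(up))
        stop("rates block requested but bounds for '", m, "' are missing")
      pos <- rates[[m]] > 0
      sdlog <- ifelse(pos, (log(pmax(up, 1e-300)) - log(pmax(lo, 1e-300))) /
                        (2 * stats::qnorm(0.975)), 0)
      rates[[m]][pos] <- exp(stats::rnorm(sum(pos), log(rates[[m]][pos]),
                                          sdlog[pos]))
    }
    lo <- rates$prevalence_lower; up <- rates$prevalence_upper
    if (is.null(lo) || is.null(up))
      stop("rates block requested but bounds for 'prevalence' are missing")
    pos <- rates$prevalence > 0 & rates$prevalence < 1
    logit <- function(p) log(p / (1 - p))
    sdl <- ifelse(pos & lo > 0 & up < 1,
                  (logit(up) - logit(lo)) / (2 * stats::qnorm(0.975)), 0)
    rates$prevalence[pos] <- stats::plogis(
      stats::rnorm(sum(pos), logit(rates$prevalence[pos]), sdl[pos]))
    # keep the perturbed table internally consistent
    rates$all_cause_mortality <- pmax(rates$all_cause_mortality,
                                      rates$cause_mortality)
  }
  strata$hr <- lapply(seq_along(strata$hr), function(i) {
    h <- strata$hr[[i]]
    if (strata$group[i] == strata$reference) return(h)
    if (is.numeric(h) && "hr" %in% config$blocks) {
      if (!is.finite(strata$se[i]))
        stop("hr block requested but SE missing for group '",
             strata$group[i], "'")
      return(exp(stats::rnorm(1, log(h), strata$se[i])))
    }
    if (inherits(h, "age_trend") && "trend" %in% config$blocks)
      return(.perturb_trend(h, config$trend_mode))
    h
  })
  list(rates = rates, strata = strata)
}

.perturb_trend <- function(trend, mode) {
  if (mode == "refit" && !is.null(trend$data) && nrow(trend$data) >= 2L) {
    d <- trend$data
    yi <- stats::rnorm(nrow(d), d$log_hr, d$se)
    return(age_trend_wls(yi, d$se, d$age))
  }
  v <- trend$vcov
  ev <- eigen(v, symmetric = TRUE)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  draw <- c(trend$intercept, trend$slope) + as.vector(root %*% stats::rnorm(2))
  out <- trend
  out$intercept <- draw[1]
  out$slope <- draw[2]
  out
}

#' Bootstrap confidence bands for stratified risk curves
#'
#' Recomputes the stratified cumulative-incidence curves over `B`
#' parameter-perturbed replicates and appends pointwise percentile bands
#' per (stratum, age). Deterministic under the config seed.
#'
#' @param rates rate table (with uncertainty bounds if the `"rates"`
#'   block is requested).
#' @param strata a [strata_hr()] (or per-sex list) with SEs for the
#'   requested blocks.
#' @param config a [bootstrap_config()].
#' @param location,sex slice selectors as in
#'   [stratified_cumulative_incidence()].
#' @return The point-estimate `risk_curves` with `lower` and `upper`
#'   columns appended.
#' @export
bootstrap_curves <- function(rates, strata, config = bootstrap_config(),
                             location = NULL, sex = NULL) {
  point <- stratified_cumulative_incidence(rates, strata, location, sex)
  strata1 <- attr(point, "strata_hr")
  set.seed(config$seed)
  reps <- matrix(NA_real_, nrow(point), config$B)
  for (b in seq_len(config$B)) {
    p <- .perturb_inputs(rates, strata1, config)
    cb <- stratified_cumulative_incidence(p$rates, p$strata,
                                          point$location[1], point$sex[1])
    reps[, b] <- cb$cumulative_incidence
  }
  qs <- apply(reps, 1L, stats::quantile,
              probs = config$percentiles / 100, names = FALSE, type = 7)
  point$lower <- qs[1, ]
  point$upper <- qs[2, ]
  point
}

#' Bootstrap percentile interval for a scalar summary
#'
#' Applies `fn(rates, strata, ...)` (a deterministic map to a scalar,
#' e.g. a threshold-crossing age) to `B` perturbed replicates and returns
#' the percentile interval. Replicates where the scalar is undefined
#' (`NA`, e.g. a threshold never reached) are counted; if more than half
#' are undefined the interval is flagged unreliable.
#'
#' @param fn function of `(rates, strata, ...)` returning one number.
#' @param rates,strata,config as in [bootstrap_curves()].
#' @param ... passed through to `fn`.
#' @return List with `point`, `lower`, `upper`, `n_undefined`, `B` and
#'   `reliable`.
#' @export
bootstrap_scalar <- function(fn, rates, strata, config = bootstrap_config(),
                             ...) {
  point <- fn(rates, strata, ...)
  set.seed(config$seed)
  vals <- vapply(seq_len(config$B), function(b) {
    p <- .perturb_inputs(rates, strata, config)
    as.numeric(fn(p$rates, p$strata, ...))
  }, numeric(1))
  n_na <- sum(!is.finite(vals))
  ok <- vals[is.finite(vals)]
  qs <- if (length(ok)) stats::quantile(ok, config$percentiles / 100,
                                        names = FALSE, type = 7)
        else c(NA_real_, NA_real_)
  list(point = point, lower = qs[1], upper = qs[2],
       n_undefined = n_na, B = config$B,
       reliable = n_na <= config$B / 2)
}

#' Band overlap between two sets of risk curves
#'
#' For every (stratum, age) shared by the two curve sets, checks whether
#' the second set's point estimate lies within the first set's bootstrap
#' band, as used when comparing transferred (meta-analyzed-HR) curves to
#' original country-specific estimates.
#'
#' @param curves_a `risk_curves` with `lower`/`upper` columns.
#' @param curves_b `risk_curves` (bands not required).
#' @return List with `table` (per stratum/age indicator) and `fraction`
#'   (proportion covered).
#' @export
ci_overlap <- function(curves_a, curves_b) {
  if (is.null(curves_a$lower) || is.null(curves_a$upper))
    stop("curves_a must carry bootstrap bands")
  key_a <- paste(curves_a$stratum, curves_a$age)
  key_b <- paste(curves_b$stratum, curves_b$age)
  if (!setequal(key_a, key_b))
    stop("curve sets are on different stratum/age grids")
  idx <- match(key_a, key_b)
  tab <- data.frame(stratum = curves_a$stratum, age = curves_a$age,
                    covered = curves_b$cumulative_incidence[idx] >=
                      curves_a$lower &
                      curves_b$cumulative_incidence[idx] <= curves_a$upper)
  list(table = tab, fraction = mean(tab$covered))
}
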