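#' Simulate a biobank-style cohort with known PGS effects
#'
#' Draws one individual-level cohort from the generative model described in
#' [sim_config()]. Each individual has a standard-normal PGS and a sex;
#' a disease age is sampled from the piecewise-constant baseline hazard
#' multiplied by `exp(logHR(age, sex) * PGS)` by exact inversion within
#' hazard segments (no time-step discretization), an other-cause death age
#' is sampled from its own piecewise-constant hazard, and the earliest of
#' disease, death and `max_age` determines status and exit age.
#'
#' @param cfg a [sim_config()].
#' @param study study label stored in the output.
#' @param log_hr_offset additive study-specific log-HR offset (used by
#'   [simulate_multistudy()]).
#' @param seed integer seed; defaults to `cfg$seed`. The same config and
#'   seed always reproduce the identical table.
#'
#' @return A `data.frame` with columns `study`, `id`, `sex` (`"female"` /
#'   `"male"`), `pgs`, `status` (`"disease"`, `"other_death"`,
#'   `"censored"`) and `exit_age`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 500, seed = 7))
#' table(coh$status)
#' @export
simulate_cohort <- function(cfg, study = "study_1", log_hr_offset = 0,
                            seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  n <- cfg$n_individuals
  sex <- ifelse(stats::runif(n) < cfg$sex_fraction_female, "female", "male")
  pgs <- stats::rnorm(n)
  e_disease <- stats::rexp(n)
  e_death <- stats::rexp(n)

  t_disease <- .invert_disease_time(cfg, sex, pgs, e_disease, log_hr_offset)
  t_death <- .invert_pw_time(.pw(cfg$other_mortality, cfg$max_age), e_death)

  exit_age <- pmin(t_disease, t_death, cfg$max_age)
  status <- ifelse(t_disease <= exit_age & t_disease < cfg$max_age, "disease",
                   ifelse(t_death < cfg$max_age, "other_death", "censored"))
  # guard the measure-zero tie disease == death in favour of disease
  status[t_disease == t_death & is.finite(t_disease)] <- "disease"
  data.frame(study = study, id = seq_len(n), sex = sex, pgs = pgs,
             status = status, exit_age = exit_age,
             stringsAsFactors = FALSE)
}

# Exact inversion of the individual disease cumulative hazard.
# logHR(a) * x = A + B * a with A = x*(beta0 + beta_sex*male + u -
# beta_age*age_ref), B = x*beta_age; within baseline segment j the
# cumulative hazard is h_j * exp(A) * (exp(B*t) - exp(B*s)) / B.
.invert_disease_time <- function(cfg, sex, pgs, e, log_hr_offset) {
  pw <- .pw(cfg$baseline_hazard, cfg$max_age)
  n <- length(pgs)
  male <- as.numeric(sex == "male")
  A <- pgs * (cfg$beta0 + cfg$beta_sex * male + log_hr_offset -
                cfg$beta_age * cfg$age_ref)
  B <- pgs * cfg$beta_age
  nseg <- length(pw$rates)
  lin <- abs(B) < 1e-12

  cum <- matrix(0, n, nseg)
  for (j in seq_len(nseg)) {
    s <- pw$breaks[j]; t <- pw$breaks[j + 1L]
    seg <- numeric(n)
    seg[lin] <- pw$rates[j] * exp(A[lin]) * (t - s)
    if (any(!lin)) {
      b <- B[!lin]
      seg[!lin] <- pw$rates[j] * exp(A[!lin]) * (exp(b * t) - exp(b * s)) / b
    }
    cum[, j] <- seg + if (j > 1L) cum[, j - 1L] else 0
  }

  idx <- rowSums(cum < e) + 1L
  out <- rep(Inf, n)
  hit <- idx <= nseg
  if (any(hit)) {
    j <- idx[hit]
    s <- pw$breaks[j]
    prev <- ifelse(j > 1L, cum[cbind(which(hit), pmax(j - 1L, 1L))], 0)
    prev[j == 1L] <- 0
    r <- e[hit] - prev
    h <- pw$rates[j]
    a <- A[hit]; b <- B[hit]
    tt <- numeric(sum(hit))
    l2 <- abs(b) < 1e-12
    tt[l2] <- s[l2] + r[l2] / (h[l2] * exp(a[l2]))
    if (any(!l2)) {
      tt[!l2] <- log(exp(b[!l2] * s[!l2]) +
                       r[!l2] * b[!l2] / (h[!l2] * exp(a[!l2]))) / b[!l2]
    }
    out[hit] <- tt
  }
  out
}

# Inversion for a covariate-free piecewise-constant hazard (other-cause
# mortality); zero-rate segments pass the exponential clock through.
.invert_pw_time <- function(pw, e) {
  cum <- cumsum(pw$rates * diff(pw$breaks))
  idx <- findInterval(e, cum) + 1L
  out <- rep(Inf, length(e))
  hit <- idx <= length(pw$rates) & pw$rates[pmin(idx, length(pw$rates))] > 0
  j <- idx[hit]
  prev <- ifelse(j > 1L, cum[pmax(j - 1L, 1L)], 0)
  out[hit] <- pw$breaks[j] + (e[hit] - prev) / pw$rates[j]
  out
}

#' Simulate several studies with between-study log-HR heterogeneity
#'
#' Draws one cohort per study, each with a study-specific log-HR offset
#' sampled from Normal(0, `study_sd`). With `study_sd = 0` the offsets are
#' exactly zero and a single study reproduces [simulate_cohort()] on the
#' same seed.
#'
#' @param cfg a [sim_config()] with `n_studies >= 1`.
#' @return A named list of cohorts (`study_1`, `study_2`, ...) with the
#'   drawn offsets attached as `attr(, "offsets")`.
#' @export
simulate_multistudy <- function(cfg) {
  validate_sim_config(cfg)
  k <- cfg$n_studies
  if (cfg$study_sd > 0) {
    set.seed(cfg$seed + 77003L)  # dedicated child stream for offsets
    offsets <- stats::rnorm(k, 0, cfg$study_sd)
  } else {
    offsets <- rep(0, k)
  }
  cohorts <- lapply(seq_len(k), function(s) {
    simulate_cohort(cfg, study = paste0("study_", s),
                    log_hr_offset = offsets[s],
                    seed = cfg$seed + (s - 1L))
  })
  names(cohorts) <- paste0("study_", seq_len(k))
  attr(cohorts, "offsets") <- offsets
  cohorts
}

# Disease cumulative hazard Lambda(age | x) for vectors of ages and PGS
# values; returns a length(ages) x length(x) matrix. Offset-free.
.cumhaz_disease_grid <- function(cfg, sex, ages, x) {
  pw <- .pw(cfg$baseline_hazard, cfg$max_age)
  male <- as.numeric(sex == "male")
  A <- x * (cfg$beta0 + cfg$beta_sex * male - cfg$beta_age * cfg$age_ref)
  B <- x * cfg$beta_age
  out <- matrix(0, length(ages), length(x))
  for (j in seq_along(pw$rates)) {
    s <- pw$breaks[j]; e <- pw$breaks[j + 1L]
    hi <- pmin(ages, e); lo <- pmin(ages, s)
    w <- pmax(hi - lo, 0)          # within-segment exposure per age
    act <- w > 0
    if (!any(act)) next
    for (i in which(act)) {
      lin <- abs(B) < 1e-12
      seg <- numeric(length(x))
      seg[lin] <- pw$rates[j] * exp(A[lin]) * w[i]
      if (any(!lin)) {
        b <- B[!lin]
        seg[!lin] <- pw$rates[j] * exp(A[!lin]) *
          (exp(b * hi[i]) - exp(b * lo[i])) / b
      }
      out[i, ] <- out[i, ] + seg
    }
  }
  out
}

# Gauss-Hermite nodes/weights transformed for E_X[f(X)], X ~ N(0,1)
.gh_normal <- function(nodes = 61L) {
  gh <- pracma::gaussHermite(nodes)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Derive the population rate table implied by a simulation configuration
#'
#' Computes, for each sex and 5-year age group, the analytic population
#' incidence rate, point prevalence at the bin midpoint, cause-specific
#' mortality (always 0: the generator does not model death from the
#' disease) and all-cause mortality implied by the generative model,
#' marginalized over the standard-normal PGS distribution by Gauss-Hermite
#' quadrature (and Gauss-Legendre quadrature over age within each bin).
#' The output has the shape of a GBD-style rate extract and is analytically
#' consistent with cohorts drawn by [simulate_cohort()].
#'
#' Definitions: prevalence is the proportion ever-diagnosed among those
#' alive at the bin midpoint (disease and death are independent given age,
#' so survival cancels); the incidence rate is expected new cases per
#' person-year alive within the bin.
#'
#' @param cfg a [sim_config()].
#' @param location location label for the output table.
#' @param gh_nodes number of Gauss-Hermite nodes for the PGS integral.
#' @param age_nodes Gauss-Legendre nodes per 5-year bin for the age
#'   integral.
#' @return A rate table `data.frame` with columns `location`, `sex`, `age`
#'   (bin lower bound, 0 to 75 by 5), `incidence`, `prevalence`,
#'   `cause_mortality`, `all_cause_mortality`.
#' @export
derive_population_rates <- function(cfg, location = "synthetic",
                                    gh_nodes = 61L, age_nodes = 8L) {
  validate_sim_config(cfg)
  gh <- .gh_normal(gh_nodes)
  if (any(!is.finite(gh$x)) || any(!is.finite(gh$w)))
    stop("quadrature failure: non-finite Gauss-Hermite nodes/weights")
  pw_mort <- .pw(cfg$other_mortality, cfg$max_age)
  bins <- seq(0, cfg$max_age - 5, by = 5)
  gl <- pracma::gaussLegendre(age_nodes, 0, 1)

  rows <- lapply(c("female", "male"), function(sx) {
    inc <- prev <- mort <- numeric(length(bins))
    for (i in seq_along(bins)) {
      m <- bins[i]
      # prevalence among alive at the bin midpoint
      lam_mid <- .cumhaz_disease_grid(cfg, sx, m + 2.5, gh$x)
      prev[i] <- sum(gh$w * (1 - exp(-lam_mid[1, ])))
      # incidence: new cases per person-year alive in [m, m+5)
      a <- m + 5 * gl$x                       # age nodes in the bin
      wa <- 5 * gl$w
      lam <- .cumhaz_disease_grid(cfg, sx, a, gh$x)
      h0 <- .pw_rate(.pw(cfg$baseline_hazard, cfg$max_age), a)
      male <- as.numeric(sx == "male")
      loghr <- outer(cfg$beta0 + cfg$beta_sex * male +
                       cfg$beta_age * (a - cfg$age_ref), gh$x)
      dens <- h0 * exp(loghr) * exp(-lam)     # case density per x
      f_new <- as.vector(dens %*% gh$w)       # E_x[...] at each age node
      alive <- exp(-.pw_cumhaz(pw_mort, a))
      num <- sum(wa * f_new * alive)
      den <- sum(wa * alive)
      if (!is.finite(num) || !is.finite(den) || den <= 0)
        stop("quadrature failure in bin [", m, ",", m + 5, ")")
      inc[i] <- num / den
      mort[i] <- sum(wa * .pw_rate(pw_mort, a) * alive) / den
    }
    data.frame(location = location, sex = sx, age = bins,
               incidence = inc, prevalence = prev,
               cause_mortality = 0, all_cause_mortality = mort,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analytic cumulative incidence of the generative model
#'
#' Exact (quadrature-level) continuous-time cumulative incidence
#' \deqn{CI(a) = E_X\left[\int_0^a \lambda(u \mid X)\,
#'   e^{-\Lambda(u \mid X) - M(u)}\,du\right]} for the generative model of
#' [sim_config()], optionally restricted to a PGS quantile slice
#' (`pgs_quantile_range`, proportions in \[0, 1\]). This is the ground
#' truth that life-table estimates and simulated cohorts are compared
#' against.
#'
#' @param cfg a [sim_config()].
#' @param sex `"female"` or `"male"`.
#' @param ages ages at which to report the cumulative incidence.
#' @param pgs_quantile_range lower/upper PGS quantiles defining the slice
#'   (default the whole population).
#' @param age_nodes Gauss-Legendre nodes per age segment.
#' @param x_nodes quadrature nodes for the PGS integral.
#' @return `data.frame` with columns `age`, `cumulative_incidence`.
#' @export
analytic_cumulative_incidence <- function(cfg, sex = "female",
                                          ages = seq(0, 80, 5),
                                          pgs_quantile_range = c(0, 1),
                                          age_nodes = 16L, x_nodes = 61L) {
  validate_sim_config(cfg)
  stopifnot(length(pgs_quantile_range) == 2,
            pgs_quantile_range[1] < pgs_quantile_range[2])
  if (identical(pgs_quantile_range, c(0, 1))) {
    q <- .gh_normal(x_nodes)
    xw <- q$w
    xx <- q$x
  } else {
    lo <- max(stats::qnorm(pgs_quantile_range[1]), -8.5)
    hi <- min(stats::qnorm(pgs_quantile_range[2]), 8.5)
    gl <- pracma::gaussLegendre(x_nodes, lo, hi)
    mass <- diff(pgs_quantile_range)
    xx <- gl$x
    xw <- gl$w * stats::dnorm(gl$x) / mass
  }
  pw_base <- .pw(cfg$baseline_hazard, cfg$max_age)
  pw_mort <- .pw(cfg$other_mortality, cfg$max_age)
  segs <- sort(unique(c(.pw_union_breaks(pw_base, pw_mort),
                        ages[ages > 0 & ages <= cfg$max_age])))
  segs <- segs[segs <= cfg$max_age]
  if (segs[1] != 0) segs <- c(0, segs)
  male <- as.numeric(sex == "male")

  gl_a <- pracma::gaussLegendre(age_nodes, 0, 1)
  cum <- 0
  boundary_ci <- stats::setNames(numeric(length(segs)), segs)
  boundary_ci[1] <- 0
  for (j in seq_len(length(segs) - 1L)) {
    s <- segs[j]; e <- segs[j + 1L]
    a <- s + (e - s) * gl_a$x
    wa <- (e - s) * gl_a$w
    lam <- .cumhaz_disease_grid(cfg, sex, a, xx)
    h0 <- .pw_rate(pw_base, a)
    loghr <- outer(cfg$beta0 + cfg$beta_sex * male +
                     cfg$beta_age * (a - cfg$age_ref), xx)
    surv_death <- exp(-.pw_cumhaz(pw_mort, a))
    dens <- (h0 * exp(loghr) * exp(-lam)) %*% xw
    cum <- cum + sum(wa * as.vector(dens) * surv_death)
    boundary_ci[j + 1L] <- cum
  }
  ci <- stats::approx(x = segs, y = boundary_ci, xout = pmin(ages, cfg$max_age),
                      rule = 2)$y
  data.frame(age = ages, cumulative_incidence = ci)
}
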