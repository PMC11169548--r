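# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops, brute-force likelihood
# maximization and bisection.

# Naive loop implementation of the rate -> life-table -> cumulative
# incidence computation, one scalar at a time.
naive_lifetable_ci <- function(incidence, prevalence, cause_mortality,
                               all_cause_mortality) {
  nbin <- length(incidence)
  hazard <- numeric(nbin)
  other <- numeric(nbin)
  for (j in seq_len(nbin)) {
    hazard[j] <- incidence[j] / (1 - prevalence[j])
    other[j] <- all_cause_mortality[j] - cause_mortality[j]
  }
  survival <- numeric(nbin + 1)
  survival[1] <- 1
  for (k in seq_len(nbin)) {
    tot <- 0
    for (m in seq_len(k)) tot <- tot + other[m] + hazard[m]
    survival[k + 1] <- exp(-5 * tot)
  }
  risk <- numeric(nbin)
  for (j in seq_len(nbin)) risk[j] <- 1 - exp(-5 * hazard[j])
  ci <- numeric(nbin + 1)
  for (a in seq_len(nbin)) {
    tot <- 0
    for (k in seq_len(a)) tot <- tot + survival[k] * risk[k]
    ci[a + 1] <- tot
  }
  list(survival = survival, risk = risk, ci = ci)
}

# Brute-force maximization of the (tie-free) Cox partial likelihood for a
# single covariate, with optional delayed entry.
oracle_cox_loglik <- function(beta, x, exit, event, entry = NULL) {
  if (is.null(entry)) entry <- rep(0, length(x))
  ll <- 0
  for (i in which(event)) {
    at_risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

oracle_cox_beta <- function(x, exit, event, entry = NULL) {
  stats::optimize(function(b) -oracle_cox_loglik(b, x, exit, event, entry),
                  interval = c(-8, 8), tol = 1e-10)$minimum
}

# Bisection solve of CI(a) = threshold on a monotone curve evaluator.
oracle_bisect_age <- function(f, threshold, lower = 0, upper = 80,
                              tol = 1e-6) {
  if (f(upper) < threshold) return(NA_real_)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) >= threshold) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

# Small default-shaped configs reused in tests
quick_config <- function(n = 20000, seed = 1, ...) {
  sim_config(n_individuals = n, seed = seed, ...)
}

# Random valid rate table for oracle-equivalence checks
random_rate_table <- function(seed) {
  set.seed(seed)
  data.frame(
    location = "x", sex = "female", age = seq(0, 75, 5),
    incidence = runif(16, 0, 0.05),
    prevalence = runif(16, 0, 0.6),
    cause_mortality = runif(16, 0, 0.01),
    all_cause_mortality = runif(16, 0.01, 0.05) + 0.01,
    stringsAsFactors = FALSE
  )
}
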