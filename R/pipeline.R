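#' Pipeline configuration
#'
#' Assembles the settings of a full pipeline run: the synthetic-cohort
#' generator, PGS grouping, bootstrap, significance thresholds, the
#' screening index age, stage toggles and the output directory. Can also
#' be loaded from a YAML or JSON file with [read_pipeline_config()].
#'
#' @param sim a [sim_config()].
#' @param group_spec a [pgs_group_spec()].
#' @param boot a [bootstrap_config()] or `NULL` to skip uncertainty
#'   bands.
#' @param alpha_main,alpha_slope model-selection thresholds (see
#'   [select_model()]).
#' @param index_age screening index age in years.
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run, in fixed order:
#'   `"simulate"`, `"associate"`, `"select"`, `"calibrate"`, `"screen"`.
#' @param seed master seed; reseeds every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            group_spec = pgs_group_spec(),
                            boot = bootstrap_config(B = 200L,
                                                    blocks = c("hr", "trend")),
                            alpha_main = 0.05 / 18, alpha_slope = 0.05,
                            index_age = 45,
                            out_dir = tempfile("pgsrisk_run_"),
                            stages = c("simulate", "associate", "select",
                                       "calibrate", "screen"),
                            seed = sim$seed) {
  stages <- match.arg(stages, c("simulate", "associate", "select",
                                "calibrate", "screen"), several.ok = TRUE)
  structure(list(sim = sim, group_spec = group_spec, boot = boot,
                 alpha_main = alpha_main, alpha_slope = alpha_slope,
                 index_age = index_age, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; the
#' `sim`, `group_spec` and `boot` entries are passed as argument lists to
#' their constructors ([sim_config()], [pgs_group_spec()],
#' [bootstrap_config()]); `boot: null` disables the bootstrap.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$sim)) {
    sa <- raw$sim
    for (nm in c("baseline_hazard", "other_mortality"))
      if (!is.null(sa[[nm]])) sa[[nm]] <- as.data.frame(sa[[nm]])
    args$sim <- do.call(sim_config, sa)
  }
  if (!is.null(raw$group_spec))
    args$group_spec <- do.call(pgs_group_spec, raw$group_spec)
  if (!is.null(raw$boot)) args$boot <- do.call(bootstrap_config, raw$boot)
  if (!is.null(raw) && "boot" %in% names(raw) && is.null(raw$boot))
    args["boot"] <- list(NULL)
  for (nm in c("alpha_main", "alpha_slope", "index_age", "out_dir",
               "stages", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

#' Run the full risk-stratification pipeline
#'
#' Orchestrates simulate, associate (standardize, group, Cox fits), model
#' selection, life-table calibration (with optional bootstrap bands) and
#' screening-age derivation, writing all tables as CSV, the model-choice
#' evidence and screening results as JSON, a plain-text log, and a
#' manifest with the seed, the numerical conventions in force and MD5
#' checksums of every output. Re-running with the same configuration
#' reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly; outputs are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("seed: %d", config$seed)
  logf("conventions: ties=efron; quantile=type7; alpha_main=%.3g; alpha_slope=%.3g; hr_age_eval=bin_midpoint; extrapolation=nearest_hr",
       config$alpha_main, config$alpha_slope)
  outputs <- character(0)
  save_csv <- function(x, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  save_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  cohorts <- choice <- curves <- NULL
  sim <- config$sim
  sim$seed <- config$seed

  if ("simulate" %in% config$stages) {
    cohorts <- simulate_multistudy(sim)
    save_csv(do.call(rbind, cohorts), "cohorts.csv")
    logf("simulate: %d studies x %d individuals", sim$n_studies,
         sim$n_individuals)
  }

  hr_table <- NULL
  quart <- NULL
  if ("associate" %in% config$stages) {
    if (is.null(cohorts)) stop("associate stage needs the simulate stage")
    cohorts <- lapply(cohorts, function(coh)
      assign_pgs_groups(standardize_pgs(coh), config$group_spec))
    quart <- compute_age_quartiles(cohorts)
    hr_table <- do.call(rbind, lapply(cohorts, function(coh) {
      rbind(fit_cox_full(coh),
            fit_cox_by_sex(coh),
            fit_cox_age_intervals(coh, quart))
    }))
    rownames(hr_table) <- NULL
    save_csv(hr_table, "hr_estimates.csv")
    logf("associate: %d HR estimates, quartile boundaries %s",
         nrow(hr_table), paste(round(quart$boundaries, 1), collapse = "/"))
  }

  if ("select" %in% config$stages) {
    if (is.null(hr_table)) stop("select stage needs the associate stage")
    ev <- pipeline_evidence(cohorts, quart)
    choice <- select_model(ev$p_interaction, ev$p_q_overall, ev$p_q_female,
                           ev$p_q_male, ev$p_slope_diff,
                           config$alpha_main, config$alpha_slope)
    save_json(list(choice = choice$choice, evidence = choice$evidence),
              "model_choice.json")
    logf("select: chose '%s'", choice$choice)
  }

  rates <- NULL
  if ("calibrate" %in% config$stages) {
    if (is.null(choice)) stop("calibrate stage needs the select stage")
    rates <- derive_population_rates(sim)
    save_csv(rates, "rates.csv")
    strata_by_study <- lapply(cohorts, estimate_strata_hr,
                              model = choice, quartiles = quart)
    curves <- list()
    for (sx in c("female", "male")) {
      pooled <- pool_strata_hr(lapply(strata_by_study, `[[`, sx))
      curves[[sx]] <- if (is.null(config$boot)) {
        stratified_cumulative_incidence(rates, pooled, sex = sx)
      } else {
        bootstrap_curves(rates, pooled, config$boot, sex = sx)
      }
      attr(curves[[sx]], "pooled_strata") <- pooled
    }
    save_csv(rbind(as.data.frame(curves$female),
                   as.data.frame(curves$male)), "risk_curves.csv")
    logf("calibrate: curves for %d strata per sex%s",
         length(unique(curves$female$stratum)),
         if (is.null(config$boot)) "" else sprintf(" with B=%d bands",
                                                   config$boot$B))
  }

  if ("screen" %in% config$stages) {
    if (is.null(curves)) stop("screen stage needs the calibrate stage")
    reports <- lapply(c("female", "male"), function(sx) {
      rep <- screening_report(curves[[sx]], config$index_age,
                              rates = rates,
                              strata = attr(curves[[sx]], "pooled_strata"),
                              boot = config$boot)
      cbind(sex = sx, as.data.frame(rep),
            threshold = attr(rep, "threshold"))
    })
    screen <- do.call(rbind, reports)
    save_csv(screen, "screening.csv")
    save_json(screen, "screening.json")
    logf("screen: index age %g", config$index_age)
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pgsrisk")),
    stages = config$stages,
    conventions = list(ties = "efron", quantile_type = 7,
                       alpha_main = config$alpha_main,
                       alpha_slope = config$alpha_slope,
                       hr_age_evaluation = "bin_midpoint",
                       hr_extrapolation = "nearest_endpoint"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  save_json(manifest, "manifest.json")
  invisible(manifest)
}

# Meta-analyzed model-selection evidence across studies
pipeline_evidence <- function(cohorts, quartiles) {
  inter <- lapply(cohorts, function(coh)
    tryCatch(fit_sex_interaction(coh), error = function(e) NULL))
  inter <- inter[!vapply(inter, is.null, logical(1))]
  inter <- inter[vapply(inter, `[[`, logical(1), "converged")]
  p_int <- if (length(inter)) {
    m <- meta_fixed(vapply(inter, `[[`, numeric(1), "log_hr"),
                    vapply(inter, `[[`, numeric(1), "se"))
    2 * stats::pnorm(-abs(m$log_hr / m$se))
  } else NA_real_

  q_for <- function(filter_sex = NULL) {
    ests <- do.call(rbind, lapply(cohorts, function(coh) {
      sub <- if (is.null(filter_sex)) coh else
        coh[coh$sex == filter_sex, , drop = FALSE]
      tryCatch(fit_cox_age_intervals(sub, quartiles),
               error = function(e) NULL)
    }))
    if (is.null(ests)) return(list(p = NA_real_, trend = NULL))
    pooled <- tryCatch(meta_strata(ests), error = function(e) NULL)
    if (is.null(pooled) || nrow(pooled) < 2L)
      return(list(p = NA_real_, trend = NULL))
    p <- tryCatch(cochran_q(pooled$log_hr, pooled$se)$p,
                  error = function(e) NA_real_)
    trend <- if (nrow(pooled) >= 2L)
      tryCatch(age_trend_wls(pooled$log_hr, pooled$se,
                             quartiles$median_onset[pooled$age_interval]),
               error = function(e) NULL) else NULL
    list(p = p, trend = trend)
  }
  overall <- q_for(NULL)
  female <- q_for("female")
  male <- q_for("male")
  p_slope <- if (!is.null(female$trend) && !is.null(male$trend))
    compare_sex_slopes(female$trend, male$trend)$p else NA_real_
  list(p_interaction = p_int, p_q_overall = overall$p,
       p_q_female = female$p, p_q_male = male$p, p_slope_diff = p_slope)
}

#' Validate pipeline input files
#'
#' Schema and invariant checks for CSV inputs: rate tables (validated
#' with [validate_rate_table()]) and cohort tables (status values,
#' exit ages within (0, 80], finite PGS). File type is inferred from the
#' header.
#'
#' @param paths character vector of file paths.
#' @param max_age upper bound for cohort exit ages.
#' @return `data.frame` with columns `file`, `type`, `ok`, `message`;
#'   an empty `message` means the file passed.
#' @export
validate_inputs <- function(paths, max_age = 80) {
  rows <- lapply(paths, function(p) {
    if (!file.exists(p))
      return(data.frame(file = p, type = "missing", ok = FALSE,
                        message = "file not found"))
    tab <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(tab))
      return(data.frame(file = p, type = "unreadable", ok = FALSE,
                        message = "could not parse as CSV"))
    if (all(c("incidence", "prevalence") %in% names(tab))) {
      msg <- tryCatch({ validate_rate_table(tab); "" },
                      error = function(e) conditionMessage(e))
      return(data.frame(file = p, type = "rate_table", ok = msg == "",
                        message = msg))
    }
    if (all(c("pgs", "status", "exit_age") %in% names(tab))) {
      problems <- character(0)
      bad <- setdiff(unique(tab$status),
                     c("disease", "other_death", "censored"))
      if (length(bad))
        problems <- c(problems, paste("unknown status:",
                                      paste(bad, collapse = ", ")))
      if (any(tab$exit_age <= 0 | tab$exit_age > max_age))
        problems <- c(problems,
                      paste0("exit_age outside (0, ", max_age, "]"))
      if (any(!is.finite(tab$pgs)))
        problems <- c(problems, "non-finite PGS values")
      msg <- paste(problems, collapse = "; ")
      return(data.frame(file = p, type = "cohort", ok = msg == "",
                        message = msg))
    }
    data.frame(file = p, type = "unknown", ok = FALSE,
               message = "unrecognized header")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
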