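# Cohort I/O and the end-to-end mapping pipeline: complete-case filter,
# specification grid (mixtures plus the OLS baseline), metrics, selection,
# prediction, simulation, calibration and exports.

required_cohort_columns <- c("id", "timepoint", "catprom5", "age", "sex",
                             "diabetes")

#' Read a cohort CSV
#'
#' Expects a header with columns `id`, `timepoint`, `catprom5`, `age`,
#' `sex`, `diabetes` and the instrument's outcome column (named by the
#' instrument id, e.g. `eq5d3l`, or plain `outcome`). Missing cells are
#' preserved as `NA`; non-missing outcomes are validated against the
#' instrument's value set with row-level error reporting. `sex` and
#' `diabetes` must be coded 0/1 (sex 1 = female, diabetes 1 = diabetic).
#'
#' @param path CSV file path; lines starting with `#` are ignored.
#' @param instrument target instrument id.
#' @return Cohort data frame with a standardised `outcome` column and the
#'   instrument id in `attr(, "instrument")`.
#' @export
read_cohort <- function(path, instrument) {
  spec <- value_set(instrument)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  out_col <- if (spec$instrument %in% names(df)) spec$instrument
             else if ("outcome" %in% names(df)) "outcome"
             else NA_character_
  missing_cols <- setdiff(required_cohort_columns, names(df))
  if (is.na(out_col))
    missing_cols <- c(missing_cols, paste0(spec$instrument, " (outcome)"))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (v in c("catprom5", "age", out_col)) df[[v]] <- as.numeric(df[[v]])
  for (v in c("sex", "diabetes")) {
    df[[v]] <- as.integer(df[[v]])
    bad <- !is.na(df[[v]]) & !df[[v]] %in% c(0L, 1L)
    if (any(bad))
      stop("column '", v, "' must be coded 0/1; offending row ",
           which(bad)[1L])
  }
  y <- df[[out_col]]
  ok <- is.na(y) | is_feasible(ifelse(is.na(y), spec$floor, y), spec)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    reason <- if (y[i] > spec$gap_lower && y[i] < spec$ceiling)
      sprintf("lies in the open gap (%g, %g)", spec$gap_lower,
              spec$ceiling)
    else sprintf("is outside [%g, %g]", spec$floor, spec$ceiling)
    stop(sprintf("infeasible %s value %g at row %d: %s",
                 spec$instrument, y[i], i, reason))
  }
  names(df)[names(df) == out_col] <- "outcome"
  attr(df, "instrument") <- spec$instrument
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: the `outcome` column is written under the
#' instrument's name so files are self-describing.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @param instrument instrument id (default: the cohort's attribute).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path,
                         instrument = attr(cohort, "instrument")) {
  if (!is.null(instrument) && "outcome" %in% names(cohort))
    names(cohort)[names(cohort) == "outcome"] <- instrument
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Configuration of an end-to-end mapping run
#'
#' Exactly one of `input` (a cohort CSV) or `scenario` (a
#' [cohort_scenario()], from which a synthetic cohort is simulated) must
#' be given.
#'
#' @param instrument target instrument id.
#' @param input path to a cohort CSV, or `NULL`.
#' @param scenario a [cohort_scenario()], or `NULL`.
#' @param components component counts for the grid.
#' @param covariate_universe covariates varied over the grid.
#' @param seed integer master seed, recorded in all outputs.
#' @param output_dir directory for the run artifacts (created if needed);
#'   `NULL` skips all file output.
#' @param confidence calibration interval level.
#' @param n_sim_values minimum number of simulated index values drawn
#'   from the selected model for the distribution comparison.
#' @param control an [aldvmm_control()] list.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(instrument, input = NULL, scenario = NULL,
                            components = c(2L, 3L),
                            covariate_universe = c("age", "sex",
                                                   "diabetes"),
                            seed = 1L, output_dir = NULL,
                            confidence = 0.95, n_sim_values = 1000L,
                            control = aldvmm_control()) {
  if (is.null(input) == is.null(scenario))
    stop("exactly one of 'input' and 'scenario' must be set")
  if (!is.null(scenario) && !inherits(scenario, "cohort_scenario"))
    stop("'scenario' must be a cohort_scenario object")
  structure(list(instrument = tolower(instrument), input = input,
                 scenario = scenario,
                 components = as.integer(components),
                 covariate_universe = covariate_universe,
                 seed = as.integer(seed), output_dir = output_dir,
                 confidence = confidence,
                 n_sim_values = as.integer(n_sim_values),
                 control = control),
            class = "pipeline_config")
}

# Fit every mixture specification in the grid; non-convergence is recorded
# per row, never raised.
run_grid <- function(cohort, grid, spec, control) {
  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ms <- grid[[i]]
    fit <- tryCatch(
      aldvmm(spec_mean_formula(ms), cohort,
             membership = spec_membership_formula(ms),
             components = ms$components, value_set = spec,
             control = control),
      error = function(e) NULL)
    fits[[i]] <- fit
    conv <- !is.null(fit) && fit$converged
    fv <- if (conv) face_validity(fit, cohort) else FALSE
    em <- if (!is.null(fit))
      error_metrics(cohort$outcome, fitted(fit))
    else c(rmse = NA_real_, mae = NA_real_)
    ic <- if (conv) information_criteria(fit)
          else c(AIC = NA_real_, BIC = NA_real_)
    rows[[i]] <- data.frame(
      model = "aldvmm", specification = spec_label(ms),
      components = ms$components,
      mean_covariates = paste(c("catprom5", ms$mean_covariates),
                              collapse = "+"),
      membership_covariates = paste(c("catprom5",
                                      ms$membership_covariates),
                                    collapse = "+"),
      rmse = unname(em["rmse"]), mae = unname(em["mae"]),
      aic = unname(ic["AIC"]), bic = unname(ic["BIC"]),
      converged = conv, face_valid = fv,
      n_restarts = if (is.null(fit)) NA_integer_ else fit$n_restarts_used)
  }
  list(fits = fits, metrics = do.call(rbind, rows))
}

# OLS baseline across all mean-covariate subsets, with gap diagnostics.
run_ols_grid <- function(cohort, covariate_universe, spec) {
  subsets <- all_subsets(covariate_universe)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    m <- subsets[[i]]
    fit <- fit_linear(cohort, m)
    fits[[i]] <- fit
    pred <- predict(fit)
    em <- error_metrics(cohort$outcome, pred)
    gv <- gap_violation_rate(pred, spec)
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    rows[[i]] <- data.frame(
      model = "ols",
      specification = paste0("OLS|mean:",
                             paste(c("catprom5", m), collapse = "+")),
      components = 1L,
      mean_covariates = paste(c("catprom5", m), collapse = "+"),
      membership_covariates = "",
      rmse = unname(em["rmse"]), mae = unname(em["mae"]),
      aic = as.numeric(stats::AIC(ll)), bic = -2 * as.numeric(ll) +
        k * log(fit$n),
      converged = TRUE, face_valid = face_validity(fit, cohort),
      n_restarts = 0L, prop_in_gap = gv$prop_in_gap,
      prop_outside_range = gv$prop_outside_range)
  }
  list(fits = fits, metrics = do.call(rbind, rows))
}

#' Run the full mapping pipeline
#'
#' Executes the method end to end: load or simulate the cohort,
#' complete-case filter, fit the mixture specification grid plus the OLS
#' baselines, compute metrics, apply the selection rule, predict from the
#' selected model, simulate at least `n_sim_values` index values from it,
#' build the decile calibration table and the distribution summary, and
#' (when `output_dir` is set) write the metrics, selected-model parameter
#' and covariance spreadsheets, calibration table, plots and a structured
#' log. Every CSV is stamped with the seed and a configuration hash. A
#' run in which no specification converges completes with the report
#' saying so rather than failing.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `utilmap_run`: list with the cohort,
#'   metrics table, selection, fits, predictions, simulated values,
#'   calibration table and distribution summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- value_set(config$instrument)
  # the hash identifies the analysis configuration; the output location
  # is not part of it
  hash <- config_hash(config[setdiff(names(config), "output_dir")])
  log_lines <- c(sprintf("utilmap pipeline run"),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", hash),
                 sprintf("instrument: %s", spec$instrument))

  cohort <- if (!is.null(config$input))
    read_cohort(config$input, spec$instrument)
  else simulate_cohort(config$scenario, spec$instrument,
                       seed = config$seed)
  n0 <- nrow(cohort)
  used <- unique(c(required_cohort_columns, "outcome"))
  cohort <- complete_case_filter(cohort, used)
  log_lines <- c(log_lines,
                 sprintf("cohort: %d rows (%d removed as incomplete)",
                         nrow(cohort), attr(cohort, "n_removed")))

  grid <- build_specification_grid(config$components,
                                   config$covariate_universe,
                                   spec$instrument)
  if (length(grid) == 0L) stop("invalid grid: no specifications")
  mix <- run_grid(cohort, grid, spec, config$control)
  ols <- run_ols_grid(cohort, config$covariate_universe, spec)
  metrics <- merge_metrics(mix$metrics, ols$metrics)
  log_lines <- c(log_lines,
    sprintf("grid: %d mixture specifications (%d converged), %d OLS",
            nrow(mix$metrics), sum(mix$metrics$converged),
            nrow(ols$metrics)))

  selection <- NULL
  selected_fit <- NULL
  predictions <- simulated <- NULL
  calibration <- NULL
  summaries <- NULL
  if (any(mix$metrics$converged)) {
    selection <- withCallingHandlers(
      select_model(mix$metrics),
      warning = function(w) {
        log_lines <<- c(log_lines, paste("selection:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    sel_idx <- attr(selection, "selected_index")
    selected_fit <- mix$fits[[sel_idx]]
    log_lines <- c(log_lines,
                   sprintf("selected: %s (%s)",
                           selection$specification,
                           attr(selection, "selection_note")))
    predictions <- fitted(selected_fit)
    n_draws <- max(1L, ceiling(config$n_sim_values / nrow(cohort)))
    simulated <- simulate_from_fit(selected_fit$params, cohort, spec,
                                   n_draws = n_draws,
                                   seed = config$seed + 1L)
    calibration <- decile_calibration(cohort$outcome, predictions,
                                      cohort$catprom5,
                                      confidence = config$confidence)
    summaries <- rbind(
      observed = summarize_distribution(cohort$outcome, spec),
      predicted = summarize_distribution(predictions, spec),
      simulated = summarize_distribution(simulated, spec))
  } else {
    log_lines <- c(log_lines,
      "selection: NO specification converged; no model selected")
  }

  run <- structure(list(config = config, cohort = cohort,
                        metrics = metrics, selection = selection,
                        fits = mix$fits, ols_fits = ols$fits,
                        selected_fit = selected_fit,
                        predictions = predictions, simulated = simulated,
                        calibration = calibration, summaries = summaries,
                        log = log_lines),
                   class = "utilmap_run")
  if (!is.null(config$output_dir)) write_run_artifacts(run)
  run
}

merge_metrics <- function(mix, ols) {
  mix$prop_in_gap <- 0
  mix$prop_outside_range <- 0
  mix$prop_in_gap[!mix$converged] <- NA_real_
  mix$prop_outside_range[!mix$converged] <- NA_real_
  rbind(mix, ols)
}

#' @export
print.utilmap_run <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  if (!is.null(x$summaries)) {
    cat("\nDistribution summary (observed / predicted / simulated):\n")
    print(round(x$summaries, 4))
  }
  invisible(x)
}

write_run_artifacts <- function(run) {
  config <- run$config
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%d config_hash=%s", config$seed,
                   config_hash(config[setdiff(names(config),
                                              "output_dir")]))
  path <- function(f) file.path(config$output_dir, f)
  write_stamped <- function(df, file) {
    con <- file(path(file), "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.csv(format_sig(df), con, row.names = FALSE)
  }
  write_stamped(run$metrics, "metrics.csv")
  if (!is.null(run$selected_fit)) {
    export_parameters(run$selected_fit, path("parameters.csv"),
                      path("vcov.csv"))
    write_stamped(as.data.frame(run$calibration), "calibration.csv")
    write_stamped(data.frame(series = rownames(run$summaries),
                             run$summaries), "summary.csv")
    grDevices::png(path("fit_histograms.png"), 900, 450)
    plot(run$selected_fit, which = 1, catprom5 = run$cohort$catprom5)
    grDevices::dev.off()
    grDevices::png(path("calibration.png"), 700, 500)
    plot_calibration(run$calibration)
    grDevices::dev.off()
  }
  writeLines(c(run$log,
               sprintf("tolerances: reltol=%g grad_tol=%g",
                       config$control$reltol, config$control$grad_tol)),
             path("run_log.txt"))
  invisible(run)
}
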