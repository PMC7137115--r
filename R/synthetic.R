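# Synthetic cataract-surgery cohorts. The generator emulates the marginal
# structure of a pre/post cataract-surgery cohort of older adults: age
# from a truncated normal (eligibility at 50+), sex and diabetic status as
# independent Bernoulli draws, the Cat-PROM5 index (more negative =
# better vision-related outcome) from a truncated normal matched to the
# published per-timepoint mean/SD/range, and target indices drawn from a
# known ALDVMM so downstream estimation can be validated against truth.

#' Covariate scenario for a synthetic cohort
#'
#' Defaults reproduce the published cohort marginals: mean age 73.8 years
#' (SD 8.2, eligibility at 50+), 51% women, 19% diabetic; Cat-PROM5 at
#' baseline mean -0.31, SD 2.34, range \[-9.18, 7.45\], and at follow-up
#' (6-8 weeks after surgery) mean -3.20, SD 3.08, range \[-9.18, 4.98\].
#'
#' @param timepoint `"baseline"` or `"followup"`; sets the Cat-PROM5
#'   defaults.
#' @param n cohort size.
#' @param age_mean,age_sd target mean and SD (years) of the age marginal
#'   after truncation at `age_min`; the generator solves for the
#'   underlying normal so the realised moments match these.
#' @param age_min eligibility age; the age distribution is truncated here.
#' @param prop_female,prop_diabetic Bernoulli probabilities (sex coded
#'   1 = female, diabetes 1 = diabetic).
#' @param catprom5_mean,catprom5_sd,catprom5_range target mean/SD and
#'   truncation range of the Cat-PROM5 marginal (moment-matched the same
#'   way).
#' @param seed integer seed used by [generate_covariates()].
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(timepoint = c("baseline", "followup"),
                            n = 1000L,
                            age_mean = 73.8, age_sd = 8.2, age_min = 50,
                            prop_female = 0.51, prop_diabetic = 0.19,
                            catprom5_mean = NULL, catprom5_sd = NULL,
                            catprom5_range = NULL, seed = 1L) {
  timepoint <- match.arg(timepoint)
  if (is.null(catprom5_mean))
    catprom5_mean <- if (timepoint == "baseline") -0.31 else -3.20
  if (is.null(catprom5_sd))
    catprom5_sd <- if (timepoint == "baseline") 2.34 else 3.08
  if (is.null(catprom5_range))
    catprom5_range <- if (timepoint == "baseline") c(-9.18, 7.45)
                      else c(-9.18, 4.98)
  if (n <= 0) stop("invalid scenario: n must be positive")
  if (prop_female < 0 || prop_female > 1 ||
      prop_diabetic < 0 || prop_diabetic > 1)
    stop("invalid scenario: proportions must lie in [0, 1]")
  if (age_sd <= 0 || catprom5_sd <= 0)
    stop("invalid scenario: standard deviations must be positive")
  if (catprom5_range[1L] >= catprom5_range[2L])
    stop("invalid scenario: catprom5_range must be increasing")
  structure(list(timepoint = timepoint, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd, age_min = age_min,
                 prop_female = prop_female, prop_diabetic = prop_diabetic,
                 catprom5_mean = catprom5_mean, catprom5_sd = catprom5_sd,
                 catprom5_range = catprom5_range,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Read a covariate scenario from a key-value configuration file
#'
#' One `key = value` pair per line (`#` comments allowed); keys are the
#' [cohort_scenario()] argument names, with `catprom5_min`/`catprom5_max`
#' for the range endpoints. Unspecified keys fall back to the scenario
#' defaults.
#'
#' @param path path to the configuration file.
#' @return A [cohort_scenario()] object.
#' @export
read_scenario <- function(path) {
  kv <- read_keyvalue(path)
  num <- function(key) if (key %in% names(kv)) as.numeric(kv[[key]])
  args <- list(
    timepoint = if ("timepoint" %in% names(kv)) kv[["timepoint"]]
                else "baseline",
    n = num("n") %||% 1000L,
    seed = num("seed") %||% 1L)
  for (key in c("age_mean", "age_sd", "age_min", "prop_female",
                "prop_diabetic", "catprom5_mean", "catprom5_sd"))
    if (!is.null(num(key))) args[[key]] <- num(key)
  if (!is.null(num("catprom5_min")) || !is.null(num("catprom5_max"))) {
    if (is.null(num("catprom5_min")) || is.null(num("catprom5_max")))
      stop("scenario config must set both catprom5_min and catprom5_max")
    args$catprom5_range <- c(num("catprom5_min"), num("catprom5_max"))
  }
  do.call(cohort_scenario, args)
}

#' Generate cohort covariates (outcomes left missing)
#'
#' @param scenario a [cohort_scenario()].
#' @param seed optional seed overriding the scenario's.
#' @return Data frame with columns `id`, `timepoint`, `catprom5`, `age`,
#'   `sex`, `diabetes` and an all-`NA` `outcome` column; fully
#'   reproducible for a given seed.
#' @export
generate_covariates <- function(scenario, seed = scenario$seed) {
  if (!inherits(scenario, "cohort_scenario"))
    stop("'scenario' must be a cohort_scenario object")
  n <- scenario$n
  # the scenario's mean/sd are target moments of the truncated marginal;
  # solve for the underlying normal so truncation does not shift them
  age_par <- truncnorm_match(scenario$age_mean, scenario$age_sd,
                             lower = scenario$age_min)
  cat_par <- truncnorm_match(scenario$catprom5_mean, scenario$catprom5_sd,
                             lower = scenario$catprom5_range[1L],
                             upper = scenario$catprom5_range[2L])
  with_seed(seed, {
    age <- rtruncnorm(n, age_par$mean, age_par$sd,
                      lower = scenario$age_min)
    sex <- stats::rbinom(n, 1L, scenario$prop_female)
    diabetes <- stats::rbinom(n, 1L, scenario$prop_diabetic)
    catprom5 <- rtruncnorm(n, cat_par$mean, cat_par$sd,
                           lower = scenario$catprom5_range[1L],
                           upper = scenario$catprom5_range[2L])
    data.frame(id = seq_len(n), timepoint = scenario$timepoint,
               catprom5 = catprom5, age = age, sex = sex,
               diabetes = diabetes, outcome = NA_real_)
  })
}

#' Fill cohort outcomes by drawing from a known ALDVMM
#'
#' The generator is the model's own data-generating process: each subject's
#' latent class is drawn from the multinomial-logit membership
#' probabilities, a latent normal from that class, and the draw is censored
#' to the value set (above the gap anchor to the ceiling, at or below the
#' floor to the floor). All generated outcomes are feasible by
#' construction.
#'
#' @param cohort data frame from [generate_covariates()] (or any table
#'   holding the parameter set's term columns).
#' @param true_params an [aldvmm_params()] object.
#' @param spec a [value_set()] or instrument id.
#' @param seed integer seed.
#' @return The cohort with `outcome` filled and the instrument recorded in
#'   `attr(, "instrument")`.
#' @export
generate_outcomes <- function(cohort, true_params, spec, seed = 1L) {
  spec <- value_set(spec)
  cohort$outcome <- simulate_from_fit(true_params, cohort, spec,
                                      n_draws = 1L, seed = seed)
  attr(cohort, "instrument") <- spec$instrument
  cohort
}

#' Default data-generating parameters per instrument
#'
#' Two-component parameter sets used as ground truth in validation
#' scenarios, calibrated (by the closed-form censoring probabilities, at
#' the baseline Cat-PROM5 mean) so that the implied population mean and
#' ceiling mass sit in the published range for each instrument: a
#' "healthy" class near the ceiling with a small scale, a lower morbid
#' class with a larger scale, and class membership loaded negatively on
#' Cat-PROM5 (a worse -- more positive -- Cat-PROM5 score lowers the
#' probability of the healthy class). Cat-PROM5 mean coefficients are
#' negative in both components.
#'
#' @param instrument `"eq5d3l"`, `"eq5d5l"` or `"icecapo"`.
#' @param diabetes_shift optional additive shift (index-value units) on
#'   the mean linear predictor for diabetic subjects; nonzero values add a
#'   `diabetes` mean term (around -0.06 reflects the published baseline
#'   EQ-5D-3L contrast).
#' @return An [aldvmm_params()] object.
#' @export
default_true_params <- function(instrument, diabetes_shift = 0) {
  base <- switch(tolower(instrument),
    eq5d3l = list(beta = cbind(c(0.88, -0.020), c(0.55, -0.035)),
                  sigma = c(0.10, 0.22),
                  gamma = cbind(c(0.4, -0.25))),
    eq5d5l = list(beta = cbind(c(0.93, -0.012), c(0.66, -0.030)),
                  sigma = c(0.06, 0.18),
                  gamma = cbind(c(0.0, -0.25))),
    icecapo = list(beta = cbind(c(0.97, -0.010), c(0.72, -0.025)),
                   sigma = c(0.05, 0.13),
                   gamma = cbind(c(0.2, -0.20))),
    stop("unsupported instrument '", instrument, "'"))
  mean_terms <- "catprom5"
  if (diabetes_shift != 0) {
    base$beta <- rbind(base$beta, diabetes_shift)
    mean_terms <- c("catprom5", "diabetes")
  }
  aldvmm_params(base$beta, base$sigma, base$gamma,
                mean_terms = mean_terms, membership_terms = "catprom5")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_covariates()] then [generate_outcomes()]
#' with [default_true_params()] unless other truth is supplied.
#'
#' @inheritParams generate_covariates
#' @param instrument target instrument id.
#' @param true_params data-generating [aldvmm_params()].
#' @return Cohort data frame with outcomes filled.
#' @export
simulate_cohort <- function(scenario, instrument,
                            true_params = default_true_params(instrument),
                            seed = scenario$seed) {
  cohort <- generate_covariates(scenario, seed = seed)
  generate_outcomes(cohort, true_params, value_set(instrument),
                    seed = seed + 1L)
}

#' Complete-case filter
#'
#' Removes rows with a missing value in any required column, preserving
#' row order; the number of rows removed is recorded in
#' `attr(, "n_removed")`.
#'
#' @param cohort data frame.
#' @param required_columns columns that must be non-missing (default: all
#'   columns).
#' @return The filtered data frame.
#' @export
complete_case_filter <- function(cohort, required_columns = names(cohort)) {
  unknown <- setdiff(required_columns, names(cohort))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  keep <- if (length(required_columns) == 0L) rep(TRUE, nrow(cohort))
          else stats::complete.cases(cohort[required_columns])
  out <- cohort[keep, , drop = FALSE]
  attr(out, "instrument") <- attr(cohort, "instrument")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Spearman rank correlation
#'
#' Rank correlation between a source score and a target index; ties are
#' handled by midranks, as in the exploratory association checks between
#' Cat-PROM5 and each target instrument.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return The correlation coefficient in \[-1, 1\].
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' have different lengths")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  stats::cor(x, y, method = "spearman")
}
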