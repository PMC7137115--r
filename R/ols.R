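# Ordinary least squares comparator. Linear models are the benchmark the
# mixture approach is judged against; their predictions are deliberately
# NOT clipped to the feasible range, because predicting into the gap or
# outside the bounds is exactly the failure mode under study.

#' Fit the linear (OLS) mapping baseline
#'
#' Regresses the target index on the Cat-PROM5 score plus any selected
#' covariates by least squares.
#'
#' @param cohort complete-case cohort data frame with `outcome`,
#'   `catprom5` and any requested covariate columns.
#' @param mean_covariates character subset of extra covariates (e.g.
#'   `c("age", "sex")`); Cat-PROM5 is always included.
#' @return An object of class `linear_map`: coefficients, `residual_scale`
#'   (maximum-likelihood residual standard deviation, `sqrt(RSS/n)`), `n`,
#'   and the underlying [stats::lm()] fit.
#' @export
fit_linear <- function(cohort, mean_covariates = character()) {
  if (!"outcome" %in% names(cohort)) stop("cohort lacks an 'outcome' column")
  vars <- c("catprom5", mean_covariates)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  f <- stats::reformulate(vars, response = "outcome")
  n <- nrow(cohort)
  if (n <= length(vars) + 1L) stop("more coefficients than observations")
  fit <- stats::lm(f, data = cohort)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(coefficients = stats::coef(fit),
                 residual_scale = sqrt(mean(stats::resid(fit)^2)),
                 n = n, mean_covariates = mean_covariates,
                 formula = f, lm_fit = fit),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, digits = 4, ...) {
  cat("Linear (OLS) mapping baseline, n =", x$n, "\n")
  print(round(x$coefficients, digits))
  cat("Residual scale (MLE):", signif(x$residual_scale, digits), "\n")
  invisible(x)
}

#' @export
coef.linear_map <- function(object, ...) object$coefficients

#' @export
predict.linear_map <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) unname(stats::fitted(object$lm_fit))
  else unname(stats::predict(object$lm_fit, newdata = newdata))
}

#' @export
fitted.linear_map <- function(object, ...) predict(object)

#' @export
residuals.linear_map <- function(object, ...)
  unname(stats::resid(object$lm_fit))

#' @export
logLik.linear_map <- function(object, ...) stats::logLik(object$lm_fit)

#' Gap and range violations of a prediction vector
#'
#' Fraction of predictions strictly inside the open gap
#' `(gap_lower, ceiling)` and fraction outside `[floor, ceiling]` -- the
#' infeasibility diagnostics under which unconstrained linear predictions
#' fail (a censored mixture has both at zero by construction).
#'
#' @param predictions numeric vector of predicted index values.
#' @param spec a [value_set()] or instrument id.
#' @return List with `prop_in_gap` and `prop_outside_range`.
#' @export
gap_violation_rate <- function(predictions, spec) {
  spec <- value_set(spec)
  if (length(predictions) == 0L) stop("empty prediction vector")
  in_gap <- predictions > spec$gap_lower & predictions < spec$ceiling
  outside <- predictions < spec$floor | predictions > spec$ceiling
  list(prop_in_gap = mean(in_gap), prop_outside_range = mean(outside))
}
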