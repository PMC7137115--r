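# S3 methods for fitted ALDVMMs, plus the closed-form prediction and
# simulation primitives shared with the synthetic-cohort generator.

# Closed-form E[Y | x, z] under censoring. With a = (L - mu)/sigma and
# b = (Psi - mu)/sigma, each component contributes
#   U (1 - Phi(b)) + L Phi(a) + mu (Phi(b) - Phi(a))
#     + sigma (phi(a) - phi(b)),
# and components are averaged with the membership probabilities.
expected_values <- function(params, X, Z, spec) {
  C <- params$n_components
  mu <- X %*% params$beta
  pmat <- membership_probabilities(Z, params$gamma)
  if (!is.matrix(pmat)) pmat <- matrix(pmat, nrow(X), C)
  E <- matrix(0, nrow(X), C)
  for (k in seq_len(C)) {
    s <- params$sigma[k]
    a <- (spec$floor - mu[, k]) / s
    b <- (spec$gap_lower - mu[, k]) / s
    E[, k] <- spec$ceiling * stats::pnorm(b, lower.tail = FALSE) +
      spec$floor * stats::pnorm(a) +
      mu[, k] * (stats::pnorm(b) - stats::pnorm(a)) +
      s * (stats::dnorm(a) - stats::dnorm(b))
  }
  unname(rowSums(pmat * E))
}

# One censored draw per row of mu; component picked from pmat.
draw_outcomes <- function(mu, sigma, pmat, spec) {
  n <- nrow(mu)
  C <- ncol(mu)
  comp <- if (C == 1L) rep(1L, n) else {
    u <- stats::runif(n)
    cs <- pmat %*% upper.tri(diag(C), diag = TRUE)
    1L + as.integer(rowSums(u > cs[, -C, drop = FALSE]))
  }
  latent <- stats::rnorm(n, mu[cbind(seq_len(n), comp)], sigma[comp])
  ifelse(latent > spec$gap_lower, spec$ceiling,
         pmax(latent, spec$floor))
}

#' Expected index values under an ALDVMM parameter set
#'
#' Closed-form expectation of the censored mixture for each cohort row;
#' every prediction lies in `[floor, ceiling]` by construction.
#'
#' @param params an [aldvmm_params()] object.
#' @param data cohort data frame holding the columns named by the
#'   parameter set's `mean_terms` and `membership_terms`.
#' @param spec a [value_set()] or instrument id.
#' @return Numeric vector of expected index values, one per row.
#' @export
predict_expected_value <- function(params, data, spec) {
  spec <- value_set(spec)
  des <- params_design(params, data, need_outcome = FALSE)
  expected_values(params, des$X, des$Z, spec)
}

#' Simulate index values from an ALDVMM parameter set
#'
#' Draws latent class membership from the multinomial logit, a latent
#' normal from the class, and censors it to the value set (above the gap
#' anchor to the ceiling, at or below the floor to the floor) -- the same
#' mechanism the synthetic-cohort generator uses. With `n_draws > 1` the
#' whole cohort is replicated per draw.
#'
#' @inheritParams predict_expected_value
#' @param n_draws replicates of the cohort to draw.
#' @param seed integer seed (the caller's RNG stream is left untouched).
#' @return Numeric vector of length `nrow(data) * n_draws`, all feasible.
#' @export
simulate_from_fit <- function(params, data, spec, n_draws = 1L,
                              seed = NULL) {
  spec <- value_set(spec)
  if (inherits(params, "aldvmm")) params <- params$params
  if (n_draws < 1L) stop("'n_draws' must be at least 1")
  des <- params_design(params, data, need_outcome = FALSE)
  C <- params$n_components
  mu <- des$X %*% params$beta
  pmat <- membership_probabilities(des$Z, params$gamma)
  if (!is.matrix(pmat)) pmat <- matrix(pmat, nrow(mu), C)
  with_seed(seed, {
    as.vector(vapply(seq_len(n_draws), function(d)
      draw_outcomes(mu, params$sigma, pmat, spec), numeric(nrow(mu))))
  })
}

#' Information criteria of a converged fit
#'
#' `AIC = 2k - 2 loglik`, `BIC = k log(n) - 2 loglik` with `k` the number
#' of free parameters. Lower is better for both.
#'
#' @param fit a converged [aldvmm()] fit (or any object with `loglik`,
#'   `n_params` and `converged` fields).
#' @param n sample size (defaults to the fit's).
#' @return Named numeric vector `c(AIC =, BIC =)`.
#' @export
information_criteria <- function(fit, n = fit$nobs) {
  if (!isTRUE(fit$converged))
    stop("information criteria are only defined for a converged fit")
  k <- fit$n_params
  ll <- fit$loglik
  c(AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll)
}

#' @export
print.aldvmm <- function(x, digits = 4, ...) {
  cat("Adjusted limited dependent variable mixture model\n")
  cat("  instrument:", x$value_set$instrument,
      " components:", x$components, "\n")
  cat("  n =", x$nobs, " logLik =", format(x$loglik, digits = 7),
      " params =", x$n_params, "\n")
  cat("  converged:", x$converged,
      " (start:", x$start_strategy,
      ", restarts:", x$n_restarts_used, ")\n")
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
coef.aldvmm <- function(object, ...) object$coefficients

#' @export
vcov.aldvmm <- function(object, ...) object$vcov

#' @export
logLik.aldvmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.aldvmm <- function(object, ...) object$nobs

#' @export
fitted.aldvmm <- function(object, ...) object$fitted.values

#' @export
residuals.aldvmm <- function(object, ...) object$residuals

#' Predictions from a fitted ALDVMM
#'
#' @param object an [aldvmm()] fit.
#' @param newdata optional data frame; default reuses the estimation data.
#' @param type `"expected"` for the closed-form expected index value,
#'   `"membership"` for the n x C matrix of class probabilities,
#'   `"components"` for the n x C matrix of component mean linear
#'   predictors.
#' @param ... unused.
#' @return Vector or matrix according to `type`.
#' @export
predict.aldvmm <- function(object, newdata = NULL,
                           type = c("expected", "membership",
                                    "components"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    Z <- object$Z
  } else {
    des <- params_design(object$params, newdata, need_outcome = FALSE)
    X <- des$X
    Z <- des$Z
  }
  switch(type,
    expected = expected_values(object$params, X, Z, object$value_set),
    membership = {
      pm <- membership_probabilities(Z, object$params$gamma)
      if (!is.matrix(pm)) pm <- matrix(pm, nrow(X), object$components)
      pm
    },
    components = X %*% object$params$beta)
}

#' @export
simulate.aldvmm <- function(object, nsim = 1, seed = NULL, ...) {
  # stats convention: a data frame, one column per replicate, rows
  # matching the estimation data.
  C <- object$components
  mu <- object$X %*% object$params$beta
  pmat <- membership_probabilities(object$Z, object$params$gamma)
  if (!is.matrix(pmat)) pmat <- matrix(pmat, nrow(mu), C)
  out <- with_seed(seed, {
    as.data.frame(lapply(seq_len(nsim), function(d)
      draw_outcomes(mu, object$params$sigma, pmat, object$value_set)))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.aldvmm <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  ic <- if (object$converged) information_criteria(object) else
    c(AIC = NA_real_, BIC = NA_real_)
  structure(list(call = object$call, coefficients = tab,
                 loglik = object$loglik, n_params = object$n_params,
                 nobs = object$nobs, converged = object$converged,
                 start_strategy = object$start_strategy,
                 n_restarts_used = object$n_restarts_used,
                 instrument = object$value_set$instrument,
                 components = object$components, ic = ic),
            class = "summary.aldvmm")
}

#' @export
print.summary.aldvmm <- function(x, digits = 4, ...) {
  cat("Call:\n")
  print(x$call)
  cat(sprintf("\nALDVMM: %d components, instrument %s, n = %d\n",
              x$components, x$instrument, x$nobs))
  cat(sprintf("logLik %.4f on %d free parameters; AIC %.3f, BIC %.3f\n",
              x$loglik, x$n_params, x$ic["AIC"], x$ic["BIC"]))
  if (!x$converged)
    cat("** model did not converge; estimates are not reliable **\n")
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  invisible(x)
}

#' Diagnostic plots for a fitted ALDVMM
#'
#' `which = 1`: observed versus simulated index-value histograms (the
#' simulated panel uses draws from the fitted mixture, so ceiling mass,
#' skewness and the gap are visible). `which = 2`: observed and predicted
#' means with normal-approximation confidence intervals by decile of the
#' mapping covariate.
#'
#' @param x an [aldvmm()] fit.
#' @param which subset of `1:2`.
#' @param catprom5 optional covariate vector for the decile panel; default
#'   takes the first mean covariate from the model design.
#' @param n_draws simulated cohort replicates for the histogram panel.
#' @param seed seed for the simulated panel.
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.aldvmm <- function(x, which = 1:2, catprom5 = NULL, n_draws = 3L,
                        seed = 1L, ...) {
  if (1 %in% which) {
    sim <- as.vector(vapply(seq_len(n_draws), function(d)
      with_seed(seed + d, draw_outcomes(
        x$X %*% x$params$beta,
        x$params$sigma,
        predict(x, type = "membership"),
        x$value_set)), numeric(x$nobs)))
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old), add = TRUE)
    brk <- seq(x$value_set$floor, x$value_set$ceiling, length.out = 40)
    graphics::hist(x$y, breaks = brk, main = "Observed",
                   xlab = "index value", ...)
    graphics::hist(sim, breaks = brk, main = "Simulated from fit",
                   xlab = "index value", ...)
  }
  if (2 %in% which) {
    cp <- catprom5 %||% x$X[, setdiff(colnames(x$X), "(Intercept)")[1L]]
    cal <- decile_calibration(x$y, fitted(x), cp)
    plot_calibration(cal)
  }
  invisible(x)
}

#' Export fitted parameters and covariance matrix as spreadsheets
#'
#' Writes two CSV files: a long-format parameter table (component, term,
#' estimate, standard error) and the square covariance matrix of the free
#' parameters with matching labels, so a fitted mapping can be reused
#' without refitting.
#'
#' @param fit an [aldvmm()] fit.
#' @param params_file,vcov_file output CSV paths.
#' @return Invisibly, the parameter table.
#' @export
export_parameters <- function(fit, params_file, vcov_file) {
  nm <- names(fit$coefficients)
  part <- sub("\\..*$", "", nm)
  term <- sub("^[^.]*\\.", "", nm)
  tab <- data.frame(component = part, term = term,
                    estimate = unname(fit$coefficients),
                    std_error = sqrt(pmax(diag(fit$vcov), 0)))
  utils::write.csv(format_sig(tab), params_file, row.names = FALSE)
  vc <- as.data.frame(format_sig(as.data.frame(fit$vcov)))
  vc <- cbind(parameter = nm, vc)
  utils::write.csv(vc, vcov_file, row.names = FALSE)
  invisible(tab)
}

# 10-significant-digit formatting so exported numbers are stable across
# platforms.
format_sig <- function(df, digits = 10) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = digits, format = "g")
    else col)
  df
}
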