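# Specification grid, error metrics, model-selection rule and calibration
# diagnostics.

#' A single mixture model specification
#'
#' Records which covariates (beyond Cat-PROM5, which is always present)
#' enter the component means and the class-membership logits, and the
#' component count.
#'
#' @param components number of latent classes.
#' @param mean_covariates,membership_covariates character subsets of the
#'   covariate universe.
#' @param instrument target instrument id.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(components, mean_covariates = character(),
                       membership_covariates = character(),
                       instrument = "eq5d3l") {
  if (components < 1L) stop("'components' must be at least 1")
  structure(list(components = as.integer(components),
                 mean_covariates = as.character(mean_covariates),
                 membership_covariates = as.character(membership_covariates),
                 instrument = instrument),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %d components | mean: %s | membership: %s\n",
              x$components,
              paste(c("catprom5", x$mean_covariates), collapse = "+"),
              paste(c("catprom5", x$membership_covariates),
                    collapse = "+")))
  invisible(x)
}

spec_mean_formula <- function(ms)
  stats::reformulate(c("catprom5", ms$mean_covariates),
                     response = "outcome")

spec_membership_formula <- function(ms)
  stats::reformulate(c("catprom5", ms$membership_covariates))

spec_label <- function(ms)
  sprintf("C%d|mean:%s|memb:%s", ms$components,
          paste(c("catprom5", ms$mean_covariates), collapse = "+"),
          paste(c("catprom5", ms$membership_covariates), collapse = "+"))

all_subsets <- function(universe) {
  if (length(universe) == 0L) return(list(character()))
  unlist(lapply(0:length(universe), function(k)
    if (k == 0L) list(character())
    else utils::combn(universe, k, simplify = FALSE)), recursive = FALSE)
}

#' Build the covariate specification grid
#'
#' Cartesian product of all mean-covariate subsets, all
#' membership-covariate subsets and the requested component counts;
#' Cat-PROM5 is always present in both roles. The full universe
#' `{age, sex, diabetes}` with components `{2, 3}` yields
#' 8 x 8 x 2 = 128 specifications.
#'
#' @param components set of component counts (default `c(2, 3)`; one- and
#'   four-component models are allowed but off by default).
#' @param covariate_universe covariates to vary over.
#' @param instrument target instrument id.
#' @return List of [model_spec()] objects.
#' @export
build_specification_grid <- function(components = c(2L, 3L),
                                     covariate_universe = c("age", "sex",
                                                            "diabetes"),
                                     instrument = "eq5d3l") {
  if (length(components) == 0L) stop("invalid grid: empty component set")
  subsets <- all_subsets(covariate_universe)
  out <- list()
  for (C in sort(unique(as.integer(components))))
    for (m in subsets)
      for (g in subsets)
        out[[length(out) + 1L]] <-
          model_spec(C, m, g, instrument = instrument)
  out
}

#' Root-mean-square and mean-absolute prediction error
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @return Named vector `c(rmse =, mae =)`; `rmse >= mae` always.
#' @export
error_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' have different lengths")
  if (length(observed) == 0L) stop("empty input")
  d <- observed - predicted
  c(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Face validity of a fitted mapping
#'
#' A mapping is face-valid when predicted outcomes do not improve as the
#' disease-specific score worsens: mean predictions across Cat-PROM5
#' deciles must be non-increasing (equality allowed). Operationalises the
#' informal graphical sign check applied to candidate models.
#'
#' @param object a fitted [aldvmm()] or [fit_linear()] model.
#' @param cohort data frame with a `catprom5` column (and the model's
#'   covariates) on which predictions are evaluated.
#' @return `TRUE` or `FALSE`.
#' @export
face_validity <- function(object, cohort) {
  pred <- predict(object, newdata = cohort)
  g <- min(10L, nrow(cohort))
  bins <- stable_quantile_bins(cohort$catprom5, g)
  m <- vapply(seq_len(g), function(b) mean(pred[bins == b]), numeric(1))
  all(diff(m) <= 1e-8)
}

#' Select a model from a metrics table
#'
#' Implements the published rule: among converged, face-valid
#' specifications taken in ascending RMSE order, choose the first whose
#' AIC, BIC or MAE is strictly better (lower) than the median of that
#' criterion across all converged specifications. Medians are computed
#' over converged rows only; non-convergent rows never enter. If no row
#' passes the gate, the lowest-RMSE converged face-valid row is returned
#' with a warning (recorded in the `selection_note` attribute); ties are
#' broken by input order.
#'
#' @param rows data frame with columns `rmse`, `mae`, `aic`, `bic`,
#'   `converged`, `face_valid` (one row per specification).
#' @return The selected row (one-row data frame) with attributes
#'   `selected_index` and `selection_note` (`"gate_passed"` or a fallback
#'   note).
#' @export
select_model <- function(rows) {
  stopifnot(is.data.frame(rows))
  need <- c("rmse", "mae", "aic", "bic", "converged", "face_valid")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    stop("metrics table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  conv <- which(rows$converged)
  if (length(conv) == 0L)
    stop("selection impossible: no converged specification")
  med <- vapply(c("aic", "bic", "mae"),
                function(cr) stats::median(rows[[cr]][conv]), numeric(1))
  cand <- conv[rows$face_valid[conv]]
  note <- "gate_passed"
  pick <- NA_integer_
  if (length(cand)) {
    ordered <- cand[order(rows$rmse[cand])]   # stable: ties keep input order
    for (i in ordered) {
      if (rows$aic[i] < med["aic"] || rows$bic[i] < med["bic"] ||
          rows$mae[i] < med["mae"]) {
        pick <- i
        break
      }
    }
    if (is.na(pick)) {
      pick <- ordered[1L]
      note <- "gate_failed_lowest_rmse_fallback"
      warning("no specification beat the median on AIC, BIC or MAE; ",
              "returning the lowest-RMSE converged face-valid row")
    }
  } else {
    pick <- conv[order(rows$rmse[conv])][1L]
    note <- "no_face_valid_lowest_rmse_fallback"
    warning("no converged specification was face-valid; ",
            "returning the lowest-RMSE converged row")
  }
  out <- rows[pick, , drop = FALSE]
  attr(out, "selected_index") <- pick
  attr(out, "selection_note") <- note
  out
}

#' Observed versus predicted calibration by decile of the source score
#'
#' Bins subjects into Cat-PROM5 deciles (stable tie-breaking by row
#' order, so the bins partition the order statistics) and reports
#' per-decile means with normal-approximation confidence intervals for
#' both observed and predicted index values. Overlapping intervals across
#' deciles indicate a well-calibrated mapping.
#'
#' @param observed,predicted numeric vectors of equal length (>= 10).
#' @param catprom5 source-score vector defining the deciles.
#' @param confidence interval level (default 0.95).
#' @return A data frame of class `calibration_table`: one row per decile
#'   with `n`, `catprom5_mean`, observed/predicted means and interval
#'   bounds.
#' @export
decile_calibration <- function(observed, predicted, catprom5,
                               confidence = 0.95) {
  n <- length(observed)
  if (length(predicted) != n || length(catprom5) != n)
    stop("inputs have different lengths")
  if (n < 10L) stop("need at least 10 observations for decile calibration")
  bins <- stable_quantile_bins(catprom5, 10L)
  zq <- stats::qnorm(1 - (1 - confidence) / 2)
  ci <- function(v) {
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    c(m, m - zq * s, m + zq * s)
  }
  rows <- lapply(seq_len(10L), function(b) {
    o <- ci(observed[bins == b])
    p <- ci(predicted[bins == b])
    data.frame(decile = b, n = sum(bins == b),
               catprom5_mean = mean(catprom5[bins == b]),
               observed_mean = o[1], observed_lo = o[2], observed_hi = o[3],
               predicted_mean = p[1], predicted_lo = p[2],
               predicted_hi = p[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "confidence") <- confidence
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Plot a calibration table
#'
#' @param cal a [decile_calibration()] table.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `cal`.
#' @export
plot_calibration <- function(cal, ...) {
  rng <- range(cal$observed_lo, cal$observed_hi, cal$predicted_lo,
               cal$predicted_hi)
  graphics::plot(cal$decile - 0.1, cal$observed_mean, pch = 16,
                 ylim = rng, xlab = "Cat-PROM5 decile (best to worst)",
                 ylab = "index value",
                 main = "Observed vs predicted by decile", ...)
  graphics::arrows(cal$decile - 0.1, cal$observed_lo, cal$decile - 0.1,
                   cal$observed_hi, angle = 90, code = 3, length = 0.03)
  graphics::points(cal$decile + 0.1, cal$predicted_mean, pch = 17,
                   col = "red3")
  graphics::arrows(cal$decile + 0.1, cal$predicted_lo, cal$decile + 0.1,
                   cal$predicted_hi, angle = 90, code = 3, length = 0.03,
                   col = "red3")
  graphics::legend("bottomleft", pch = c(16, 17),
                   col = c("black", "red3"),
                   legend = c("observed", "predicted"), bty = "n")
  invisible(cal)
}

#' Distribution summary panel
#'
#' Mean, standard deviation, proportion exactly at the ceiling (perfect
#' health / full capability) and minimum -- the panel used to compare an
#' observed outcome vector with predicted or simulated values.
#'
#' @param values numeric vector of index values.
#' @param spec a [value_set()] or instrument id.
#' @return Named numeric vector `c(mean, sd, ceiling_prop, min)`;
#'   `ceiling_prop` is a proportion in \[0, 1\].
#' @export
summarize_distribution <- function(values, spec) {
  spec <- value_set(spec)
  if (length(values) == 0L) stop("empty input")
  c(mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    ceiling_prop = mean(values == spec$ceiling),
    min = min(values))
}
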