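#' Parameter set of an adjusted limited dependent variable mixture model
#'
#' Bundles, for a C-component mixture: per-component mean-regression
#' coefficients and scales, and the multinomial-logit coefficients that
#' govern latent class membership (last component is the reference class,
#' its logit coefficients fixed at zero).
#'
#' @param beta numeric matrix of mean coefficients, one column per
#'   component; rows are `(Intercept)` followed by `mean_terms`, in units
#'   of index value per covariate unit.
#' @param sigma positive numeric vector of component scales (index-value
#'   units), length C.
#' @param gamma numeric matrix of membership logit coefficients with C-1
#'   columns (component c versus the last component); rows are
#'   `(Intercept)` followed by `membership_terms`. `NULL` when C = 1.
#' @param mean_terms character vector naming the cohort columns entering
#'   the component means (besides the intercept), e.g.
#'   `c("catprom5", "age")`.
#' @param membership_terms character vector naming the columns entering
#'   class membership (besides the intercept).
#' @return An object of class `aldvmm_params`.
#' @examples
#' aldvmm_params(beta = cbind(c(0.9, -0.02), c(0.55, -0.035)),
#'               sigma = c(0.10, 0.22),
#'               gamma = cbind(c(0.4, -0.25)),
#'               mean_terms = "catprom5", membership_terms = "catprom5")
#' @export
aldvmm_params <- function(beta, sigma, gamma = NULL,
                          mean_terms = character(),
                          membership_terms = character()) {
  beta <- as.matrix(beta)
  C <- ncol(beta)
  if (C < 1L) stop("need at least one component")
  if (nrow(beta) != length(mean_terms) + 1L)
    stop("beta must have 1 + length(mean_terms) rows (intercept first)")
  if (length(sigma) != C) stop("sigma must have one entry per component")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("component scales must be strictly positive and finite")
  if (C == 1L) {
    if (!is.null(gamma) && length(gamma) > 0L)
      stop("gamma must be NULL for a one-component model")
    gamma <- NULL
  } else {
    if (is.null(gamma)) stop("gamma required for C > 1 components")
    gamma <- as.matrix(gamma)
    if (ncol(gamma) != C - 1L)
      stop("gamma must have C - 1 columns (last component is reference)")
    if (nrow(gamma) != length(membership_terms) + 1L)
      stop("gamma must have 1 + length(membership_terms) rows")
  }
  rownames(beta) <- c("(Intercept)", mean_terms)
  colnames(beta) <- paste0("comp", seq_len(C))
  if (!is.null(gamma)) {
    rownames(gamma) <- c("(Intercept)", membership_terms)
    colnames(gamma) <- paste0("comp", seq_len(C - 1L))
  }
  structure(list(beta = beta, sigma = unname(sigma), gamma = gamma,
                 mean_terms = mean_terms,
                 membership_terms = membership_terms,
                 n_components = C),
            class = "aldvmm_params")
}

#' @export
print.aldvmm_params <- function(x, digits = 4, ...) {
  cat(sprintf("ALDVMM parameters: %d component(s)\n", x$n_components))
  cat("Component means (beta):\n")
  print(round(x$beta, digits))
  cat("Scales (sigma):", paste(signif(x$sigma, digits), collapse = ", "),
      "\n")
  if (!is.null(x$gamma)) {
    cat("Membership logits (gamma, last component reference):\n")
    print(round(x$gamma, digits))
  }
  invisible(x)
}

n_free_params <- function(params) {
  C <- params$n_components
  nrow(params$beta) * C + C +
    if (C > 1L) nrow(params$gamma) * (C - 1L) else 0L
}

#' Latent class membership probabilities
#'
#' Multinomial-logit probabilities over mixture components: the linear
#' predictors `z %*% gamma` for components 1..C-1 are completed with a zero
#' for the reference (last) component and passed through a softmax.
#'
#' @param z numeric vector (one covariate row, intercept included) or a
#'   matrix with one row per subject.
#' @param gamma membership coefficient matrix with C-1 columns, or `NULL`
#'   for a one-component model.
#' @return A probability vector of length C (or an n x C matrix); rows are
#'   positive and sum to one.
#' @examples
#' membership_probabilities(c(1, 0.5), cbind(c(1, 2)))  # e^2/(e^2+1), rest
#' @export
membership_probabilities <- function(z, gamma) {
  if (is.null(gamma)) {
    n <- if (is.matrix(z)) nrow(z) else 1L
    p <- matrix(1, n, 1L)
    return(if (is.matrix(z)) p else drop(p))
  }
  gamma <- as.matrix(gamma)
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(zm) != nrow(gamma))
    stop("membership covariate row has ", ncol(zm),
         " entries but gamma has ", nrow(gamma), " rows")
  eta <- cbind(zm %*% gamma, 0)
  eta <- eta - apply(eta, 1L, max)   # guard against overflow
  w <- exp(eta)
  p <- w / rowSums(w)
  if (is.matrix(z)) p else drop(p)
}
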