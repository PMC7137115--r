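# Mixture-of-censored-normals likelihood.
#
# Each component is a normal on a latent index scale, observed through the
# value set: latent values strictly above the gap anchor (gap_lower) are
# recorded as the ceiling, values at or below the floor as the floor, and
# interior values as themselves. Observations therefore contribute a point
# mass at the ceiling, a point mass at the floor, or a density in
# (floor, gap_lower]. The open gap (gap_lower, ceiling) has probability
# zero by construction.

#' Censored-normal likelihood contribution of one component
#'
#' For a component with mean `mu = x . beta` and scale `sigma` under a
#' value set with floor L, gap anchor Psi and ceiling U:
#' an observation at the ceiling contributes the mass
#' `1 - pnorm((Psi - mu)/sigma)`, an observation at the floor the mass
#' `pnorm((L - mu)/sigma)`, and an interior observation the density
#' `dnorm(y, mu, sigma)`.
#'
#' @param y numeric vector of feasible index values.
#' @param x covariate row (intercept first), conformable with `beta`.
#' @param beta component mean coefficients.
#' @param sigma component scale, positive.
#' @param spec a [value_set()] (or instrument id).
#' @return Numeric vector of densities/masses, same length as `y`.
#' @export
component_likelihood <- function(y, x, beta, sigma, spec) {
  spec <- value_set(spec)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive scale")
  if (length(x) != length(beta))
    stop("covariate row and beta have different lengths")
  if (!all(is_feasible(y, spec)))
    stop("infeasible index value(s): ",
         paste(utils::head(y[!is_feasible(y, spec)], 3L), collapse = ", "))
  mu <- sum(x * beta)
  drop(censored_density(y, matrix(mu, length(y), 1L), sigma, spec))
}

# Region masks reused by likelihood, gradient and prediction code.
outcome_regions <- function(y, spec) {
  at_ceiling <- y == spec$ceiling
  at_floor <- !at_ceiling & y == spec$floor
  list(ceiling = at_ceiling, floor = at_floor,
       interior = !at_ceiling & !at_floor)
}

# n x C matrix of per-component densities/masses; mu is n x C.
censored_density <- function(y, mu, sigma, spec) {
  n <- length(y)
  C <- ncol(mu)
  reg <- outcome_regions(y, spec)
  g <- matrix(NA_real_, n, C)
  for (k in seq_len(C)) {
    s <- sigma[k]
    if (any(reg$ceiling))
      g[reg$ceiling, k] <- stats::pnorm(
        (spec$gap_lower - mu[reg$ceiling, k]) / s, lower.tail = FALSE)
    if (any(reg$floor))
      g[reg$floor, k] <- stats::pnorm((spec$floor - mu[reg$floor, k]) / s)
    if (any(reg$interior))
      g[reg$interior, k] <- stats::dnorm(y[reg$interior],
                                         mu[reg$interior, k], s)
  }
  g
}

# --- free-parameter vector <-> structured parameters ----------------------
# Packing order: beta columns (p per component), then log sigma (C), then
# gamma columns (q per non-reference component).

theta_length <- function(p, q, C) p * C + C + if (C > 1L) q * (C - 1L) else 0L

pack_theta <- function(params) {
  C <- params$n_components
  c(as.vector(params$beta), log(params$sigma),
    if (C > 1L) as.vector(params$gamma))
}

unpack_theta <- function(theta, p, q, C, mean_terms, membership_terms) {
  stopifnot(length(theta) == theta_length(p, q, C))
  beta <- matrix(theta[seq_len(p * C)], p, C)
  lsig <- theta[p * C + seq_len(C)]
  gamma <- if (C > 1L)
    matrix(theta[p * C + C + seq_len(q * (C - 1L))], q, C - 1L)
  aldvmm_params(beta, exp(lsig), gamma, mean_terms, membership_terms)
}

theta_names <- function(x_names, z_names, C) {
  nm <- as.vector(vapply(seq_len(C), function(k)
    paste0("comp", k, ".", x_names), character(length(x_names))))
  nm <- c(nm, paste0("comp", seq_len(C), ".lnsigma"))
  if (C > 1L)
    nm <- c(nm, as.vector(vapply(seq_len(C - 1L), function(k)
      paste0("memb", k, ".", z_names), character(length(z_names)))))
  nm
}

# Log-likelihood and analytic score in the free parameterization.
# Returns list(value, gradient (if grad), mix (n-vector of mixture
# likelihoods), posterior (n x C)).
aldvmm_objective <- function(theta, y, X, Z, spec, C, grad = TRUE) {
  p <- ncol(X)
  q <- ncol(Z)
  beta <- matrix(theta[seq_len(p * C)], p, C)
  lsig <- theta[p * C + seq_len(C)]
  sigma <- exp(lsig)
  gamma <- if (C > 1L)
    matrix(theta[p * C + C + seq_len(q * (C - 1L))], q, C - 1L)
  mu <- X %*% beta
  pmat <- membership_probabilities(Z, gamma)
  if (!is.matrix(pmat)) pmat <- matrix(pmat, nrow(X), C)
  g <- censored_density(y, mu, sigma, spec)
  mix <- rowSums(pmat * g)
  if (any(!is.finite(mix)) || any(mix <= 0)) {
    mix <- pmax(mix, 1e-300)
    if (any(!is.finite(mix)))
      return(list(value = -Inf, gradient = rep(0, length(theta))))
  }
  value <- sum(log(mix))
  if (!grad) return(list(value = value, mix = mix))
  w <- (pmat * g) / mix            # posterior class probabilities
  reg <- outcome_regions(y, spec)
  dmu <- matrix(0, length(y), C)   # d log g / d mu
  dls <- matrix(0, length(y), C)   # d log g / d log sigma
  for (k in seq_len(C)) {
    s <- sigma[k]
    if (any(reg$interior)) {
      r <- (y[reg$interior] - mu[reg$interior, k]) / s
      dmu[reg$interior, k] <- r / s
      dls[reg$interior, k] <- r * r - 1
    }
    if (any(reg$ceiling)) {
      d <- (spec$gap_lower - mu[reg$ceiling, k]) / s
      # inverse Mills ratio phi(d) / (1 - Phi(d)), computed on log scale
      imr <- exp(stats::dnorm(d, log = TRUE) -
                 stats::pnorm(d, lower.tail = FALSE, log.p = TRUE))
      dmu[reg$ceiling, k] <- imr / s
      dls[reg$ceiling, k] <- imr * d
    }
    if (any(reg$floor)) {
      a <- (spec$floor - mu[reg$floor, k]) / s
      imr <- exp(stats::dnorm(a, log = TRUE) -
                 stats::pnorm(a, log.p = TRUE))
      dmu[reg$floor, k] <- -imr / s
      dls[reg$floor, k] <- -imr * a
    }
  }
  gb <- vapply(seq_len(C), function(k) crossprod(X, w[, k] * dmu[, k])[, 1L],
               numeric(p))
  gs <- colSums(w * dls)
  gradient <- c(as.vector(gb), gs)
  if (C > 1L) {
    gg <- vapply(seq_len(C - 1L), function(k)
      crossprod(Z, w[, k] - pmat[, k])[, 1L], numeric(q))
    gradient <- c(gradient, as.vector(gg))
  }
  list(value = value, gradient = gradient, mix = mix, posterior = w)
}

#' Mixture log-likelihood of a parameter set on a cohort
#'
#' Evaluates the ALDVMM log-likelihood
#' `sum_i log sum_c p_c(z_i) g_c(y_i)` where `p_c` are the
#' multinomial-logit membership probabilities and `g_c` the censored-normal
#' component contributions of [component_likelihood()].
#'
#' @param params an [aldvmm_params()] object; its `mean_terms` and
#'   `membership_terms` name the columns of `data` that enter the design.
#' @param data cohort data frame with an `outcome` column and all term
#'   columns, complete cases only.
#' @param spec a [value_set()] or instrument id.
#' @return The log-likelihood (scalar).
#' @export
aldvmm_loglik <- function(params, data, spec) {
  spec <- value_set(spec)
  des <- params_design(params, data)
  if (!all(is_feasible(des$y, spec)))
    stop("cohort contains infeasible outcome values")
  aldvmm_objective(pack_theta(params), des$y, des$X, des$Z, spec,
                   params$n_components, grad = FALSE)$value
}

# Build (y, X, Z) design from a cohort and the terms a parameter set names.
params_design <- function(params, data, need_outcome = TRUE) {
  cols <- unique(c(params$mean_terms, params$membership_terms))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  y <- NULL
  if (need_outcome) {
    if (!"outcome" %in% names(data)) stop("cohort lacks an 'outcome' column")
    y <- data$outcome
    if (anyNA(y)) stop("cohort outcome contains missing values; apply ",
                       "complete_case_filter() first")
  }
  X <- matrix(c(rep(1, nrow(data)),
                unlist(lapply(params$mean_terms, function(v) data[[v]]))),
              nrow = nrow(data),
              dimnames = list(NULL, c("(Intercept)", params$mean_terms)))
  Z <- matrix(c(rep(1, nrow(data)),
                unlist(lapply(params$membership_terms,
                              function(v) data[[v]]))),
              nrow = nrow(data),
              dimnames = list(NULL, c("(Intercept)",
                                      params$membership_terms)))
  if (anyNA(X) || anyNA(Z))
    stop("cohort covariates contain missing values; apply ",
         "complete_case_filter() first")
  list(y = y, X = X, Z = Z)
}
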