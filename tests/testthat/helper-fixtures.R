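# Shared fixtures and independent oracles. Oracles are written as plain
# per-row loops so they share no code path with the package internals.

# Direct-summation mixture log-likelihood: explicit loops, manual softmax,
# if/else censoring.
oracle_loglik <- function(params, cohort, spec) {
  spec <- value_set(spec)
  C <- params$n_components
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    x <- c(1, vapply(params$mean_terms,
                     function(v) cohort[[v]][i], numeric(1)))
    z <- c(1, vapply(params$membership_terms,
                     function(v) cohort[[v]][i], numeric(1)))
    eta <- numeric(C)
    if (C > 1L)
      for (k in seq_len(C - 1L)) eta[k] <- sum(z * params$gamma[, k])
    pk <- exp(eta) / sum(exp(eta))
    y <- cohort$outcome[i]
    li <- 0
    for (k in seq_len(C)) {
      mu <- sum(x * params$beta[, k])
      s <- params$sigma[k]
      g <- if (y == spec$ceiling) {
        1 - pnorm((spec$gap_lower - mu) / s)
      } else if (y == spec$floor) {
        pnorm((spec$floor - mu) / s)
      } else {
        dnorm((y - mu) / s) / s
      }
      li <- li + pk[k] * g
    }
    total <- total + log(li)
  }
  total
}

# 5-row cohort with one ceiling, one floor and three interior outcomes.
fixture_cohort <- function() {
  data.frame(
    id = 1:5, timepoint = "baseline",
    catprom5 = c(-2.0, 0.5, 3.0, -4.0, 1.5),
    age = c(70, 75, 68, 80, 72),
    sex = c(1L, 0L, 1L, 0L, 1L),
    diabetes = c(0L, 0L, 1L, 0L, 1L),
    outcome = c(1.0, 0.62, 0.20, -0.594, 0.80))
}

fixture_params <- function(C) {
  switch(as.character(C),
    "1" = aldvmm_params(beta = cbind(c(0.5, -0.03)), sigma = 0.25,
                        mean_terms = "catprom5"),
    "2" = aldvmm_params(beta = cbind(c(0.88, -0.02), c(0.55, -0.035)),
                        sigma = c(0.10, 0.22),
                        gamma = cbind(c(0.4, -0.25)),
                        mean_terms = "catprom5",
                        membership_terms = "catprom5"),
    "3" = aldvmm_params(
      beta = cbind(c(0.95, -0.01), c(0.70, -0.02), c(0.30, -0.03)),
      sigma = c(0.05, 0.10, 0.20),
      gamma = cbind(c(1.0, -0.2), c(0.5, -0.1)),
      mean_terms = "catprom5",
      membership_terms = "catprom5"))
}

# Three-component truth with class membership driven by sex; used by the
# grid-selection recovery property.
threecomp_truth <- function() {
  aldvmm_params(
    beta = cbind(c(0.95, -0.010), c(0.70, -0.020), c(0.30, -0.030)),
    sigma = c(0.05, 0.08, 0.15),
    gamma = cbind(c(1.2, -0.20, -1.8), c(0.8, -0.10, 1.2)),
    mean_terms = "catprom5",
    membership_terms = c("catprom5", "sex"))
}

small_cohort <- function(n = 400, seed = 42, instrument = "eq5d3l") {
  simulate_cohort(cohort_scenario(n = n, seed = seed), instrument,
                  seed = seed)
}
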