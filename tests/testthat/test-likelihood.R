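test_that("membership probabilities are a softmax with reference last", {
  # symmetry: zero coefficients split mass equally
  expect_equal(membership_probabilities(c(1, 0), cbind(c(0, 0), c(0, 0))),
               rep(1 / 3, 3))
  # one component is degenerate
  expect_equal(membership_probabilities(c(1, 2.5), NULL), 1)
  # hand-evaluated softmax: eta = 1 + 2 * 0.5 = 2
  expect_equal(membership_probabilities(c(1, 0.5), cbind(c(1, 2)))[1],
               exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(membership_probabilities(c(1, 0.5), cbind(c(1, 2)))[1],
               0.8807970779778823, tolerance = 1e-12)
  # rows always sum to one, entries positive
  set.seed(1)
  Z <- cbind(1, matrix(rnorm(40), 20))
  G <- matrix(rnorm(9), 3)
  P <- membership_probabilities(Z, G)
  expect_equal(rowSums(P), rep(1, 20))
  expect_true(all(P > 0))
  expect_error(membership_probabilities(c(1, 2, 3), cbind(c(1, 2))),
               "entries but gamma")
})

test_that("component contributions split into ceiling mass, floor mass and density", {
  eq3 <- value_set("eq5d3l")
  # latent mean at the gap anchor: half the mass is censored to 1
  expect_equal(component_likelihood(1, c(1, 0), c(0.883, 0), 0.3, eq3),
               0.5)
  # interior density at its mode: phi(0)/sigma
  expect_equal(component_likelihood(0.5, c(1, 0), c(0.5, 0), 0.2, eq3),
               dnorm(0) / 0.2, tolerance = 1e-12)
  expect_equal(component_likelihood(0.5, c(1, 0), c(0.5, 0), 0.2, eq3),
               1.994711402007164, tolerance = 1e-9)
  expect_error(component_likelihood(0.95, c(1, 0), c(0.5, 0), 0.2, eq3),
               "infeasible")
  expect_error(component_likelihood(0.5, c(1, 0), c(0.5, 0), -0.1, eq3),
               "positive scale")
})

test_that("ceiling + floor + interior masses integrate to one", {
  for (id in c("eq5d3l", "eq5d5l", "icecapo")) {
    vs <- value_set(id)
    for (mu in c(-0.5, 0.2, 0.7, 1.1)) {
      for (s in c(0.05, 0.2, 0.5)) {
        ceiling_mass <- 1 - pnorm((vs$gap_lower - mu) / s)
        floor_mass <- pnorm((vs$floor - mu) / s)
        interior <- integrate(function(y) dnorm(y, mu, s), vs$floor,
                              vs$gap_lower, rel.tol = 1e-10)$value
        expect_equal(ceiling_mass + floor_mass + interior, 1,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("log-likelihood equals the direct-summation oracle", {
  coh <- fixture_cohort()
  for (C in 1:3) {
    pars <- fixture_params(C)
    expect_equal(aldvmm_loglik(pars, coh, "eq5d3l"),
                 oracle_loglik(pars, coh, "eq5d3l"), tolerance = 1e-10)
  }
  # frozen oracle value pins the two-component fixture
  expect_equal(aldvmm_loglik(fixture_params(2), coh, "eq5d3l"),
               -22.069607688707, tolerance = 1e-10)
})

test_that("a mixture of identical components collapses to one", {
  coh <- fixture_cohort()
  one <- fixture_params(1)
  two <- aldvmm_params(beta = cbind(one$beta[, 1], one$beta[, 1]),
                       sigma = rep(one$sigma, 2),
                       gamma = cbind(c(0.7, -0.3)),
                       mean_terms = "catprom5",
                       membership_terms = "catprom5")
  expect_equal(aldvmm_loglik(two, coh, "eq5d3l"),
               aldvmm_loglik(one, coh, "eq5d3l"), tolerance = 1e-12)
})

test_that("label switching leaves likelihood and predictions unchanged", {
  coh <- fixture_cohort()
  p3 <- fixture_params(3)
  # permute components (3, 1, 2); new reference is old component 2, so
  # gamma'_j = gamma_{pi(j)} - gamma_{pi(3)} with gamma_3 = 0
  perm <- c(3L, 1L, 2L)
  gfull <- cbind(p3$gamma, 0)
  gnew <- gfull[, perm[1:2], drop = FALSE] - gfull[, perm[3]]
  p3p <- aldvmm_params(beta = p3$beta[, perm], sigma = p3$sigma[perm],
                       gamma = gnew, mean_terms = "catprom5",
                       membership_terms = "catprom5")
  expect_equal(aldvmm_loglik(p3p, coh, "eq5d3l"),
               aldvmm_loglik(p3, coh, "eq5d3l"), tolerance = 1e-12)
  expect_equal(predict_expected_value(p3p, coh, "eq5d3l"),
               predict_expected_value(p3, coh, "eq5d3l"),
               tolerance = 1e-12)
})

test_that("analytic score matches central finite differences", {
  coh <- small_cohort(300, seed = 21)
  spec <- value_set("eq5d3l")
  pars <- fixture_params(2)
  des <- utilmap:::params_design(pars, coh)
  th <- utilmap:::pack_theta(pars) + 0.03
  obj <- utilmap:::aldvmm_objective(th, des$y, des$X, des$Z, spec, 2)
  num <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * (1 + abs(th[j]))
    up <- replace(th, j, th[j] + h)
    dn <- replace(th, j, th[j] - h)
    (utilmap:::aldvmm_objective(up, des$y, des$X, des$Z, spec, 2,
                                grad = FALSE)$value -
     utilmap:::aldvmm_objective(dn, des$y, des$X, des$Z, spec, 2,
                                grad = FALSE)$value) / (2 * h)
  }, numeric(1))
  expect_equal(obj$gradient, num, tolerance = 1e-5)
})

test_that("infeasible outcomes are rejected by the likelihood", {
  coh <- fixture_cohort()
  coh$outcome[2] <- 0.95   # inside the EQ-5D-3L gap
  expect_error(aldvmm_loglik(fixture_params(2), coh, "eq5d3l"),
               "infeasible")
})
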