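test_that("covariate generation is seeded, truncated and validated", {
  sc <- cohort_scenario(n = 500, seed = 9)
  a <- generate_covariates(sc)
  b <- generate_covariates(sc)
  expect_identical(a, b)
  expect_true(all(a$age >= 50))
  expect_true(all(a$catprom5 >= -9.18 & a$catprom5 <= 7.45))
  expect_true(all(is.na(a$outcome)))

  allf <- generate_covariates(cohort_scenario(n = 50, prop_female = 1))
  expect_true(all(allf$sex == 1L))

  expect_error(cohort_scenario(n = 0), "invalid scenario")
  expect_error(cohort_scenario(prop_female = 1.2), "invalid scenario")
  expect_error(cohort_scenario(catprom5_sd = -1), "invalid scenario")
  expect_error(generate_covariates(list(n = 5)), "cohort_scenario")
})

test_that("default scenarios reproduce the published cohort marginals", {
  # moderate n here; the large-n calibration check lives with the
  # acceptance properties
  coh <- generate_covariates(cohort_scenario(n = 20000, seed = 2))
  expect_equal(mean(coh$age), 73.8, tolerance = 0.005)
  expect_equal(sd(coh$age), 8.2, tolerance = 0.02)
  expect_equal(mean(coh$catprom5), -0.31, tolerance = 0.2)
  fu <- generate_covariates(cohort_scenario("followup", n = 20000,
                                            seed = 2))
  expect_equal(mean(fu$catprom5), -3.20, tolerance = 0.05)
  expect_equal(sd(fu$catprom5), 3.08, tolerance = 0.05)
})

test_that("scenarios round-trip through key-value config files", {
  tmp <- withr::local_tempfile(fileext = ".conf")
  writeLines(c("# follow-up scenario, small cohort",
               "timepoint = followup", "n = 250", "seed = 9",
               "prop_female = 0.6",
               "catprom5_min = -9.18", "catprom5_max = 4.98"), tmp)
  sc <- read_scenario(tmp)
  expect_identical(sc$timepoint, "followup")
  expect_identical(sc$n, 250L)
  expect_equal(sc$prop_female, 0.6)
  expect_equal(sc$catprom5_mean, -3.20)   # follow-up default retained
  expect_identical(generate_covariates(sc),
                   generate_covariates(cohort_scenario(
                     "followup", n = 250, prop_female = 0.6, seed = 9)))
  writeLines("catprom5_min = -2", tmp)
  expect_error(read_scenario(tmp), "both catprom5_min and catprom5_max")
})

test_that("outcome generation censors the latent normals to the value set", {
  # degenerate scale: every outcome equals the interior linear predictor
  pin <- aldvmm_params(beta = cbind(c(0.5, 0)), sigma = 1e-9,
                       mean_terms = "catprom5")
  coh <- generate_covariates(cohort_scenario(n = 200, seed = 5))
  out <- generate_outcomes(coh, pin, "eq5d3l", seed = 1)
  expect_equal(out$outcome, rep(0.5, 200))

  # linear predictor at the gap anchor: by symmetry half the latent mass
  # exceeds it, so about half the outcomes sit at the ceiling
  pgap <- aldvmm_params(beta = cbind(c(0.883, 0)), sigma = 0.1,
                        mean_terms = "catprom5")
  big <- generate_covariates(cohort_scenario(n = 40000, seed = 6))
  outg <- generate_outcomes(big, pgap, "eq5d3l", seed = 2)
  se <- sqrt(0.25 / 40000)
  expect_lt(abs(mean(outg$outcome == 1) - 0.5), 3 * se)
})

test_that("empirical ceiling mass matches the closed-form mixture probability", {
  tp <- fixture_params(2)
  spec <- value_set("eq5d3l")
  coh <- generate_covariates(cohort_scenario(n = 50000, seed = 7))
  out <- generate_outcomes(coh, tp, spec, seed = 3)
  # independent closed form: sum_c p_c (1 - Phi((Psi - mu_c)/sigma_c)),
  # averaged over subjects
  p_ceil <- vapply(seq_len(nrow(coh)), function(i) {
    z <- c(1, coh$catprom5[i])
    e1 <- exp(sum(z * tp$gamma[, 1]))
    pk <- c(e1, 1) / (e1 + 1)
    mu <- c(sum(c(1, coh$catprom5[i]) * tp$beta[, 1]),
            sum(c(1, coh$catprom5[i]) * tp$beta[, 2]))
    sum(pk * (1 - pnorm((spec$gap_lower - mu) / tp$sigma)))
  }, numeric(1))
  expected <- mean(p_ceil)
  mc_se <- sqrt(expected * (1 - expected) / nrow(coh))
  expect_lt(abs(mean(out$outcome == 1) - expected), 3 * mc_se)
})

test_that("generated outcomes are always feasible and negatively associated", {
  for (id in c("eq5d3l", "eq5d5l", "icecapo")) {
    vs <- value_set(id)
    for (s in 1:3) {
      coh <- simulate_cohort(cohort_scenario(n = 400, seed = s), id,
                             seed = s)
      expect_true(all(is_feasible(coh$outcome, vs)))
      if (vs$has_gap)
        expect_false(any(coh$outcome > vs$gap_lower &
                           coh$outcome < vs$ceiling))
      # negative Cat-PROM5 coefficient in all components: worse score,
      # worse outcome
      expect_lt(spearman_correlation(coh$catprom5, coh$outcome), 0)
    }
  }
  # default truths put ceiling mass in the published 15-40% band
  for (id in c("eq5d3l", "eq5d5l", "icecapo")) {
    coh <- simulate_cohort(cohort_scenario(n = 20000, seed = 11), id,
                           seed = 11)
    pc <- mean(coh$outcome == 1)
    expect_gt(pc, 0.15)
    expect_lt(pc, 0.40)
  }
})

test_that("complete-case filter removes exactly the incomplete rows", {
  toy <- data.frame(id = 1:5, catprom5 = c(1, NA, 3, 4, 5),
                    outcome = c(0.5, 0.6, NA, NA, 0.7))
  kept <- complete_case_filter(toy, c("catprom5", "outcome"))
  expect_identical(kept$id, c(1L, 5L))
  expect_identical(attr(kept, "n_removed"), 3L)

  full <- data.frame(a = 1:3, b = 4:6)
  ff <- complete_case_filter(full)
  expect_identical(ff$a, full$a)
  expect_identical(attr(ff, "n_removed"), 0L)
  # vacuous filter keeps everything, including NA rows
  expect_identical(nrow(complete_case_filter(toy, character())), 5L)
  expect_error(complete_case_filter(toy, "nope"), "unknown column")
})

test_that("spearman correlation uses midranks and validates input", {
  expect_identical(spearman_correlation(1:3, 3:1), -1)
  expect_identical(spearman_correlation(1:3, 1:3), 1)
  expect_error(spearman_correlation(1:3, 1:4), "different lengths")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  # tie-heavy fixture against a direct midrank-then-Pearson recomputation
  x <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 4, 6, 7, 7)
  expect_equal(spearman_correlation(x, y),
               cor(rank(x), rank(y)), tolerance = 1e-12)
})
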