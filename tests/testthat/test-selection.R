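test_that("the specification grid is the expected Cartesian product", {
  g <- build_specification_grid(c(2L, 3L), c("age", "sex", "diabetes"))
  expect_length(g, 128L)     # 8 x 8 x 2
  expect_length(build_specification_grid(2L, character()), 1L)
  expect_length(build_specification_grid(c(2L, 3L), "age"), 8L)
  expect_error(build_specification_grid(integer(), "age"),
               "empty component set")
  # Cat-PROM5 always present in both roles
  labs <- vapply(g, utilmap:::spec_label, "")
  expect_true(all(grepl("mean:catprom5", labs)))
  expect_true(all(grepl("memb:catprom5", labs)))
  expect_false(any(duplicated(labs)))
})

test_that("error metrics follow their definitions and rmse >= mae", {
  expect_equal(error_metrics(1:5, 1:5), c(rmse = 0, mae = 0))
  expect_equal(error_metrics(1:5, 1:5 + 0.3),
               c(rmse = 0.3, mae = 0.3))
  obs <- c(1, 0.8, 0.6, 0.4, 0.2, 0, -0.2, 1)
  pred <- c(0.9, 0.7, 0.7, 0.5, 0.1, 0.1, -0.1, 0.8)
  em <- error_metrics(obs, pred)
  expect_equal(em[["rmse"]], sqrt(0.01375), tolerance = 1e-12)
  expect_equal(em[["mae"]], 0.1125, tolerance = 1e-12)
  expect_error(error_metrics(1:3, 1:4), "different lengths")
  set.seed(2)
  for (r in 1:10) {
    o <- rnorm(50)
    p <- rnorm(50)
    m <- error_metrics(o, p)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
})

test_that("face validity is monotone non-increase across source deciles", {
  d <- data.frame(catprom5 = seq(-5, 5, length.out = 60))
  d$outcome <- 0.9 - 0.05 * d$catprom5   # worsening score, worse outcome
  expect_true(face_validity(fit_linear(d), d))
  d$outcome <- 0.2 + 0.05 * d$catprom5   # improves as score worsens
  expect_false(face_validity(fit_linear(d), d))
  dflat <- d
  set.seed(41)
  dflat$outcome <- 0.5 + rnorm(60, 0, 1e-12)  # flat counts as valid
  expect_true(face_validity(fit_linear(dflat), dflat))
})

test_that("the selection rule reproduces hand-enumerated choices", {
  # single converged candidate selects itself (its own metrics are the
  # medians, so the strict gate cannot pass and the fallback warns)
  one <- data.frame(spec = "a", rmse = 0.2, mae = 0.1, aic = 1, bic = 2,
                    converged = TRUE, face_valid = TRUE)
  expect_warning(sel0 <- select_model(one), "lowest-RMSE")
  expect_identical(sel0$spec, "a")

  # the lowest-RMSE row loses all side conditions; second lowest wins
  tab <- data.frame(
    spec = c("low_rmse_bad_rest", "runner_up", "mid"),
    rmse = c(0.10, 0.12, 0.20),
    mae = c(0.30, 0.10, 0.20),
    aic = c(300, 100, 200),
    bic = c(300, 100, 200),
    converged = TRUE, face_valid = TRUE)
  sel <- select_model(tab)
  expect_identical(sel$spec, "runner_up")
  expect_identical(attr(sel, "selection_note"), "gate_passed")

  # identical metrics: gate cannot be strictly beaten, fall back to the
  # first row by stable order with a warning
  same <- data.frame(spec = c("first", "second", "third"),
                     rmse = 0.2, mae = 0.1, aic = 5, bic = 6,
                     converged = TRUE, face_valid = TRUE)
  expect_warning(sel2 <- select_model(same), "lowest-RMSE")
  expect_identical(sel2$spec, "first")

  # non-convergent rows are excluded from medians and from selection
  mixed <- tab
  mixed$converged <- c(FALSE, TRUE, TRUE)
  sel3 <- select_model(mixed)
  expect_identical(sel3$spec, "runner_up")

  expect_error(select_model(data.frame(rmse = 1, mae = 1, aic = 1,
                                       bic = 1, converged = FALSE,
                                       face_valid = TRUE)),
               "no converged")
  expect_error(select_model(data.frame(rmse = 1)), "lacks column")
})

test_that("selection is invariant to row order up to tie-breaking", {
  set.seed(5)
  tab <- data.frame(spec = letters[1:12],
                    rmse = round(runif(12, 0.1, 0.3), 3),
                    mae = round(runif(12, 0.05, 0.2), 3),
                    aic = round(runif(12, -300, -100)),
                    bic = round(runif(12, -250, -50)),
                    converged = rep(c(TRUE, TRUE, FALSE), 4),
                    face_valid = rep(c(TRUE, FALSE), 6))
  base <- select_model(tab)$spec
  for (r in 1:5) {
    shuffled <- tab[sample(nrow(tab)), ]
    expect_identical(select_model(shuffled)$spec, base)
  }
})

test_that("decile calibration partitions subjects and nails exact fits", {
  set.seed(6)
  cp <- rnorm(100)
  y <- 0.8 - 0.04 * cp + rnorm(100, 0, 0.1)
  cal <- decile_calibration(y, y, cp)
  expect_identical(cal$n, rep(10L, 10))
  expect_equal(cal$observed_mean, cal$predicted_mean)
  expect_equal(cal$observed_lo, cal$predicted_lo)
  expect_error(decile_calibration(y[1:5], y[1:5], cp[1:5]),
               "at least 10")
  expect_error(decile_calibration(y, y[1:50], cp), "different lengths")
})

test_that("normal-approximation intervals agree with a bootstrap oracle", {
  set.seed(7)
  n <- 200
  cp <- rnorm(n)
  y <- 0.7 - 0.05 * cp + rnorm(n, 0, 0.2)
  cal <- decile_calibration(y, y, cp)
  bins <- utilmap:::stable_quantile_bins(cp, 10L)
  for (b in c(1L, 5L, 10L)) {
    v <- y[bins == b]
    boot <- replicate(4000, mean(sample(v, replace = TRUE)))
    analytic_se <- (cal$observed_hi[b] - cal$observed_mean[b]) /
      qnorm(0.975)
    expect_lt(abs(analytic_se - sd(boot)), 0.15 * sd(boot))
  }
})

test_that("distribution summaries report the Table-style panel", {
  eq3 <- value_set("eq5d3l")
  expect_equal(summarize_distribution(rep(1, 4), eq3),
               c(mean = 1, sd = 0, ceiling_prop = 1, min = 1))
  two <- summarize_distribution(c(0, 1), eq3)
  expect_equal(two[["mean"]], 0.5)
  expect_equal(two[["sd"]], sd(c(0, 1)))
  expect_equal(two[["ceiling_prop"]], 0.5)
  expect_equal(two[["min"]], 0)
  v <- c(1, 1, 0.7, 0.5, 0.3, -0.1, 0.883, 1, 0.62, 0.44)
  s <- summarize_distribution(v, eq3)
  expect_equal(s[["mean"]], mean(v))
  expect_equal(s[["ceiling_prop"]], 0.3)
  expect_equal(s[["min"]], -0.1)
  expect_error(summarize_distribution(numeric(0), eq3), "empty")
})

test_that("grid selection recovers a sex-driven three-component truth", {
  spec <- value_set("eq5d3l")
  truth <- threecomp_truth()
  hits <- 0L
  for (s in 1:20) {
    coh <- generate_covariates(cohort_scenario(n = 1000, seed = 700 + s))
    coh <- generate_outcomes(coh, truth, spec, seed = 800 + s)
    grid <- build_specification_grid(c(2L, 3L), "sex", "eq5d3l")
    gr <- utilmap:::run_grid(coh, grid, spec, aldvmm_control())
    sel <- suppressWarnings(select_model(gr$metrics))
    hits <- hits + (sel$components == 3L &&
                      grepl("sex", sel$membership_covariates))
  }
  expect_gt(hits, 10L)
})
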