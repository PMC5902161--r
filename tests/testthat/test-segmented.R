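test_that("noiseless piecewise data pin the change point", {
  obs <- piecewise_obs(psi = 30)
  fit <- suppressWarnings(fit_segmented(obs, segmented_options()))
  expect_lt(abs(fit$breakpoint_mb - 30), 0.25)

  # continuity of the fitted mean at the change point
  eps <- 1e-7
  left <- predict(fit, data.frame(consub_length_mb = fit$breakpoint_mb - eps))
  right <- predict(fit, data.frame(consub_length_mb = fit$breakpoint_mb + eps))
  expect_lt(abs(left - right), 1e-6)

  # the segments themselves
  expect_equal(unname(fit$slopes_below[[1]]), -0.005, tolerance = 1e-3)
  expect_equal(unname(fit$slopes_above[[1]]), 0, tolerance = 1e-3)

  # noiseless data: delta-method CI collapses around the truth
  ci <- breakpoint_ci(fit, segmented_options(ci_method = "delta"))
  expect_lt(ci[2] - ci[1], 0.5)
  expect_true(ci[1] < 30 && ci[2] > 30)
})

test_that("profile minimum matches a dense-grid oracle and is grid-optimal", {
  set.seed(8)
  ds <- generate_cross_dataset(generator_config(seed = 8))
  s2 <- ds$scores[ds$scores$cross == "2chr", ]
  fit <- suppressWarnings(fit_segmented(s2, segmented_options()))
  oracle <- dense_grid_psi(s2, step = 0.01)
  expect_lt(abs(fit$breakpoint_mb - oracle), 0.25 + 0.01)
  # global grid optimality of the returned breakpoint
  expect_true(all(fit$residual_ss <= fit$profile_rss + 1e-9))
})

test_that("per-chromosome fits stay continuous and bootstrap CI brackets the estimate", {
  ds <- generate_cross_dataset(generator_config(seed = 12))
  s2 <- ds$scores[ds$scores$cross == "2chr", ]
  opts <- segmented_options(per_chromosome_slopes = TRUE, n_boot = 100,
                            seed = 99)
  fit <- suppressWarnings(fit_segmented(s2, opts))
  eps <- 1e-7
  for (ch in names(fit$intercepts)) {
    left <- predict(fit, data.frame(consub_length_mb = fit$breakpoint_mb - eps,
                                    chrom = ch))
    right <- predict(fit, data.frame(consub_length_mb = fit$breakpoint_mb + eps,
                                     chrom = ch))
    expect_lt(abs(left - right), 1e-6)
  }
  ci <- breakpoint_ci(fit, opts)
  expect_lt(ci[1], fit$breakpoint_mb)
  expect_gt(ci[2], fit$breakpoint_mb)
})

test_that("slope-heterogeneity F test behaves at both extremes", {
  ds <- generate_cross_dataset(generator_config(seed = 21))
  s2 <- ds$scores[ds$scores$cross == "2chr", ]
  fit_g <- suppressWarnings(
    fit_segmented(s2, segmented_options(per_chromosome_slopes = TRUE)))
  fit_c <- suppressWarnings(
    fit_segmented(s2, segmented_options(per_chromosome_slopes = FALSE)))

  # generator slopes differ by chromosome, so heterogeneity should be seen
  het <- slope_equality_test(fit_g, fit_c)
  expect_lt(het$p_value, 0.01)

  # a model against itself carries no extra explanation
  self <- slope_equality_test(fit_c, fit_c)
  expect_equal(self$F_statistic, 0)
  expect_equal(self$p_value, 1)

  other <- generate_cross_dataset(generator_config(seed = 22))
  fit_other <- suppressWarnings(fit_segmented(
    other$scores[other$scores$cross == "2chr", ], segmented_options()))
  expect_error(slope_equality_test(fit_g, fit_other), "identical data")
})

test_that("rescue classification uses a strict 5% baseline", {
  expect_true(classify_synapsis_rescue(0.049))
  expect_false(classify_synapsis_rescue(0.05))
  expect_false(classify_synapsis_rescue(0.262))
  expect_equal(classify_synapsis_rescue(c(0.01, 0.3), baseline = 0.2),
               c(TRUE, FALSE))
  expect_error(classify_synapsis_rescue(1.2))
})

test_that("degenerate designs are rejected", {
  obs <- data.frame(male_id = letters[1:6], chrom = "1",
                    consub_length_mb = rep(10, 6),
                    n_scored = 100, n_asynapsed = 5)
  expect_error(fit_segmented(obs), "degenerate|distinct")
  expect_error(fit_segmented(piecewise_obs()[1:4, ]), "at least 6")
  expect_error(segmented_options(n_boot = 50), "at least 100")
})
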