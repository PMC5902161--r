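test_that("asynapsis rate table pools counts and carries LR intervals", {
  scores <- data.frame(
    male_id = c("a", "a", "b", "b"),
    chrom = c("1", "19", "1", "19"),
    n_scored = c(50, 40, 50, 60),
    n_asynapsed = c(1, 16, 2, 26))
  rt <- asynapsis_rate_table(scores)
  expect_equal(rt$pooled$rate[rt$pooled$chrom == "1"], 3 / 100)
  expect_equal(rt$pooled$rate[rt$pooled$chrom == "19"], 42 / 100)
  expect_true(all(rt$pooled$ci_low <= rt$pooled$rate))
  expect_true(all(rt$pooled$ci_high >= rt$pooled$rate))

  zero <- asynapsis_rate_table(data.frame(
    male_id = "a", chrom = "1", n_scored = 50, n_asynapsed = 0))
  expect_equal(zero$pooled$rate, 0)
  expect_equal(zero$pooled$ci_low, 0)
  expect_gt(zero$pooled$ci_high, 0)

  expect_error(asynapsis_rate_table(data.frame(
    male_id = "a", chrom = "1", n_scored = 10, n_asynapsed = 11)), "exceeds")
})

test_that("full-synapsis expectation is the product rule", {
  expect_equal(expected_full_synapsis(rep(1, 19)), 1)
  expect_equal(expected_full_synapsis(rep(0.9, 19)), 0.9^19)

  # permutation invariance and multiplicativity over disjoint sets
  set.seed(2)
  r <- runif(10, 0.5, 1)
  expect_identical(expected_full_synapsis(r), expected_full_synapsis(rev(r)))
  expect_equal(expected_full_synapsis(r),
               expected_full_synapsis(r[1:4]) * expected_full_synapsis(r[5:10]))
})

test_that("per-male expectation combines own rates with the F1 baseline", {
  baseline <- c("1" = 1, "2" = 1, "3" = 0.5)
  expect_equal(expected_full_synapsis_per_male(c("3" = 1), baseline[1:2],
                                               autosomes = c("1", "2", "3")),
               1)
  expect_equal(expected_full_synapsis_per_male(c("1" = 0.8, "2" = 0.9),
                                               c("3" = 0.5)),
               0.36)
  expect_error(expected_full_synapsis_per_male(
    c("1" = 0.8), c("2" = 0.9), autosomes = c("1", "2", "3")),
    "no baseline")
})

test_that("rescue prediction replaces rescued chromosomes by certainty", {
  rates <- c("1" = 0.9, "2" = 0.8, "3" = 0.7)
  expect_equal(predict_rescue_fraction(rates, names(rates)), 1)
  expect_equal(predict_rescue_fraction(rates, character()),
               expected_full_synapsis(rates))
  # monotone as the rescued set grows
  e0 <- predict_rescue_fraction(rates, character())
  e1 <- predict_rescue_fraction(rates, "3")
  e2 <- predict_rescue_fraction(rates, c("3", "2"))
  expect_true(e0 <= e1 && e1 <= e2)
  expect_error(predict_rescue_fraction(rates, "99"), "unknown")
})

test_that("trans-effect elasticity is detected with the expected sign", {
  ds <- generate_cross_dataset(generator_config(seed = 11))
  s4 <- ds$scores[ds$scores$cross == "4chr", ]
  te <- trans_effect_loglog(s4)
  expect_lt(te$loglog_slope, 0)
  expect_gt(te$pct_change_per_10pct, 0)
  # summary percentage is tied to the slope by the stated transform
  expect_equal(te$pct_change_per_10pct, 100 * (1 - 1.1^te$loglog_slope))
  expect_equal(nrow(te$per_chromosome), 4)
  expect_true(all(te$pct_ci[1] <= te$pct_change_per_10pct &
                    te$pct_change_per_10pct <= te$pct_ci[2]))

  expect_error(trans_effect_loglog(s4[s4$male_id == s4$male_id[1], ]),
               "usable males")
})

test_that("fertility summary bins counts into exhaustive percentages", {
  rec <- data.frame(male_id = sprintf("m%02d", 1:10),
                    sperm_million = c(rep(0, 5), 0.3, 0.6, 2, 5, 9))
  bins <- data.frame(lo = c(0, 0.01, 1), hi = c(0, 0.99, Inf))
  fs <- fertility_summary(rec, bins)
  expect_equal(fs$n, c(5, 2, 3))
  expect_equal(fs$pct, c(50, 20, 30))
  expect_equal(sum(fs$pct), 100)

  all_zero <- fertility_summary(data.frame(male_id = "a", sperm_million = 0),
                                bins)
  expect_equal(all_zero$pct, c(100, 0, 0))

  expect_error(fertility_summary(
    data.frame(male_id = "a", sperm_million = 0.995), bins), "no bin")
})

test_that("sperm presence separates by full-synapsis probability", {
  set.seed(14)
  p_all <- c(runif(9, 0.75, 0.95), runif(9, 0.2, 0.6))
  names(p_all) <- sprintf("m%02d", 1:18)
  rec <- data.frame(male_id = names(p_all),
                    sperm_million = ifelse(p_all > 0.7, runif(18, 1, 8), 0))
  res <- sperm_presence_vs_synapsis(rec, p_all)
  expect_false(res$degenerate)
  expect_lt(res$test$p_value, 0.01)
  expect_equal(unname(res$frac_above_threshold["sperm_positive"]), 1)

  rec_all <- data.frame(male_id = names(p_all), sperm_million = 1)
  degen <- sperm_presence_vs_synapsis(rec_all, p_all)
  expect_true(degen$degenerate)
  expect_null(degen$test)

  expect_error(sperm_presence_vs_synapsis(
    data.frame(male_id = "zz", sperm_million = 1), p_all), "no synapsis")
})
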