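test_that("fully consubspecific or p_sym = 1 chromosomes make every DSB symmetric", {
  k <- karyotype("1", 100, 1)
  # deterministic total of 4 DSBs on a single chromosome
  p <- dsb_sim_params(mean_total_dsb = 4, sd_total_dsb = 0, p_sym = 0,
                      n_sims = 2000, seed = 1)
  d <- simulate_symmetric_pmf(k, c("1" = 1), p)
  expect_equal(unname(d[["1"]]$pmf[["4"]]), 1)

  p1 <- dsb_sim_params(mean_total_dsb = 4, sd_total_dsb = 0, p_sym = 1,
                       n_sims = 2000, seed = 1)
  d1 <- simulate_symmetric_pmf(k, c("1" = 0.3), p1)
  expect_equal(unname(d1[["1"]]$pmf[["4"]]), 1)
})

test_that("Monte-Carlo P(0 symmetric) matches the binomial oracle", {
  k <- karyotype("1", 100, 1)
  p <- dsb_sim_params(mean_total_dsb = 4, sd_total_dsb = 0, p_sym = 0.28,
                      n_sims = 100000, seed = 7)
  d <- simulate_symmetric_pmf(k, NULL, p)
  expected <- (1 - 0.28)^4
  se <- sqrt(expected * (1 - expected) / p$n_sims)
  expect_lt(abs(prob_fewer_than_k(d[["1"]], 1) - expected), 3 * se)
})

test_that("closed form collapses binomial thinning exactly", {
  # per-DSB symmetric probability
  p <- dsb_sim_params()
  expect_equal(0 + (1 - 0) * p$p_sym, 0.28)
  expect_equal(0.5 + (1 - 0.5) * p$p_sym, 0.64)

  # sd = 0, mean 250, share 0.02: P(0) = (1 - 0.02 * 0.28)^250
  p0 <- dsb_sim_params(sd_total_dsb = 0)
  cs <- list(chrom = "1", spo11_share = 0.02)
  a <- closed_form_symmetric_pmf(cs, 0, p0)
  expect_equal(prob_fewer_than_k(a, 1), (1 - 0.02 * 0.28)^250,
               tolerance = 1e-12)

  # pmf is a proper distribution
  a2 <- closed_form_symmetric_pmf(list(chrom = "1", spo11_share = 0.05), 0.3,
                                  dsb_sim_params())
  expect_equal(sum(a2$pmf), 1, tolerance = 1e-9)
  expect_true(all(a2$pmf >= 0))
})

test_that("simulated pmfs agree with the analytic oracle on realistic karyotypes", {
  K <- generate_karyotype(19, seed = 5)
  p <- dsb_sim_params(n_sims = 30000, seed = 13)
  d <- simulate_symmetric_pmf(K, c("19" = 0.4), p)
  for (ch in c("1", "10", "19")) {
    fh <- if (ch == "19") 0.4 else 0
    a <- closed_form_symmetric_pmf(K[K$chrom == ch, ], fh, p)
    for (k in 1:5) {
      an <- prob_fewer_than_k(a, k)
      mc <- prob_fewer_than_k(d[[ch]], k)
      se <- sqrt(an * (1 - an) / p$n_sims)
      expect_lt(abs(mc - an), max(4 * se, 1e-12))
    }
  }
})

test_that("explicit DSB positions reproduce the collapsed membership model", {
  K <- generate_karyotype(4, seed = 2)
  cs <- K[K$chrom == "2", ]
  iv <- homozygous_intervals("2", 20, 20, 80, 80)
  rc <- recombinant_chromosome(cs, iv)
  p_exp <- dsb_sim_params(n_sims = 40000, seed = 3, explicit_positions = TRUE)
  d_exp <- simulate_symmetric_pmf(K, list(rc), p_exp)
  a <- closed_form_symmetric_pmf(cs, rc$f_homo, p_exp)
  for (k in c(1, 3, 5)) {
    an <- prob_fewer_than_k(a, k)
    se <- sqrt(an * (1 - an) / p_exp$n_sims)
    expect_lt(abs(prob_fewer_than_k(d_exp[["2"]], k) - an), 4 * se)
  }
})

test_that("symmetric counts are stochastically nondecreasing in f_homo", {
  cs <- list(chrom = "1", spo11_share = 0.04)
  p <- dsb_sim_params()
  prev <- NULL
  for (fh in c(0, 0.25, 0.5, 0.75, 1)) {
    a <- closed_form_symmetric_pmf(cs, fh, p)
    cdf <- cumsum(a$pmf)
    if (!is.null(prev)) expect_true(all(cdf <= prev + 1e-12))
    prev <- cdf
  }
})

test_that("with no consubspecific sequence the mean symmetric total is mean_dsb * p_sym", {
  K <- generate_karyotype(19, seed = 9)
  p <- dsb_sim_params(n_sims = 50000, seed = 17, k_max = 40)
  d <- simulate_symmetric_pmf(K, NULL, p)
  total <- sum(vapply(d, function(x) {
    k <- length(x$pmf) - 1L
    sum((0:k) * x$pmf)
  }, numeric(1)))
  expect_equal(total, 250 * 0.28, tolerance = 0.01)
})

test_that("prob_fewer_than_k is cumulative, monotone and range-checked", {
  d <- structure(list(chrom = "1",
                      pmf = c(`0` = 0.3, `1` = 0.7, tail = 0),
                      n_sims = 0L, mc_se = NULL), class = "dsb_pmf")
  expect_equal(prob_fewer_than_k(d, 1), 0.3)
  expect_equal(prob_fewer_than_k(d, 2), 1.0)
  expect_error(prob_fewer_than_k(d, 3), "exceeds")
  expect_error(prob_fewer_than_k(d, 0), "positive integer")

  a <- closed_form_symmetric_pmf(list(chrom = "1", spo11_share = 0.05), 0.2,
                                 dsb_sim_params())
  ps <- vapply(1:6, prob_fewer_than_k, numeric(1), dist = a)
  expect_true(all(diff(ps) >= 0))
})

test_that("simulation is reproducible given a seed and flags bad input", {
  K <- toy_karyotype()
  p <- dsb_sim_params(n_sims = 1000, seed = 5)
  d1 <- simulate_symmetric_pmf(K, NULL, p)
  d2 <- simulate_symmetric_pmf(K, NULL, p)
  expect_identical(d1[["1"]]$pmf, d2[["1"]]$pmf)
  expect_error(simulate_symmetric_pmf(K, c("99" = 0.5), p), "unknown chromosome")
  expect_error(dsb_sim_params(n_sims = 0), "n_sims")
})

test_that("proportional allocation is a working alternative to multinomial", {
  K <- toy_karyotype()
  p <- dsb_sim_params(n_sims = 20000, seed = 11, k_max = 120,
                      allocation = "proportional")
  d <- simulate_symmetric_pmf(K, NULL, p)
  # deterministic allocation: chromosome 1 always receives round(0.75 * T)
  # DSBs, so the mean symmetric count is 0.75 * 250 * 0.28
  mean_sym <- sum((0:120) * d[["1"]]$pmf[1:121])
  expect_equal(mean_sym, 0.75 * 250 * 0.28, tolerance = 0.02)
  expect_equal(sum(d[["1"]]$pmf), 1, tolerance = 1e-9)
})
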