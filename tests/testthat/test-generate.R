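test_that("generated karyotypes are deterministic, normalised and length-coupled", {
  k1 <- generate_karyotype(19, seed = 3)
  k2 <- generate_karyotype(19, seed = 3)
  expect_identical(k1, k2)
  expect_equal(sum(k1$spo11_share), 1, tolerance = 1e-12)
  expect_true(all(diff(k1$length_mb) < 0))

  rhos <- vapply(1:100, function(s) {
    k <- generate_karyotype(19, seed = s)
    suppressWarnings(spearman_correlation(k$length_mb, k$spo11_share)$rho)
  }, numeric(1))
  expect_gte(mean(rhos), 0.8)
})

test_that("cross datasets are bit-identical given (config, seed)", {
  d1 <- generate_cross_dataset(generator_config(seed = 6))
  d2 <- generate_cross_dataset(generator_config(seed = 6))
  expect_identical(d1$scores, d2$scores)
  expect_identical(d1$intervals, d2$intervals)
  expect_identical(d1$fertility, d2$fertility)
  d3 <- generate_cross_dataset(generator_config(seed = 7))
  expect_false(identical(d1$scores, d3$scores))
})

test_that("generated tables satisfy their structural invariants", {
  ds <- generate_cross_dataset(generator_config(seed = 15))
  s <- ds$scores
  expect_true(all(s$n_scored >= 20))
  expect_true(all(s$n_asynapsed >= 0 & s$n_asynapsed <= s$n_scored))
  expect_equal(s$n_complete + s$n_partial + s$n_intermingled, s$n_asynapsed)
  expect_true(all(s$consub_length_mb[s$cross == "F1"] == 0))
  expect_true(all(s$consub_length_min_mb <= s$consub_length_max_mb + 1e-9))

  iv <- ds$intervals
  expect_true(all(iv$start_min_mb <= iv$start_max_mb &
                    iv$start_max_mb <= iv$end_min_mb &
                    iv$end_min_mb <= iv$end_max_mb))
  # intervals parse through the interval constructor without error
  expect_silent(homozygous_intervals(iv$chrom, iv$start_min_mb,
                                     iv$start_max_mb, iv$end_min_mb,
                                     iv$end_max_mb))

  # 2-chr design: 61 males, two scored chromosomes each
  expect_equal(nrow(s[s$cross == "2chr", ]), 122)

  # sperm model: aspermic exactly below the synapsis-probability threshold
  truth_p <- unlist(ds$truth$p_all_synapsed)[ds$fertility$male_id]
  expect_equal(ds$fertility$sperm_million == 0,
               unname(truth_p < ds$config$tau))
})

test_that("a floor-only configuration yields rates at the baseline", {
  cfg <- generator_config(seed = 4, sigma_u = 0, gamma = 0, p_whole = 1,
                          p_none = 0, p_interstitial = 0)
  ds <- generate_cross_dataset(cfg)
  s2 <- ds$scores[ds$scores$cross != "F1", ]
  # every consomic chromosome is whole-length consubspecific: rate at floor
  pooled <- sum(s2$n_asynapsed) / sum(s2$n_scored)
  expect_lt(pooled, 0.05)
  expect_equal(pooled, cfg$asyn_floor, tolerance = 0.3)
})

test_that("the generator's latent parameters are recoverable", {
  # sigma_u from the F1 arm via a known-baseline offset model
  cfg <- generator_config(seed = 23)
  ds <- generate_cross_dataset(cfg)
  f1 <- ds$scores[ds$scores$cross == "F1", ]
  f1$base <- unlist(cfg$f1_max_asynapsis)[f1$chrom]
  fit <- fit_mixed_logit(
    cbind(n_asynapsed, n_scored - n_asynapsed) ~ 1 + offset(qlogis(base)),
    f1, group = "male_id")
  expect_lt(abs(fit$sigma_u - cfg$sigma_u), 0.3 * cfg$sigma_u)
  expect_lt(abs(coef(fit)[["(Intercept)"]]), 0.15)

  # trans-effect coupling gamma from the cross arms, truth-assisted design
  rates <- ds$truth$rates
  cross_rows <- ds$scores[ds$scores$cross != "F1", ]
  cross_rows$base <- rates$base_rate[match(
    paste(cross_rows$male_id, cross_rows$chrom),
    paste(rates$male_id, rates$chrom))]
  f1_max <- unlist(cfg$f1_max_asynapsis)
  delta <- vapply(seq_len(nrow(cross_rows)), function(i) {
    others <- cross_rows[cross_rows$male_id == cross_rows$male_id[i] &
                           cross_rows$chrom != cross_rows$chrom[i], ]
    mean(others$base) - mean(f1_max[others$chrom])
  }, numeric(1))
  cross_rows$delta <- delta
  gfit <- fit_mixed_logit(
    cbind(n_asynapsed, n_scored - n_asynapsed) ~ delta + offset(qlogis(base)),
    cross_rows, group = "male_id")
  expect_lt(abs(coef(gfit)[["delta"]] - cfg$gamma), 0.4 * cfg$gamma)
})

test_that("nonrecombinant chromosomes show reduced asynapsis odds in crosses", {
  # the trans effect lowers asynapsis of 0-Mb chromosomes in 2/4-chr males
  ds <- generate_cross_dataset(generator_config(seed = 30))
  s <- ds$scores
  nonrec <- s[s$consub_length_mb == 0, ]
  nonrec$is_cross <- nonrec$cross != "F1"
  shared <- intersect(unique(nonrec$chrom[nonrec$is_cross]),
                      unique(nonrec$chrom[!nonrec$is_cross]))
  sub <- nonrec[nonrec$chrom %in% shared, ]
  fit <- fit_mixed_logit(
    cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom + is_cross,
    sub, group = "male_id")
  expect_lt(fit$odds_ratios[["is_crossTRUE"]], 1)
})
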