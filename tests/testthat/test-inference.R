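test_that("quadrature log-likelihood matches dense numeric integration", {
  d <- tiny_glmm_data()
  f <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom
  fit <- fit_mixed_logit(f, d, group = "male_id")
  ll_gh <- mixed_logit_loglik(f, d, "male_id", coef(fit), fit$sigma_u)
  ll_or <- trapezoid_loglik(f, d, "male_id", coef(fit), fit$sigma_u)
  expect_lt(abs(ll_gh - ll_or), 1e-6)
  expect_equal(fit$loglik, ll_gh, tolerance = 1e-9)
})

test_that("more quadrature nodes move the log-likelihood toward the oracle", {
  d <- tiny_glmm_data()
  f <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom
  beta <- c(-0.7, 0.9); sigma <- 0.5
  ll_or <- trapezoid_loglik(f, d, "male_id", beta, sigma)
  errs <- vapply(c(1, 3, 9, 15), function(q)
    abs(mixed_logit_loglik(f, d, "male_id", beta, sigma, n_quad = q) - ll_or),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[length(errs)], 1e-8)
})

test_that("sigma fixed at zero collapses to ordinary logistic regression", {
  d <- tiny_glmm_data()
  f <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom
  collapsed <- fit_mixed_logit(f, d, "male_id", fix_sigma = 0)
  ref <- glm(f, binomial, d)
  expect_lt(max(abs(coef(collapsed) - coef(ref))), 1e-4)
  expect_lt(abs(collapsed$loglik - as.numeric(logLik(ref))), 1e-6)
})

test_that("free fit agrees with lme4 on the tiny fixture", {
  skip_if_not_installed("lme4")
  d <- tiny_glmm_data()
  fit <- fit_mixed_logit(cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom,
                         d, group = "male_id")
  g <- lme4::glmer(
    cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom + (1 | male_id),
    data = d, family = binomial, nAGQ = 15)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(g)), tolerance = 1e-3)
  expect_equal(fit$sigma_u, sqrt(unname(unlist(lme4::VarCorr(g)))),
               tolerance = 1e-3)
})

test_that("log-likelihood is invariant to animal relabelling", {
  d <- tiny_glmm_data()
  f <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom
  fit1 <- fit_mixed_logit(f, d, "male_id")
  d2 <- d
  d2$male_id <- c(a = "z", b = "q", c = "m")[d$male_id]
  fit2 <- fit_mixed_logit(f, d2, "male_id")
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-4)
})

test_that("likelihood-ratio comparison is calibrated and self-consistent", {
  d <- tiny_glmm_data()
  f1 <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ chrom
  fit <- fit_mixed_logit(f1, d, "male_id")
  self <- lrt_compare(fit, fit)
  expect_equal(self$p_value, 1)

  f0 <- cbind(n_asynapsed, n_scored - n_asynapsed) ~ 1
  fit0 <- fit_mixed_logit(f0, d, "male_id")
  cmp <- lrt_compare(fit0, fit)
  expect_gte(cmp$statistic, 0)
  expect_equal(cmp$df, 1)

  # null calibration: covariate unrelated to the response
  set.seed(31)
  pvals <- replicate(120, {
    n_animals <- 8
    dd <- data.frame(male_id = rep(seq_len(n_animals), each = 2),
                     x = rnorm(2 * n_animals), n_scored = 60)
    u <- rnorm(n_animals, 0, 0.4)
    dd$n_asynapsed <- rbinom(nrow(dd), dd$n_scored,
                             plogis(qlogis(0.2) + u[dd$male_id]))
    a <- fit_mixed_logit(cbind(n_asynapsed, n_scored - n_asynapsed) ~ x,
                         dd, "male_id")
    b <- fit_mixed_logit(cbind(n_asynapsed, n_scored - n_asynapsed) ~ 1,
                         dd, "male_id")
    lrt_compare(b, a)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("LR binomial intervals handle boundary counts and match a grid oracle", {
  ci0 <- lr_ci_binomial(0, 50)
  expect_equal(unname(ci0[1]), 0)
  expect_gt(ci0[2], 0)

  cin <- lr_ci_binomial(50, 50)
  expect_lt(cin[1], 1)
  expect_equal(unname(cin[2]), 1)

  ci <- lr_ci_binomial(5, 10)
  oracle <- grid_lr_ci(5, 10)
  expect_lt(max(abs(ci - oracle)), 1e-4)

  ci2 <- lr_ci_binomial(3, 80)
  oracle2 <- grid_lr_ci(3, 80)
  expect_lt(max(abs(ci2 - oracle2)), 1e-4)

  expect_error(lr_ci_binomial(5, 4))
})

test_that("Mann-Whitney test enumerates exactly and detects shifts", {
  r <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  same <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(5)
  reject <- mean(replicate(200, {
    a <- rnorm(30); b <- rnorm(30, 2)
    mann_whitney_test(a, b)$p_value < 0.05
  }))
  expect_gt(reject, 0.95)
  expect_error(mann_whitney_test(numeric(0), 1), "nonempty")
})
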