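# shared fixtures and independent oracles

# two-chromosome toy karyotype with unequal DSB allocation
toy_karyotype <- function() {
  karyotype(c("1", "2"), c(60, 40), c(3, 1))
}

# tiny mixed-logit fixture: 3 animals x 2 chromosomes, grouped counts
tiny_glmm_data <- function(seed = 42) {
  set.seed(seed)
  d <- data.frame(male_id = rep(c("a", "b", "c"), each = 2),
                  chrom = rep(c("18", "19"), 3),
                  n_scored = c(30, 28, 31, 25, 29, 33),
                  stringsAsFactors = FALSE)
  u <- stats::rnorm(3, 0, 0.6)
  eta <- stats::qlogis(0.25) + (d$chrom == "19") * 0.8 +
    u[as.integer(factor(d$male_id))]
  d$n_asynapsed <- stats::rbinom(6, d$n_scored, stats::plogis(eta))
  d
}

# brute-force marginal log-likelihood: trapezoid rule over the random effect
trapezoid_loglik <- function(formula, data, group, beta, sigma,
                             n_grid = 400001, width = 12) {
  mf <- stats::model.frame(formula, data)
  resp <- stats::model.response(mf)
  y <- resp[, 1]; m <- rowSums(resp)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (g in unique(data[[group]])) {
    i <- data[[group]] == g
    us <- seq(-width * sigma, width * sigma, length.out = n_grid)
    f <- vapply(us, function(u) {
      exp(sum(stats::dbinom(y[i], m[i], stats::plogis(eta0[i] + u),
                            log = TRUE)) +
            stats::dnorm(u, 0, sigma, log = TRUE))
    }, numeric(1))
    ll <- ll + log(sum((f[-1] + f[-length(f)]) / 2 * diff(us)))
  }
  ll
}

# dense-grid oracle for the LR binomial interval
grid_lr_ci <- function(x, n, level = 0.95, step = 1e-5) {
  ps <- seq(step, 1 - step, by = step)
  ll <- function(p) {
    out <- rep(0, length(p))
    if (x > 0) out <- out + x * log(p)
    if (x < n) out <- out + (n - x) * log1p(-p)
    out
  }
  phat <- min(max(x / n, 1e-12), 1 - 1e-12)
  ll_max <- if (x == 0 || x == n) 0 else ll(phat)
  keep <- ps[2 * (ll_max - ll(ps)) <= stats::qchisq(level, 1)]
  c(if (x == 0) 0 else min(keep), if (x == n) 1 else max(keep))
}

# noiseless piecewise-linear dataset with a kink at psi
piecewise_obs <- function(psi = 30, n = 61, xmax = 60) {
  x <- seq(0, xmax, length.out = n)
  y <- ifelse(x < psi, 20 - 0.5 * x, 20 - 0.5 * psi)
  # encode the exact rates as counts out of a large denominator
  data.frame(male_id = sprintf("m%02d", seq_len(n)), chrom = "5",
             consub_length_mb = x, n_scored = 1000,
             n_asynapsed = round(y / 100 * 1000))
}

# brute-force profile oracle: dense-grid RSS minimiser for the pooled
# single-slope segmented model
dense_grid_psi <- function(obs, step = 0.01, trim = 0.05) {
  x <- obs$consub_length_mb
  y <- obs$n_asynapsed / obs$n_scored
  w <- sqrt(obs$n_scored)
  qs <- stats::quantile(x, c(trim, 1 - trim), names = FALSE)
  grid <- seq(qs[1], qs[2], by = step)
  rss <- vapply(grid, function(p) {
    X <- cbind(1, x, pmax(x - p, 0))
    sum(stats::lm.fit(X * w, y * w)$residuals^2)
  }, numeric(1))
  grid[which.min(rss)]
}
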