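#' Gauss-Hermite nodes and weights
#'
#' Physicists' convention: `sum(w * f(z))` approximates
#' `integral exp(-z^2) f(z) dz`. Computed by the Golub-Welsch eigenvalue
#' method on the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# marginal log-likelihood of the random-intercept binomial-logit model,
# adaptive Gauss-Hermite quadrature over the per-animal intercept
.ml_loglik <- function(beta, sigma, X, y, m, animal, gh, offset = 0) {
  eta0 <- drop(X %*% beta) + offset
  # stable grouped-binomial log-likelihood: log p = -log(1 + exp(-eta))
  binom_ll <- function(eta, yy, mm) {
    sum(yy * stats::plogis(eta, log.p = TRUE) +
          (mm - yy) * stats::plogis(-eta, log.p = TRUE))
  }
  if (sigma <= 0) {
    return(as.numeric(binom_ll(eta0, y, m)))
  }
  ll <- 0
  for (lev in levels(animal)) {
    idx <- which(animal == lev)
    e0 <- eta0[idx]; yi <- y[idx]; mi <- m[idx]
    h <- function(u) {
      binom_ll(e0 + u, yi, mi) + stats::dnorm(u, 0, sigma, log = TRUE)
    }
    # Newton search for the mode of the (concave) integrand
    u <- 0
    for (it in 1:50) {
      p <- stats::plogis(e0 + u)
      g1 <- sum(yi - mi * p) - u / sigma^2
      g2 <- -sum(mi * p * (1 - p)) - 1 / sigma^2
      step <- g1 / g2
      u <- u - step
      if (abs(step) < 1e-10) break
    }
    s <- 1 / sqrt(sum(mi * stats::plogis(e0 + u) *
                        (1 - stats::plogis(e0 + u))) + 1 / sigma^2)
    zu <- u + sqrt(2) * s * gh$nodes
    hv <- vapply(zu, h, numeric(1))
    hmax <- max(hv + gh$nodes^2)
    ll <- ll + log(sum(gh$weights * exp(hv + gh$nodes^2 - hmax))) + hmax +
      log(sqrt(2) * s)
  }
  as.numeric(ll)
}

#' Random-intercept logistic model of asynapsis counts
#'
#' Maximum-likelihood fit of a binomial GLMM with logit link, fixed effects
#' given by `formula`, and a normal random intercept for each animal. The
#' marginal likelihood is a one-dimensional integral per animal, evaluated by
#' adaptive Gauss-Hermite quadrature (`n_quad = 1` gives the Laplace
#' approximation). Grouped counts (`n_asynapsed` of `n_scored`) are equivalent
#' to per-pachynema binary coding but far cheaper.
#'
#' @param formula model formula with a two-column response, e.g.
#'   `cbind(n_asynapsed, n_scored - n_asynapsed) ~ cross`.
#' @param data data frame of per-animal, per-chromosome counts and covariates.
#' @param group name of the animal identifier column.
#' @param n_quad number of quadrature nodes (default 15).
#' @param start optional starting values for the fixed effects.
#' @param fix_sigma optionally hold the random-intercept standard deviation
#'   fixed (e.g. `fix_sigma = 0` collapses the model to ordinary logistic
#'   regression) instead of estimating it.
#' @return object of class `"mixed_logit"` with fixed-effect `coefficients`
#'   (log-odds scale), `odds_ratios`, the random-intercept standard deviation
#'   `sigma_u`, `loglik`, and convergence/separation flags.
#' @export
fit_mixed_logit <- function(formula, data, group, n_quad = 15, start = NULL,
                            fix_sigma = NULL) {
  mf <- stats::model.frame(formula, data)
  resp <- stats::model.response(mf)
  if (is.null(dim(resp)) || ncol(resp) != 2) {
    stop("response must be a two-column matrix: cbind(successes, failures)")
  }
  y <- resp[, 1]; m <- rowSums(resp)
  if (any(y < 0) || any(y > m)) stop("successes must lie in [0, trials]")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  animal <- factor(data[[group]])
  if (nlevels(animal) < 2) stop("need at least 2 animals")
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- 0
  gh <- gauss_hermite(n_quad)
  const <- sum(lchoose(m, y))
  p <- ncol(X)
  if (is.null(start)) {
    start <- stats::coef(stats::glm.fit(X, cbind(y, m - y), offset = off,
                                        family = stats::binomial()))
  }
  if (is.null(fix_sigma)) {
    negll <- function(par) {
      v <- -.ml_loglik(par[seq_len(p)], par[p + 1], X, y, m, animal, gh, off)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::optim(c(unname(start), 0.5), negll, method = "L-BFGS-B",
                        lower = c(rep(-Inf, p), 0),
                        control = list(maxit = 500))
    beta <- opt$par[seq_len(p)]
    sigma_u <- unname(opt$par[p + 1])
    vc <- tryCatch({
      H <- stats::optimHess(opt$par, negll)
      V <- solve(H)
      dimnames(V) <- list(c(colnames(X), "sigma_u"),
                          c(colnames(X), "sigma_u"))
      V
    }, error = function(e) NULL)
  } else {
    stopifnot(fix_sigma >= 0)
    negll <- function(par) {
      v <- -.ml_loglik(par, fix_sigma, X, y, m, animal, gh, off)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::optim(unname(start), negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    beta <- opt$par
    sigma_u <- fix_sigma
    vc <- tryCatch({
      H <- stats::optimHess(opt$par, negll)
      V <- solve(H)
      dimnames(V) <- list(colnames(X), colnames(X))
      V
    }, error = function(e) NULL)
  }
  names(beta) <- colnames(X)
  separation <- any(abs(beta) > 12)
  if (separation) {
    warning("possible separation: some coefficients are extreme")
  }
  structure(list(coefficients = beta,
                 odds_ratios = exp(beta),
                 sigma_u = sigma_u,
                 loglik = unname(-opt$value + const),
                 converged = opt$convergence == 0,
                 separation = separation,
                 n_quad = n_quad,
                 vcov = vc,
                 n_obs = length(y),
                 n_animals = nlevels(animal),
                 n_trials = sum(m),
                 n_successes = sum(y),
                 formula = formula,
                 group = group,
                 call = match.call()),
            class = "mixed_logit")
}

#' Evaluate the marginal log-likelihood at given parameters
#'
#' Exposed so the quadrature can be validated against independent numerical
#' integration; includes the binomial normalising constants.
#'
#' @inheritParams fit_mixed_logit
#' @param beta fixed-effect vector (order of `model.matrix(formula, data)`).
#' @param sigma_u random-intercept standard deviation (>= 0).
#' @return log-likelihood value.
#' @export
mixed_logit_loglik <- function(formula, data, group, beta, sigma_u,
                               n_quad = 15) {
  mf <- stats::model.frame(formula, data)
  resp <- stats::model.response(mf)
  y <- resp[, 1]; m <- rowSums(resp)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  animal <- factor(data[[group]])
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- 0
  gh <- gauss_hermite(n_quad)
  .ml_loglik(beta, sigma_u, X, y, m, animal, gh, off) + sum(lchoose(m, y))
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat("Random-intercept logistic model (adaptive Gauss-Hermite, ",
      x$n_quad, " nodes)\n", sep = "")
  cat(sprintf("  %d observations, %d animals, logLik %.4f%s\n",
              x$n_obs, x$n_animals, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$coefficients,
                    odds_ratio = x$odds_ratios)
  print(tab, digits = 4)
  cat(sprintf("  animal intercept sd (sigma_u): %.4f\n", x$sigma_u))
  invisible(x)
}

#' @export
summary.mixed_logit <- function(object, ...) {
  print(object)
  if (!is.null(object$vcov)) {
    se <- sqrt(diag(object$vcov))[seq_along(object$coefficients)]
    z <- object$coefficients / se
    tab <- data.frame(estimate = object$coefficients, se = se, z = z,
                      p_value = 2 * stats::pnorm(-abs(z)))
    cat("Wald tests:\n")
    print(tab, digits = 4)
  }
  invisible(object)
}

#' @export
coef.mixed_logit <- function(object, ...) object$coefficients

#' @export
logLik.mixed_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.mixed_logit <- function(object, ...) object$vcov

#' Likelihood-ratio test between nested mixed-logit fits
#'
#' @param fit_null,fit_alt `"mixed_logit"` fits of nested fixed-effect designs
#'   on identical data.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_compare <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "mixed_logit"), inherits(fit_alt, "mixed_logit"))
  if (fit_null$n_obs != fit_alt$n_obs ||
      fit_null$n_trials != fit_alt$n_trials ||
      fit_null$n_successes != fit_alt$n_successes) {
    stop("fits are not on identical data")
  }
  df <- length(fit_alt$coefficients) - length(fit_null$coefficients)
  if (df < 0) stop("models are not nested: null model has more parameters")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Likelihood-ratio confidence interval for a binomial proportion
#'
#' Inverts the likelihood-ratio test: the interval is the set of `p` whose
#' deviance against the maximum-likelihood estimate does not exceed the
#' chi-square quantile. Unlike Wald intervals it remains informative at
#' observed rates of exactly zero (lower bound 0, positive upper bound) or one.
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level.
#' @return numeric `c(low, high)`.
#' @export
lr_ci_binomial <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  cut <- stats::qchisq(level, 1) / 2
  ll <- function(p) {
    out <- 0
    if (x > 0) out <- out + x * log(p)
    if (x < n) out <- out + (n - x) * log1p(-p)
    out
  }
  phat <- x / n
  ll_max <- ll(min(max(phat, 1e-12), 1 - 1e-12))
  if (x == 0) ll_max <- 0
  if (x == n) ll_max <- 0
  f <- function(p) ll_max - ll(p) - cut
  eps <- 1e-12
  low <- if (x == 0) 0 else stats::uniroot(f, c(eps, phat), tol = 1e-10)$root
  high <- if (x == n) 1 else stats::uniroot(f, c(phat, 1 - eps), tol = 1e-10)$root
  c(low = low, high = high)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided; exact enumeration when the smaller sample has at most 8
#' observations and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  exact <- min(length(a), length(b)) <= 8 && !any(duplicated(c(a, b)))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(res$statistic), p_value = min(1, res$p.value),
       method = if (exact) "exact" else "normal approximation")
}
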