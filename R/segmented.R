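#' Options for the segmented (change-point) fit
#'
#' @param weighting `"n_scored"` (default) weights each per-male,
#'   per-chromosome proportion by the number of pachynemas scored, reflecting
#'   binomial heteroscedasticity; `"none"` gives equal weights.
#' @param grid_step_mb spacing of the breakpoint profile grid, Mb.
#' @param ci_method `"bootstrap"` (resampling animals) or `"delta"`
#'   (gap-variable standard error).
#' @param boot_interval bootstrap interval flavor: `"normal"` (default;
#'   symmetric, estimate plus/minus z times the bootstrap standard error) or
#'   `"percentile"`. The breakpoint estimate carries a small downward bias
#'   under realistic per-animal noise, which the percentile interval inherits
#'   twice over; the symmetric interval centres on the estimate and covers
#'   better.
#' @param n_boot bootstrap replicates (>= 100 when `ci_method = "bootstrap"`).
#' @param boot_grid_step_mb coarser profile grid used inside bootstrap refits.
#' @param seed optional seed for the bootstrap.
#' @param per_chromosome_slopes if `TRUE`, each chromosome gets its own
#'   intercept, below-breakpoint slope and slope change at the breakpoint;
#'   only the breakpoint itself is common.
#' @param trim outer fraction of predictor values excluded from the admissible
#'   breakpoint range (keeps both segments identifiable).
#' @return list of class `"segmented_options"`.
#' @export
segmented_options <- function(weighting = c("n_scored", "none"),
                              grid_step_mb = 0.25,
                              ci_method = c("bootstrap", "delta"),
                              boot_interval = c("normal", "percentile"),
                              n_boot = 200L,
                              boot_grid_step_mb = 1,
                              seed = NULL,
                              per_chromosome_slopes = FALSE,
                              trim = 0.05) {
  weighting <- match.arg(weighting)
  ci_method <- match.arg(ci_method)
  boot_interval <- match.arg(boot_interval)
  stopifnot(grid_step_mb > 0, trim >= 0, trim < 0.5)
  if (ci_method == "bootstrap" && n_boot < 100) {
    stop("n_boot must be at least 100 for bootstrap confidence intervals")
  }
  structure(list(weighting = weighting, grid_step_mb = grid_step_mb,
                 ci_method = ci_method, boot_interval = boot_interval,
                 n_boot = as.integer(n_boot),
                 boot_grid_step_mb = boot_grid_step_mb, seed = seed,
                 per_chromosome_slopes = per_chromosome_slopes, trim = trim),
            class = "segmented_options")
}

# accept either consub_length_mb or (min, max) marker bounds
.seg_prepare <- function(obs) {
  if (!"consub_length_mb" %in% names(obs)) {
    if (all(c("consub_length_min_mb", "consub_length_max_mb") %in% names(obs))) {
      obs$consub_length_mb <-
        (obs$consub_length_min_mb + obs$consub_length_max_mb) / 2
    } else {
      stop("need consub_length_mb or consub_length_min/max_mb columns")
    }
  }
  need <- c("consub_length_mb", "n_scored", "n_asynapsed")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(obs$n_scored < 1)) stop("n_scored must be >= 1")
  if (any(obs$n_asynapsed < 0 | obs$n_asynapsed > obs$n_scored)) {
    stop("n_asynapsed must lie in [0, n_scored]")
  }
  obs$rate <- obs$n_asynapsed / obs$n_scored
  obs
}

# design-matrix builder: per-group intercepts, below-breakpoint slopes and
# hinge (x - psi)+ terms; the hinge coefficient (slope change at psi) is also
# group-specific so that each chromosome's second segment is free. The group
# blocks are precomputed once; only the hinge columns depend on psi.
.seg_designer <- function(x, group) {
  n <- length(x)
  if (is.null(group)) {
    base <- cbind(`(Intercept)` = rep(1, n), x = x)
    hinge_names <- "hinge"
    gi <- rep(1L, n)
    G <- matrix(1, n, 1)
  } else {
    g <- factor(group)
    gi <- as.integer(g)
    G <- matrix(0, n, nlevels(g))
    G[cbind(seq_len(n), gi)] <- 1
    base <- cbind(G, G * x)
    colnames(base) <- c(levels(g), paste0(levels(g), ":x"))
    hinge_names <- paste0(levels(g), ":hinge")
  }
  list(
    design = function(psi) {
      H <- G * pmax(x - psi, 0)
      colnames(H) <- hinge_names
      cbind(base, H)
    },
    hinge_names = hinge_names,
    group_index = gi
  )
}

.seg_design <- function(x, group, psi) .seg_designer(x, group)$design(psi)

# profile grid search followed by iterative linearization on the gap
# variable: at the current psi the design is augmented with
# gap = -I(x > psi) * b2(group); the gap coefficient estimates the shift
# psi_new - psi and vanishes at the optimum
.seg_profile <- function(x, y, sw, group, grid) {
  dsg <- .seg_designer(x, group)
  yw <- y * sw
  rss_at <- function(p) {
    sum(stats::lm.fit(dsg$design(p) * sw, yw)$residuals^2)
  }
  rss <- vapply(grid, rss_at, numeric(1))
  psi0 <- grid[which.min(rss)]
  lo <- min(grid); hi <- max(grid)
  psi <- psi0
  converged <- FALSE
  for (it in 1:100) {
    X0 <- dsg$design(psi)
    cf <- stats::lm.fit(X0 * sw, yw)$coefficients
    b2row <- unname(cf[dsg$hinge_names])[dsg$group_index]
    if (anyNA(b2row) || all(abs(b2row) < 1e-12)) break
    X <- cbind(X0, gap = -as.numeric(x > psi) * b2row)
    gamma <- stats::lm.fit(X * sw, yw)$coefficients["gap"]
    if (is.na(gamma) || !is.finite(gamma)) break
    psi_new <- psi + unname(gamma)
    if (psi_new < lo || psi_new > hi) break
    if (abs(psi_new - psi) < 1e-8) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
  }
  if (!converged || rss_at(psi) > min(rss)) {
    psi <- psi0
    converged <- FALSE
  }
  list(psi = psi, grid = grid, profile_rss = rss, converged = converged)
}

.seg_solve <- function(x, y, sw, group, psi) {
  X <- .seg_design(x, group, psi)
  fit <- stats::lm.fit(X * sw, y * sw)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2), X = X,
       fitted = drop(X %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients)))
}

#' Fit a two-part continuous (segmented) regression of asynapsis rate
#'
#' Models the per-male, per-chromosome asynapsis proportion as a continuous
#' piecewise-linear function of consubspecific interval length: one slope below
#' the change point `psi`, another above, joined continuously through the hinge
#' basis `(x - psi)+` (per chromosome when `per_chromosome_slopes`, sharing
#' only `psi`). `psi` is estimated by a profile grid search over the
#' admissible predictor range, refined by iterative linearization on the gap
#' variable; a non-convergent refinement falls back to the best grid point
#' with a warning.
#'
#' @param obs data frame with columns `consub_length_mb` (or
#'   `consub_length_min_mb`/`consub_length_max_mb`), `n_scored`, `n_asynapsed`,
#'   and optionally `male_id`, `chrom`.
#' @param options a [segmented_options()].
#' @return object of class `"segfit"`.
#' @export
fit_segmented <- function(obs, options = segmented_options()) {
  obs <- .seg_prepare(obs)
  x <- obs$consub_length_mb
  y <- obs$rate
  if (nrow(obs) < 6) stop("need at least 6 observations")
  if (length(unique(x)) < 3) stop("degenerate design: too few distinct lengths")
  w <- if (options$weighting == "n_scored") obs$n_scored else rep(1, nrow(obs))
  sw <- sqrt(w)
  group <- if (options$per_chromosome_slopes && "chrom" %in% names(obs) &&
               length(unique(obs$chrom)) > 1) obs$chrom else NULL
  qs <- stats::quantile(x, c(options$trim, 1 - options$trim), names = FALSE)
  if (diff(qs) <= options$grid_step_mb) {
    stop("degenerate design: admissible breakpoint range is empty")
  }
  grid <- seq(qs[1], qs[2], by = options$grid_step_mb)
  prof <- .seg_profile(x, y, sw, group, grid)
  if (!prof$converged) {
    warning("breakpoint refinement did not converge; using best grid point")
  }
  sol <- .seg_solve(x, y, sw, group, prof$psi)
  cf <- sol$coef
  groups <- if (is.null(group)) "(pooled)" else levels(factor(group))
  if (is.null(group)) {
    intercepts <- stats::setNames(unname(cf["(Intercept)"]), groups)
    slopes_below <- stats::setNames(unname(cf["x"]), groups)
    slope_change <- stats::setNames(unname(cf["hinge"]), groups)
  } else {
    intercepts <- stats::setNames(unname(cf[groups]), groups)
    slopes_below <- stats::setNames(unname(cf[paste0(groups, ":x")]), groups)
    slope_change <- stats::setNames(unname(cf[paste0(groups, ":hinge")]),
                                    groups)
  }
  fit <- structure(list(
    breakpoint_mb = prof$psi,
    breakpoint_ci = NULL,
    intercepts = intercepts,
    slopes_below = slopes_below,
    slope_change = slope_change,
    slopes_above = slopes_below + slope_change,
    residual_ss = sol$rss,
    n_obs = nrow(obs),
    n_coef = sum(!is.na(cf)),
    converged = prof$converged,
    grid = prof$grid,
    profile_rss = prof$profile_rss,
    fitted_values = sol$fitted,
    data = obs,
    weights = w,
    group = group,
    options = options
  ), class = "segfit")
  fit
}

#' Confidence interval for the estimated change point
#'
#' Bootstrap resampling animals (default; observations within a male share a
#' random intercept, so the male is the exchangeable unit) with a symmetric
#' bootstrap-standard-error interval (percentile available via
#' [segmented_options()]), or the delta-method interval from the gap-variable
#' standard error.
#'
#' @param fit a `"segfit"`.
#' @param options a [segmented_options()]; defaults to the fit's own.
#' @param level confidence level.
#' @return numeric `c(low, high)`.
#' @export
breakpoint_ci <- function(fit, options = NULL, level = 0.95) {
  stopifnot(inherits(fit, "segfit"))
  if (is.null(options)) options <- fit$options
  obs <- fit$data
  alpha <- (1 - level) / 2
  if (options$ci_method == "delta") {
    x <- obs$consub_length_mb; y <- obs$rate
    sw <- sqrt(fit$weights)
    psi <- fit$breakpoint_mb
    b2row <- if (length(fit$slope_change) == 1L) {
      rep(unname(fit$slope_change), length(x))
    } else {
      unname(fit$slope_change[fit$group])
    }
    X <- cbind(.seg_design(x, fit$group, psi),
               gap = -as.numeric(x > psi) * b2row)
    Xw <- X * sw
    qrX <- qr(Xw)
    res <- qr.resid(qrX, y * sw)
    df <- length(y) - qrX$rank
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(diag(XtXinv) * sigma2)
    names(se) <- colnames(X)
    se_psi <- se["gap"]   # the gap coefficient is on the psi scale
    z <- stats::qnorm(1 - alpha)
    return(unname(c(psi - z * se_psi, psi + z * se_psi)))
  }
  males <- if ("male_id" %in% names(obs)) unique(obs$male_id) else NULL
  if (!is.null(options$seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(options$seed)
  }
  bopt <- options
  bopt$grid_step_mb <- max(options$grid_step_mb, options$boot_grid_step_mb)
  psis <- rep(NA_real_, options$n_boot)
  for (b in seq_len(options$n_boot)) {
    idx <- if (is.null(males)) {
      sample.int(nrow(obs), replace = TRUE)
    } else {
      take <- sample(males, length(males), replace = TRUE)
      unlist(lapply(take, function(m) which(obs$male_id == m)), use.names = FALSE)
    }
    bs <- obs[idx, , drop = FALSE]
    psis[b] <- tryCatch(.refit_psi(bs, bopt), error = function(e) NA_real_)
  }
  psis <- psis[is.finite(psis)]
  if (length(psis) < 10) stop("bootstrap degenerate: too few successful refits")
  if (stats::sd(psis) == 0) stop("bootstrap degenerate: all resamples identical")
  if (identical(options$boot_interval, "percentile")) {
    unname(stats::quantile(psis, c(alpha, 1 - alpha)))
  } else {
    z <- stats::qnorm(1 - alpha)
    fit$breakpoint_mb + c(-1, 1) * z * stats::sd(psis)
  }
}

# lightweight refit returning only the breakpoint (used by the bootstrap)
.refit_psi <- function(obs, options) {
  x <- obs$consub_length_mb
  y <- obs$n_asynapsed / obs$n_scored
  w <- if (options$weighting == "n_scored") obs$n_scored else rep(1, nrow(obs))
  sw <- sqrt(w)
  group <- if (options$per_chromosome_slopes && "chrom" %in% names(obs) &&
               length(unique(obs$chrom)) > 1) obs$chrom else NULL
  qs <- stats::quantile(x, c(options$trim, 1 - options$trim), names = FALSE)
  if (diff(qs) <= options$grid_step_mb) stop("degenerate resample")
  grid <- seq(qs[1], qs[2], by = options$grid_step_mb)
  .seg_profile(x, y, sw, group, grid)$psi
}

#' Extra-sum-of-squares F test for slope heterogeneity
#'
#' Compares a fit with chromosome-specific below-breakpoint slopes against a
#' nested common-slope fit on the same data.
#'
#' @param fit_groupwise the richer `"segfit"` (per-chromosome slopes).
#' @param fit_common the nested `"segfit"` (pooled slope).
#' @return list with `F_statistic`, `df1`, `df2`, `p_value`.
#' @export
slope_equality_test <- function(fit_groupwise, fit_common) {
  stopifnot(inherits(fit_groupwise, "segfit"), inherits(fit_common, "segfit"))
  if (fit_groupwise$n_obs != fit_common$n_obs ||
      !isTRUE(all.equal(sort(fit_groupwise$data$rate),
                        sort(fit_common$data$rate)))) {
    stop("fits are not on identical data")
  }
  p1 <- fit_groupwise$n_coef
  p0 <- fit_common$n_coef
  if (p1 < p0) stop("models are not nested: groupwise fit has fewer parameters")
  rss1 <- fit_groupwise$residual_ss
  rss0 <- fit_common$residual_ss
  df1 <- p1 - p0
  df2 <- fit_groupwise$n_obs - p1 - 1  # -1 for the estimated breakpoint
  if (df1 == 0) {
    return(list(F_statistic = 0, df1 = 0, df2 = df2, p_value = 1))
  }
  Fstat <- max(0, (rss0 - rss1) / df1) / (rss1 / df2)
  list(F_statistic = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Has a consubspecific interval rescued synapsis?
#'
#' @param rate observed asynapsis proportion in \[0, 1\].
#' @param baseline rescue baseline; rates strictly below it count as rescued.
#' @return logical.
#' @export
classify_synapsis_rescue <- function(rate, baseline = 0.05) {
  stopifnot(all(rate >= 0 & rate <= 1))
  rate < baseline
}

#' @export
print.segfit <- function(x, ...) {
  cat("Segmented two-part continuous regression\n")
  cat(sprintf("  change point: %.2f Mb", x$breakpoint_mb))
  if (!is.null(x$breakpoint_ci) && all(is.finite(x$breakpoint_ci))) {
    cat(sprintf(" (95%% CI %.2f, %.2f)", x$breakpoint_ci[1], x$breakpoint_ci[2]))
  }
  cat("\n")
  cat(sprintf("  %d observations, residual SS %.4f\n", x$n_obs, x$residual_ss))
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  print(object)
  tab <- data.frame(group = names(object$intercepts),
                    intercept = unname(object$intercepts),
                    slope_below = unname(object$slopes_below),
                    slope_above = unname(object$slopes_above))
  cat("Per-group segments (rate per Mb):\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.segfit <- function(object, ...) {
  c(breakpoint_mb = object$breakpoint_mb,
    stats::setNames(object$intercepts,
                    paste0("intercept.", names(object$intercepts))),
    stats::setNames(object$slopes_below,
                    paste0("slope_below.", names(object$slopes_below))),
    stats::setNames(object$slope_change,
                    paste0("slope_change.", names(object$slope_change))))
}

#' @export
predict.segfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  x <- if (is.data.frame(newdata)) newdata$consub_length_mb else newdata
  psi <- object$breakpoint_mb
  if (length(object$intercepts) == 1L) {
    b0 <- object$intercepts[[1]]; b1 <- object$slopes_below[[1]]
    b2 <- object$slope_change[[1]]
  } else {
    g <- as.character(newdata$chrom)
    if (any(!g %in% names(object$intercepts))) {
      stop("newdata contains chromosomes absent from the fit")
    }
    b0 <- object$intercepts[g]; b1 <- object$slopes_below[g]
    b2 <- object$slope_change[g]
  }
  unname(b0 + b1 * x + b2 * pmax(x - psi, 0))
}

#' @export
fitted.segfit <- function(object, ...) object$fitted_values

#' @export
residuals.segfit <- function(object, ...) object$data$rate - object$fitted_values

#' @export
plot.segfit <- function(x, ...) {
  obs <- x$data
  cols <- if (is.null(x$group)) "black" else as.integer(factor(x$group))
  graphics::plot(obs$consub_length_mb, obs$rate, col = cols, pch = 16,
                 xlab = "consubspecific length (Mb)", ylab = "asynapsis rate",
                 ...)
  xs <- seq(min(obs$consub_length_mb), max(obs$consub_length_mb), length.out = 200)
  for (g in names(x$intercepts)) {
    nd <- data.frame(consub_length_mb = xs, chrom = g)
    graphics::lines(xs, predict(x, nd),
                    col = if (is.null(x$group)) "red"
                          else which(names(x$intercepts) == g))
  }
  graphics::abline(v = x$breakpoint_mb, lty = 2)
  invisible(x)
}
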