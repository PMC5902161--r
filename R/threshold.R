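#' Least-squares regression through the origin
#'
#' Used to relate per-chromosome asynapsis rates to the simulated probability
#' of carrying fewer than `k` symmetric DSBs. The mechanistic reading — a
#' chromosome with no symmetric DSB cannot synapse, one with enough always can
#' — forces a zero intercept; an intercept can be added for sensitivity
#' analysis.
#'
#' @param x predictor (probabilities), length >= 2, not all zero.
#' @param y response (asynapsis rates), same length.
#' @param intercept fit an ordinary intercept model instead (sensitivity
#'   option); the returned slope is then the x coefficient.
#' @return list with `slope`, `residual_ss`, `n_points`.
#' @export
regress_through_origin <- function(x, y, intercept = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two points")
  if (all(x == 0)) stop("predictor is identically zero")
  if (intercept) {
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    rss <- sum(fit$residuals^2)
  } else {
    slope <- sum(x * y) / sum(x * x)
    rss <- sum((y - slope * x)^2)
  }
  list(slope = unname(slope), residual_ss = rss, n_points = length(x))
}

#' Infer the minimal sufficient number of symmetric DSBs
#'
#' For each candidate threshold `k`, regresses the per-chromosome asynapsis
#' rate through the origin on the per-chromosome probability of fewer than `k`
#' symmetric DSBs. If asynapsis occurs exactly when a chromosome has fewer
#' than `k*` symmetric DSBs, the regression at `k = k*` has unit slope; smaller
#' `k` underestimate the asynapsis probability (slope > 1) and larger `k`
#' overestimate it (slope < 1). The selected `k` is the one whose slope is
#' nearest 1 on the log scale, ties resolved toward smaller `k`.
#'
#' @param asyn_rates named (by chromosome) vector of asynapsis rates.
#' @param dists a `"dsb_pmf_set"` (or named list of `"dsb_pmf"`) aligned with
#'   `asyn_rates` by chromosome name.
#' @param k_range candidate thresholds, positive integers.
#' @return list of class `"threshold_scan"` with a per-`k` results table and
#'   the selected threshold.
#' @export
infer_threshold_k <- function(asyn_rates, dists, k_range = 1:5) {
  if (length(asyn_rates) == 0 || length(dists) == 0) {
    stop("empty inputs")
  }
  if (length(k_range) == 0) stop("k_range must be nonempty")
  chroms <- vapply(dists, function(d) d$chrom, character(1))
  if (!is.null(names(asyn_rates))) {
    if (!setequal(names(asyn_rates), chroms)) {
      stop("chromosomes of asyn_rates and dists do not match")
    }
    asyn_rates <- asyn_rates[chroms]
  } else if (length(asyn_rates) != length(dists)) {
    stop("asyn_rates and dists must align chromosome by chromosome")
  }
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    x <- vapply(dists, prob_fewer_than_k, numeric(1), k = k)
    fit <- regress_through_origin(x, asyn_rates)
    data.frame(k = k, slope = fit$slope, residual_ss = fit$residual_ss,
               n_points = fit$n_points)
  })
  tab <- do.call(rbind, rows)
  crit <- abs(log(pmax(tab$slope, .Machine$double.xmin)))
  crit[tab$slope <= 0] <- Inf
  selected <- tab$k[which.min(crit)]  # which.min takes the first: smaller k on ties
  structure(list(table = tab, selected_k = selected,
                 slope_at_selected = tab$slope[tab$k == selected]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("Symmetric-DSB threshold scan (asynapsis rate ~ P(< k symmetric))\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Selected k = %d (slope %.3f): %d or more symmetric DSBs suffice\n",
              x$selected_k, x$slope_at_selected, x$selected_k))
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, ...) {
  graphics::plot(x$table$k, x$table$slope, type = "b", log = "y",
                 xlab = "threshold k", ylab = "through-origin slope", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of (average) ranks. The p-value uses the
#' t approximation for n > 9 and exact permutation enumeration otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least three observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: Spearman's rho is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 9) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    perms <- .all_permutations(n)
    ry_mat <- matrix(ry[perms], nrow = n)
    rx_c <- rx - mean(rx)
    s_obs <- sum(rx_c * ry)
    s_all <- as.vector(crossprod(rx_c, ry_mat))
    # |rho| ordering equals |centered cross-product| ordering
    p <- mean(abs(s_all) >= abs(s_obs) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method)
}

# n x n! matrix of all permutations of 1..n (column-wise), built recursively
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  cols <- ncol(sub)
  out <- matrix(0L, n, n * cols)
  for (i in seq_len(n)) {
    block <- rbind(rep.int(i, cols),
                   sub + (sub >= i))
    out[, ((i - 1L) * cols + 1L):(i * cols)] <- block
  }
  out
}
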