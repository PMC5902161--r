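#' Per-chromosome asynapsis rate table
#'
#' Pools scored pachynemas per chromosome and attaches likelihood-ratio
#' binomial confidence intervals; also returns per-male rates. Asynapsis class
#' breakdowns (complete / partial / intermingled), when present, are carried
#' through.
#'
#' @param scores data frame with columns `male_id`, `chrom`, `n_scored`,
#'   `n_asynapsed`, optionally `n_complete`, `n_partial`, `n_intermingled`.
#' @param level confidence level for the LR intervals.
#' @return list with `pooled` (one row per chromosome) and `per_male` data
#'   frames.
#' @export
asynapsis_rate_table <- function(scores, level = 0.95) {
  need <- c("male_id", "chrom", "n_scored", "n_asynapsed")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(scores$n_asynapsed > scores$n_scored)) {
    stop("n_asynapsed exceeds n_scored")
  }
  agg_cols <- intersect(c("n_scored", "n_asynapsed", "n_complete",
                          "n_partial", "n_intermingled"), names(scores))
  pooled <- stats::aggregate(scores[agg_cols], by = list(chrom = scores$chrom),
                             FUN = sum)
  if (any(pooled$n_scored == 0)) {
    stop("chromosome with zero scored pachynemas: ",
         paste(pooled$chrom[pooled$n_scored == 0], collapse = ", "))
  }
  pooled$rate <- pooled$n_asynapsed / pooled$n_scored
  cis <- t(mapply(lr_ci_binomial, pooled$n_asynapsed, pooled$n_scored,
                  MoreArgs = list(level = level)))
  pooled$ci_low <- cis[, 1]
  pooled$ci_high <- cis[, 2]
  num <- suppressWarnings(as.numeric(pooled$chrom))
  pooled <- pooled[if (anyNA(num)) order(pooled$chrom) else order(num), ]
  rownames(pooled) <- NULL
  per_male <- scores
  per_male$rate <- per_male$n_asynapsed / per_male$n_scored
  cis_m <- t(mapply(lr_ci_binomial, per_male$n_asynapsed, per_male$n_scored,
                    MoreArgs = list(level = level)))
  per_male$ci_low <- cis_m[, 1]
  per_male$ci_high <- cis_m[, 2]
  list(pooled = pooled, per_male = per_male)
}

#' Expected fraction of fully synapsed pachynemas under independence
#'
#' Multiplies per-chromosome synapsis rates; valid exactly when chromosomes
#' synapse independently, which is the null the trans-effect analysis tests.
#'
#' @param synapsis_rates per-chromosome synapsis probabilities in \[0, 1\].
#' @return product over chromosomes.
#' @export
expected_full_synapsis <- function(synapsis_rates) {
  stopifnot(all(synapsis_rates >= 0 & synapsis_rates <= 1))
  prod(synapsis_rates)
}

#' Per-male expected fully synapsed fraction
#'
#' Combines the male's own observed synapsis rates on the chromosomes scored
#' in his cross with baseline F1 synapsis rates for the remaining autosomes.
#'
#' @param male_synapsis_rates named vector of the male's observed synapsis
#'   rates for the chromosomes scored in him.
#' @param f1_baseline named vector of baseline (F1) synapsis rates covering
#'   every autosome not scored in this male.
#' @param autosomes the full autosome set; defaults to the union of the two
#'   name sets.
#' @return expected probability that a pachynema has all autosomes synapsed.
#' @export
expected_full_synapsis_per_male <- function(male_synapsis_rates, f1_baseline,
                                            autosomes = NULL) {
  stopifnot(!is.null(names(male_synapsis_rates)), !is.null(names(f1_baseline)))
  if (is.null(autosomes)) {
    autosomes <- union(names(f1_baseline), names(male_synapsis_rates))
  }
  rest <- setdiff(autosomes, names(male_synapsis_rates))
  unmatched <- setdiff(rest, names(f1_baseline))
  if (length(unmatched)) {
    stop("no baseline synapsis rate for autosome(s): ",
         paste(unmatched, collapse = ", "))
  }
  expected_full_synapsis(c(male_synapsis_rates[
    intersect(names(male_synapsis_rates), autosomes)], f1_baseline[rest]))
}

#' Predicted fully synapsed fraction after rescuing chosen chromosomes
#'
#' Replaces the synapsis rates of the rescued chromosomes by 1 and multiplies.
#' Quantifies how much of the spermatocyte pool full rescue of a chromosome
#' subset would recover, under independence.
#'
#' @param f1_synapsis_rates named per-chromosome synapsis rates.
#' @param rescued labels of chromosomes assumed fully rescued.
#' @return predicted probability of a fully synapsed autosome set.
#' @export
predict_rescue_fraction <- function(f1_synapsis_rates, rescued = character()) {
  stopifnot(!is.null(names(f1_synapsis_rates)))
  unknown <- setdiff(rescued, names(f1_synapsis_rates))
  if (length(unknown)) {
    stop("unknown chromosome(s) in rescued set: ",
         paste(unknown, collapse = ", "))
  }
  r <- f1_synapsis_rates
  r[rescued] <- 1
  expected_full_synapsis(r)
}

#' Trans-effect log-log regression
#'
#' For each focal chromosome, regresses the log per-male asynapsis rate of
#' that chromosome on the log of the predicted synapsis rate of the other
#' scored chromosomes (their per-male product). The per-chromosome slopes
#' (elasticities) are pooled by inverse-variance weighting. The summary
#' `pct_change_per_10pct = 100 * (1 - 1.1^slope)` is the percent decrease of
#' focal asynapsis expected from a 10 percent increase in the others'
#' predicted synapsis.
#'
#' @param scores per-male scoring table (`male_id`, `chrom`, `n_scored`,
#'   `n_asynapsed`) restricted to the focal chromosome set.
#' @param focal_chroms chromosomes to analyse; default all in `scores`.
#' @param zero_handling `"anscombe"` replaces zero focal rates by
#'   `(n_asynapsed + 0.5) / (n_scored + 1)`; `"exclude"` drops them.
#' @param level confidence level.
#' @return list of class `"trans_effect"` with the pooled `loglog_slope`, its
#'   `ci`, `pct_change_per_10pct` (with CI), `p_value`, and a `per_chromosome`
#'   table.
#' @export
trans_effect_loglog <- function(scores, focal_chroms = NULL,
                                zero_handling = c("anscombe", "exclude"),
                                level = 0.95) {
  zero_handling <- match.arg(zero_handling)
  if (is.null(focal_chroms)) focal_chroms <- unique(scores$chrom)
  scores <- scores[scores$chrom %in% focal_chroms, , drop = FALSE]
  wide_rate <- function(m, ch) {
    row <- scores[scores$male_id == m & scores$chrom == ch, ]
    if (nrow(row) != 1) return(NA_real_)
    row$n_asynapsed / row$n_scored
  }
  males <- unique(scores$male_id)
  per_chrom <- lapply(focal_chroms, function(fc) {
    xs <- ys <- numeric(0)
    for (m in males) {
      focal <- scores[scores$male_id == m & scores$chrom == fc, ]
      others <- scores[scores$male_id == m & scores$chrom != fc, ]
      if (nrow(focal) != 1 || nrow(others) == 0) next
      rate <- focal$n_asynapsed / focal$n_scored
      if (rate == 0) {
        if (zero_handling == "exclude") next
        rate <- (focal$n_asynapsed + 0.5) / (focal$n_scored + 1)
      }
      pred_syn <- prod(1 - others$n_asynapsed / others$n_scored)
      if (pred_syn <= 0) next
      xs <- c(xs, log(pred_syn))
      ys <- c(ys, log(rate))
    }
    if (length(xs) < 4) {
      return(data.frame(chrom = fc, slope = NA_real_, se = NA_real_,
                        n_males = length(xs)))
    }
    fit <- stats::lm(ys ~ xs)
    sm <- summary(fit)$coefficients
    data.frame(chrom = fc, slope = sm["xs", "Estimate"],
               se = sm["xs", "Std. Error"], n_males = length(xs))
  })
  tab <- do.call(rbind, per_chrom)
  ok <- is.finite(tab$slope) & is.finite(tab$se) & tab$se > 0
  if (!any(ok)) stop("fewer than 4 usable males for every focal chromosome")
  w <- 1 / tab$se[ok]^2
  slope <- sum(w * tab$slope[ok]) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(slope - z * se, slope + z * se)
  pct <- function(s) 100 * (1 - 1.1^s)
  structure(list(loglog_slope = slope,
                 se = se,
                 ci = ci,
                 pct_change_per_10pct = pct(slope),
                 pct_ci = sort(pct(ci)),
                 p_value = 2 * stats::pnorm(-abs(slope / se)),
                 per_chromosome = tab),
            class = "trans_effect")
}

#' @export
print.trans_effect <- function(x, ...) {
  cat("Trans-effect log-log regression\n")
  cat(sprintf("  elasticity %.3f (95%% CI %.3f, %.3f), p = %.4g\n",
              x$loglog_slope, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  a 10%% rise in others' predicted synapsis -> %.2f%% (%.2f, %.2f) change in focal asynapsis\n",
              x$pct_change_per_10pct, x$pct_ci[1], x$pct_ci[2]))
  print(x$per_chromosome, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sperm-count fertility summary
#'
#' @param records data frame with columns `male_id`, `sperm_million` (and any
#'   others, carried along).
#' @param bins data frame with columns `lo`, `hi` (inclusive bounds, millions);
#'   a zero bin is `lo = hi = 0`. Bins must be disjoint and cover all values.
#' @return data frame with per-bin `n` and `pct`.
#' @export
fertility_summary <- function(records,
                              bins = data.frame(lo = c(0, 0.01, 1),
                                                hi = c(0, 0.99, Inf))) {
  stopifnot(all(records$sperm_million >= 0))
  v <- records$sperm_million
  hit <- vapply(v, function(s) {
    j <- which(s >= bins$lo & s <= bins$hi)
    if (length(j) == 0) stop("sperm count ", s, " falls in no bin")
    if (length(j) > 1) stop("bins are not disjoint at value ", s)
    j
  }, integer(1))
  n <- tabulate(hit, nbins = nrow(bins))
  data.frame(lo = bins$lo, hi = bins$hi, n = n,
             pct = 100 * n / length(v))
}

#' Sperm presence versus the probability of full synapsis
#'
#' Compares the per-male probability that all scored (consomic) chromosomes are
#' synapsed between sperm-positive and aspermic males (Mann-Whitney), and
#' reports how the `threshold` rule separates the groups.
#'
#' @param records fertility records with `male_id` and `sperm_million`.
#' @param p_all_synapsed named (by `male_id`) per-male probability that all
#'   scored chromosomes are synapsed.
#' @param threshold synapsis-probability rule of thumb for fertility.
#' @return list with the test result and per-group summaries.
#' @export
sperm_presence_vs_synapsis <- function(records, p_all_synapsed,
                                       threshold = 0.7) {
  stopifnot(!is.null(names(p_all_synapsed)))
  miss <- setdiff(records$male_id, names(p_all_synapsed))
  if (length(miss)) {
    stop("no synapsis probability for male(s): ", paste(miss, collapse = ", "))
  }
  p <- p_all_synapsed[as.character(records$male_id)]
  has_sperm <- records$sperm_million > 0
  grp <- list(sperm_positive = p[has_sperm], aspermic = p[!has_sperm])
  if (length(grp$sperm_positive) == 0 || length(grp$aspermic) == 0) {
    return(list(test = NULL, degenerate = TRUE,
                note = "one group is empty; no test performed",
                groups = grp, threshold = threshold))
  }
  test <- mann_whitney_test(grp$sperm_positive, grp$aspermic)
  list(test = test, degenerate = FALSE,
       groups = grp,
       threshold = threshold,
       frac_above_threshold = c(
         sperm_positive = mean(grp$sperm_positive > threshold),
         aspermic = mean(grp$aspermic > threshold)))
}
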