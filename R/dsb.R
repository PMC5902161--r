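#' Parameters of the symmetric-DSB simulator
#'
#' The per-cell autosomal DSB total is modelled as a rounded, zero-truncated
#' normal draw; DSBs are allocated to autosomes in proportion to their
#' SPO11-oligo shares; a DSB landing in consubspecific (homozygous) sequence is
#' always in a symmetric hotspot, while one landing in heterosubspecific
#' sequence is symmetric with probability `p_sym`.
#'
#' @param mean_total_dsb mean autosomal DSBs per leptotene/zygotene cell.
#' @param sd_total_dsb standard deviation of the per-cell total.
#' @param p_sym probability that a DSB in heterosubspecific sequence falls in a
#'   symmetric hotspot.
#' @param n_sims number of simulated cells.
#' @param seed optional integer seed; when given, simulation is reproducible.
#' @param k_max largest symmetric count tracked explicitly; larger counts pool
#'   into a tail bin.
#' @param allocation `"multinomial"` (default; preserves the cell total and has
#'   binomial per-chromosome marginals) or `"proportional"` (deterministic
#'   rounding of the expected per-chromosome counts).
#' @param explicit_positions if `TRUE`, DSB positions are drawn uniformly along
#'   the chromosome and tested against the actual interval bounds rather than
#'   using the equivalent Bernoulli(`f_homo`) membership draw.
#' @return list of class `"dsb_sim_params"`.
#' @export
dsb_sim_params <- function(mean_total_dsb = 250, sd_total_dsb = 20,
                           p_sym = 0.28, n_sims = 100000L, seed = NULL,
                           k_max = 10L,
                           allocation = c("multinomial", "proportional"),
                           explicit_positions = FALSE) {
  allocation <- match.arg(allocation)
  stopifnot(mean_total_dsb > 0, sd_total_dsb >= 0,
            p_sym >= 0, p_sym <= 1, n_sims >= 1, k_max >= 1)
  structure(list(mean_total_dsb = mean_total_dsb,
                 sd_total_dsb = sd_total_dsb,
                 p_sym = p_sym,
                 n_sims = as.integer(n_sims),
                 seed = seed,
                 k_max = as.integer(k_max),
                 allocation = allocation,
                 explicit_positions = explicit_positions),
            class = "dsb_sim_params")
}

# draw n per-cell DSB totals: round a normal draw, redraw negatives
.draw_total_dsb <- function(n, mean, sd) {
  if (sd == 0) return(rep.int(round(mean), n))
  t <- round(stats::rnorm(n, mean, sd))
  while (any(neg <- t < 0)) {
    t[neg] <- round(stats::rnorm(sum(neg), mean, sd))
  }
  t
}

# multinomial allocation of totals across chromosomes by conditional binomials
.allocate_multinomial <- function(totals, shares) {
  n <- length(totals)
  C <- length(shares)
  out <- matrix(0L, n, C)
  remaining <- totals
  tail_share <- rev(cumsum(rev(shares)))
  for (c in seq_len(C - 1L)) {
    p <- shares[c] / tail_share[c]
    draw <- stats::rbinom(n, remaining, min(1, p))
    out[, c] <- draw
    remaining <- remaining - draw
  }
  out[, C] <- remaining
  out
}

# normalise the `recombinants` argument to a named f_homo vector plus
# (optionally) the per-chromosome interval midpoints for the explicit path
.resolve_recombinants <- function(karyotype, recombinants) {
  f_homo <- stats::setNames(rep(0, nrow(karyotype)), karyotype$chrom)
  segs <- stats::setNames(vector("list", nrow(karyotype)), karyotype$chrom)
  if (is.null(recombinants)) {
    return(list(f_homo = f_homo, segments = segs))
  }
  if (is.numeric(recombinants)) {
    unknown <- setdiff(names(recombinants), karyotype$chrom)
    if (length(unknown)) {
      stop("unknown chromosome in recombinants: ",
           paste(unknown, collapse = ", "))
    }
    if (any(recombinants < 0 | recombinants > 1)) {
      stop("f_homo values must lie in [0, 1]")
    }
    f_homo[names(recombinants)] <- recombinants
    return(list(f_homo = f_homo, segments = segs))
  }
  if (inherits(recombinants, "recombinant_chromosome")) {
    recombinants <- list(recombinants)
  }
  for (rc in recombinants) {
    if (!inherits(rc, "recombinant_chromosome")) {
      stop("recombinants must be f_homo values or recombinant_chromosome objects")
    }
    if (!rc$chrom %in% karyotype$chrom) {
      stop("unknown chromosome in recombinants: ", rc$chrom)
    }
    f_homo[rc$chrom] <- rc$f_homo
    segs[[rc$chrom]] <- cbind(start = rc$start_mid_mb, end = rc$end_mid_mb)
  }
  list(f_homo = f_homo, segments = segs)
}

.new_dsb_pmf <- function(chrom, pmf, n_sims, mc_se = NULL) {
  # bins are counts 0..k_max followed by a pooled tail
  names(pmf) <- c(as.character(seq_len(length(pmf) - 1L) - 1L), "tail")
  structure(list(chrom = chrom, pmf = pmf, n_sims = n_sims, mc_se = mc_se),
            class = "dsb_pmf")
}

#' Monte-Carlo distribution of symmetric DSB counts per chromosome
#'
#' Simulates `n_sims` cells. Each cell draws a total DSB count, allocates it
#' across the karyotype's autosomes in proportion to their SPO11-oligo shares,
#' and classifies each DSB as symmetric or not: DSBs inside consubspecific
#' sequence are always symmetric, the rest independently with probability
#' `p_sym`.
#'
#' @param karyotype a [karyotype()].
#' @param recombinants consubspecific configuration: `NULL` (all
#'   heterosubspecific), a named numeric vector of homozygous fractions
#'   `f_homo` per chromosome, or a list of [recombinant_chromosome()] objects.
#' @param params a [dsb_sim_params()].
#' @return list of class `"dsb_pmf_set"`; one `"dsb_pmf"` per chromosome, each
#'   with the empirical pmf over symmetric counts `0..k_max` plus a tail bin,
#'   and per-bin Monte-Carlo standard errors.
#' @export
simulate_symmetric_pmf <- function(karyotype, recombinants = NULL,
                                   params = dsb_sim_params()) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (params$n_sims < 1) stop("n_sims must be at least 1")
  rec <- .resolve_recombinants(karyotype, recombinants)
  if (!is.null(params$seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(params$seed)
  }
  n <- params$n_sims
  totals <- .draw_total_dsb(n, params$mean_total_dsb, params$sd_total_dsb)
  shares <- karyotype$spo11_share
  counts <- if (params$allocation == "multinomial") {
    .allocate_multinomial(totals, shares)
  } else {
    round(outer(totals, shares))
  }
  out <- vector("list", nrow(karyotype))
  names(out) <- karyotype$chrom
  for (c in seq_len(nrow(karyotype))) {
    lab <- karyotype$chrom[c]
    nc <- counts[, c]
    fh <- rec$f_homo[[lab]]
    if (params$explicit_positions && !is.null(rec$segments[[lab]])) {
      in_homo <- .count_in_intervals(nc, karyotype$length_mb[c],
                                     rec$segments[[lab]])
    } else {
      in_homo <- stats::rbinom(n, nc, fh)
    }
    sym <- in_homo + stats::rbinom(n, nc - in_homo, params$p_sym)
    pmf <- .tabulate_pmf(sym, params$k_max)
    mc_se <- sqrt(pmf * (1 - pmf) / n)
    out[[c]] <- .new_dsb_pmf(lab, pmf, n, mc_se)
  }
  structure(out, class = "dsb_pmf_set", params = params)
}

# explicit-position path: draw uniform positions for all DSBs of a chromosome
# across cells at once and test membership in the resolved interval midpoints
.count_in_intervals <- function(n_per_cell, length_mb, segments) {
  total <- sum(n_per_cell)
  if (total == 0L) return(integer(length(n_per_cell)))
  pos <- stats::runif(total, 0, length_mb)
  inside <- rep(FALSE, total)
  for (s in seq_len(nrow(segments))) {
    inside <- inside | (pos >= segments[s, "start"] & pos < segments[s, "end"])
  }
  cell <- rep.int(seq_along(n_per_cell), n_per_cell)
  counts <- integer(length(n_per_cell))
  agg <- rowsum(as.integer(inside), cell)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  counts
}

.tabulate_pmf <- function(sym, k_max) {
  bins <- pmin(sym, k_max + 1L)
  p <- tabulate(bins + 1L, nbins = k_max + 2L) / length(sym)
  p
}

#' Exact distribution of symmetric DSB counts (analytic oracle)
#'
#' Closed-form counterpart of [simulate_symmetric_pmf()] for one chromosome
#' under the collapsed membership model: each of the chromosome's DSBs is
#' symmetric with probability `pi = f_homo + (1 - f_homo) * p_sym`; the
#' chromosome receives a `Binomial(T, spo11_share)` share of the cell total
#' `T`, which follows the rounded zero-truncated normal. By binomial thinning
#' the symmetric count given `T` is `Binomial(T, spo11_share * pi)`, and the
#' pmf is the exact finite mixture over `T`.
#'
#' @param chrom_spec one row of a [karyotype()] (needs `chrom`, `spo11_share`).
#' @param f_homo homozygous (consubspecific) fraction of the chromosome.
#' @param params a [dsb_sim_params()] (its `n_sims`/`seed` are ignored).
#' @return A `"dsb_pmf"` with `n_sims = 0` and no Monte-Carlo error.
#' @export
closed_form_symmetric_pmf <- function(chrom_spec, f_homo,
                                      params = dsb_sim_params()) {
  stopifnot(f_homo >= 0, f_homo <= 1)
  pi_sym <- f_homo + (1 - f_homo) * params$p_sym
  q <- pi_sym * chrom_spec$spo11_share
  mu <- params$mean_total_dsb
  sd <- params$sd_total_dsb
  if (sd == 0) {
    t_vals <- round(mu)
    w <- 1
  } else {
    lo <- max(0, floor(mu - 10 * sd))
    hi <- ceiling(mu + 10 * sd)
    t_vals <- lo:hi
    w <- stats::pnorm((t_vals + 0.5 - mu) / sd) -
      stats::pnorm((t_vals - 0.5 - mu) / sd)
    if (lo == 0) w[1] <- stats::pnorm((0.5 - mu) / sd)
    w <- w / (1 - stats::pnorm((-0.5 - mu) / sd))
  }
  k <- 0:params$k_max
  pmf_k <- vapply(k, function(kk) sum(w * stats::dbinom(kk, t_vals, q)),
                  numeric(1))
  pmf <- c(pmf_k, max(0, 1 - sum(pmf_k)))
  .new_dsb_pmf(as.character(chrom_spec$chrom), pmf, 0L)
}

#' Probability of fewer than k symmetric DSBs
#'
#' @param dist a `"dsb_pmf"`.
#' @param k positive integer; must not exceed `k_max + 1`.
#' @return `P(symmetric count < k)`.
#' @export
prob_fewer_than_k <- function(dist, k) {
  stopifnot(inherits(dist, "dsb_pmf"))
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  k_max <- length(dist$pmf) - 2L
  if (k > k_max + 1L) {
    stop("k = ", k, " exceeds the tracked range (k_max = ", k_max, ")")
  }
  sum(dist$pmf[seq_len(k)])
}

#' @export
print.dsb_pmf <- function(x, ...) {
  src <- if (x$n_sims > 0) sprintf("%d simulated cells", x$n_sims) else "analytic"
  cat(sprintf("Symmetric-DSB distribution, Chr %s (%s)\n", x$chrom, src))
  print(round(x$pmf, 5))
  invisible(x)
}

#' @export
print.dsb_pmf_set <- function(x, ...) {
  cat(sprintf("Symmetric-DSB distributions for %d chromosomes\n", length(x)))
  tab <- t(vapply(x, function(d) d$pmf, x[[1]]$pmf))
  print(round(tab, 4))
  invisible(x)
}

#' Tidy a set of symmetric-DSB distributions into a long table
#'
#' @param dists a `"dsb_pmf_set"` (or list of `"dsb_pmf"`).
#' @return data frame with columns `chrom`, `k`, `probability`, `mc_se`.
#' @export
dsb_pmf_table <- function(dists) {
  do.call(rbind, lapply(dists, function(d) {
    data.frame(chrom = d$chrom,
               k = names(d$pmf),
               probability = unname(d$pmf),
               mc_se = if (is.null(d$mc_se)) NA_real_ else unname(d$mc_se),
               stringsAsFactors = FALSE)
  }))
}

# preserve/restore global RNG state so seeded helpers do not disturb callers
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
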