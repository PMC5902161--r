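#' Synthetic mouse-like karyotype
#'
#' Autosome lengths decrease linearly from ~195 to ~61 Mb (the span of the
#' mouse autosomes); SPO11-oligo shares are proportional to length with
#' moderate lognormal perturbation, mirroring the strong but imperfect
#' observed correlation between chromosome length and DSB density.
#'
#' @param n_autosomes number of autosomes (>= 2).
#' @param seed optional seed.
#' @param share_sdlog lognormal perturbation of the length-proportional share.
#' @return a [karyotype()].
#' @export
generate_karyotype <- function(n_autosomes = 19, seed = NULL,
                               share_sdlog = 0.1) {
  stopifnot(n_autosomes >= 2)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  lengths <- seq(195, 61, length.out = n_autosomes)
  counts <- lengths * stats::rlnorm(n_autosomes, 0, share_sdlog)
  karyotype(as.character(seq_len(n_autosomes)), lengths, counts)
}

#' Configuration of the synthetic cross generator
#'
#' Defaults emulate the design of the cytological study the analysis targets:
#' 40 F1 hybrid males scored on all autosomes; three two-chromosome crosses
#' (chromosome pairs 5+12, 7+15, 17+18; 61 males, 122 scored chromosomes); a
#' four-chromosome cross (15, 16, 18, 19) with 87 males carrying fertility
#' records of which 18 are scored cytologically. Baseline F1 asynapsis rates
#' rise from 2.6 percent (Chr 1) to 42.2 percent (Chr 19); the synapsis-rescue
#' change point sits at 27 Mb of consubspecific sequence, below which the
#' asynapsis rate falls linearly from the F1 maximum to a 2 percent floor.
#' About 100 pachynemas are scored per male and chromosome.
#'
#' @param karyotype a [karyotype()]; default [generate_karyotype()] with the
#'   generator seed.
#' @param n_males_f1 F1 males.
#' @param cross_pairs list of chromosome pairs for the 2-chr crosses.
#' @param n_males_2chr males per 2-chr cross (recycled over `cross_pairs`).
#' @param chroms_4chr chromosomes segregating in the 4-chr cross.
#' @param n_males_4chr 4-chr males with fertility records.
#' @param n_scored_males_4chr 4-chr males additionally scored by FISH.
#' @param f1_max_asynapsis named per-chromosome maximal (F1, nonrecombinant)
#'   asynapsis rates; default interpolates 0.026..0.422 over the autosomes.
#' @param psi_true_mb true change point, Mb.
#' @param asyn_floor asynapsis rate reached at and beyond the change point.
#' @param slope_below named per-chromosome slope (rate per Mb) below the change
#'   point; default `(asyn_floor - f1_max) / psi_true_mb`, reaching the floor
#'   exactly at the change point.
#' @param sigma_u per-animal random-intercept standard deviation, logit scale.
#' @param gamma trans-effect coupling: logit-scale shift proportional to how
#'   much the mean true asynapsis of the other scored chromosomes falls below
#'   its F1 value.
#' @param n_scored_mean mean pachynemas scored per male and chromosome
#'   (Poisson, truncated below at 20).
#' @param tau synapsis-probability threshold below which a male is aspermic.
#' @param sperm_meanlog,sperm_sdlog lognormal parameters (millions) of positive
#'   sperm counts before scaling by the full-synapsis probability.
#' @param p_whole,p_none,p_interstitial probabilities that a transmitted
#'   consomic chromosome is nonrecombinant consubspecific, nonrecombinant
#'   intersubspecific, or carries a double-crossover interstitial interval;
#'   the remainder are single-crossover proximal/distal segments.
#' @param marker_jitter_mb marker uncertainty: interval bounds are widened
#'   outward by Uniform(0, `marker_jitter_mb`/2) on each side.
#' @param class_split multinomial split of asynapsed pachynemas into complete,
#'   partial and intermingled classes.
#' @param seed integer seed; the generator is deterministic given the
#'   (config, seed) pair.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(karyotype = NULL,
                             n_males_f1 = 40L,
                             cross_pairs = list(c("5", "12"), c("7", "15"),
                                                c("17", "18")),
                             n_males_2chr = c(21L, 20L, 20L),
                             chroms_4chr = c("15", "16", "18", "19"),
                             n_males_4chr = 87L,
                             n_scored_males_4chr = 18L,
                             f1_max_asynapsis = NULL,
                             psi_true_mb = 27,
                             asyn_floor = 0.02,
                             slope_below = NULL,
                             sigma_u = 0.3,
                             gamma = 1,
                             n_scored_mean = 100,
                             tau = 0.7,
                             sperm_meanlog = log(4),
                             sperm_sdlog = 1,
                             p_whole = 0.2,
                             p_none = 0.2,
                             p_interstitial = 0.1,
                             marker_jitter_mb = 3,
                             class_split = c(complete = 0.5, partial = 0.4,
                                             intermingled = 0.1),
                             seed = 1L) {
  if (is.null(karyotype)) karyotype <- generate_karyotype(19, seed = seed)
  chroms <- karyotype$chrom
  if (is.null(f1_max_asynapsis)) {
    n <- length(chroms)
    f1_max_asynapsis <- stats::setNames(
      0.026 + (0.422 - 0.026) * (seq_len(n) - 1) / (n - 1), chroms)
  }
  if (any(f1_max_asynapsis < 0 | f1_max_asynapsis > 1)) {
    stop("f1_max_asynapsis rates must lie in [0, 1]")
  }
  if (psi_true_mb <= 0 || psi_true_mb >= max(karyotype$length_mb)) {
    stop("psi_true_mb must lie within the chromosome length range")
  }
  if (n_scored_mean < 20) stop("n_scored_mean must be at least 20")
  if (is.null(slope_below)) {
    slope_below <- (asyn_floor - f1_max_asynapsis) / psi_true_mb
  }
  used <- unique(c(unlist(cross_pairs), chroms_4chr))
  unknown <- setdiff(used, chroms)
  if (length(unknown)) {
    stop("cross design uses chromosomes absent from the karyotype: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(
    karyotype = karyotype,
    n_males_f1 = as.integer(n_males_f1),
    cross_pairs = cross_pairs,
    n_males_2chr = rep_len(as.integer(n_males_2chr), length(cross_pairs)),
    chroms_4chr = chroms_4chr,
    n_males_4chr = as.integer(n_males_4chr),
    n_scored_males_4chr = as.integer(n_scored_males_4chr),
    f1_max_asynapsis = f1_max_asynapsis,
    psi_true_mb = psi_true_mb,
    asyn_floor = asyn_floor,
    slope_below = slope_below,
    sigma_u = sigma_u,
    gamma = gamma,
    n_scored_mean = n_scored_mean,
    tau = tau,
    sperm_meanlog = sperm_meanlog,
    sperm_sdlog = sperm_sdlog,
    p_whole = p_whole,
    p_none = p_none,
    p_interstitial = p_interstitial,
    marker_jitter_mb = marker_jitter_mb,
    class_split = class_split,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# true asynapsis rate of one chromosome given its consubspecific length:
# piecewise linear, flat beyond the change point, clamped to (0, 1)
.true_rate <- function(len_mb, chrom, config) {
  r0 <- config$f1_max_asynapsis[[chrom]]
  s <- config$slope_below[[chrom]]
  mu <- r0 + s * pmin(len_mb, config$psi_true_mb)
  pmin(pmax(mu, 1e-4), 1 - 1e-4)
}

# draw one transmitted consomic chromosome: returns true interval bounds
# (zero-row matrix for a nonrecombinant intersubspecific chromosome)
.draw_interval <- function(length_mb, config) {
  u <- stats::runif(1)
  if (u < config$p_whole) {
    return(cbind(start = 0, end = length_mb))
  }
  if (u < config$p_whole + config$p_none) {
    return(cbind(start = numeric(0), end = numeric(0)))
  }
  if (u < config$p_whole + config$p_none + config$p_interstitial) {
    bp <- sort(stats::runif(2, 0.05 * length_mb, 0.95 * length_mb))
    return(cbind(start = bp[1], end = bp[2]))
  }
  bp <- stats::runif(1, 0.05 * length_mb, 0.95 * length_mb)
  if (stats::runif(1) < 0.5) {
    cbind(start = 0, end = bp)         # proximal consubspecific segment
  } else {
    cbind(start = bp, end = length_mb) # distal consubspecific segment
  }
}

# jitter true breakpoints outward into marker-bounded (min, max) columns
.jitter_bounds <- function(seg, length_mb, jitter_mb) {
  if (nrow(seg) == 0) return(NULL)
  out <- lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, "start"]; e <- seg[i, "end"]
    j <- stats::runif(4, 0, jitter_mb / 2)
    smin <- if (s <= 0) 0 else max(0, s - j[1])
    smax <- if (s <= 0) 0 else min(s + j[2], s + (e - s) / 2)
    emax <- if (e >= length_mb) length_mb else min(length_mb, e + j[3])
    emin <- if (e >= length_mb) length_mb else max(e - j[4], smax)
    c(start_min_mb = smin, start_max_mb = smax,
      end_min_mb = emin, end_max_mb = emax)
  })
  do.call(rbind, out)
}

#' Generate a complete synthetic cross dataset
#'
#' Produces the tables a cytological asynapsis study yields: marker-bounded
#' recombinant interval coordinates, per-male per-chromosome pachytene scoring
#' counts, and fertility records, together with a truth record of every latent
#' parameter. Per-male counts are binomial draws around a true rate that is
#' piecewise-linear in consubspecific length (change point `psi_true_mb`),
#' shifted on the logit scale by a per-animal normal intercept and by the
#' trans-effect coupling to the other scored chromosomes. A male is aspermic
#' when the probability that all his scored chromosomes synapse falls below
#' `tau`; otherwise his sperm count is lognormal scaled by that probability.
#'
#' @param config a [generator_config()].
#' @return list of class `"synthetic_cross_data"` with elements `karyotype`,
#'   `intervals`, `scores`, `fertility`, `truth`.
#' @export
generate_cross_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  K <- config$karyotype
  len_of <- stats::setNames(K$length_mb, K$chrom)

  males <- data.frame(male_id = character(), cross = character(),
                      stringsAsFactors = FALSE)
  scored_of <- list()   # chromosomes scored per male
  add_males <- function(prefix, n, cross, chroms) {
    ids <- sprintf("%s_%02d", prefix, seq_len(n))
    males <<- rbind(males, data.frame(male_id = ids, cross = cross,
                                      stringsAsFactors = FALSE))
    for (id in ids) scored_of[[id]] <<- chroms
    ids
  }
  f1_ids <- add_males("F1", config$n_males_f1, "F1", K$chrom)
  ids_2chr <- character(0)
  for (j in seq_along(config$cross_pairs)) {
    ids_2chr <- c(ids_2chr,
                  add_males(sprintf("C2%s", letters[j]),
                            config$n_males_2chr[j], "2chr",
                            config$cross_pairs[[j]]))
  }
  ids_4chr <- add_males("G4", config$n_males_4chr, "4chr", config$chroms_4chr)

  # recombinant intervals (true breakpoints + marker-jittered bounds)
  intervals <- list()
  consub_len <- list()   # per male: named lengths (midpoint convention)
  consub_bounds <- list()
  for (i in seq_len(nrow(males))) {
    id <- males$male_id[i]
    chroms <- scored_of[[id]]
    lens <- stats::setNames(numeric(length(chroms)), chroms)
    bmin <- bmax <- lens
    pcls <- stats::setNames(character(length(chroms)), chroms)
    if (males$cross[i] != "F1") {
      for (ch in chroms) {
        seg <- .draw_interval(len_of[[ch]], config)
        jb <- .jitter_bounds(seg, len_of[[ch]], config$marker_jitter_mb)
        if (!is.null(jb)) {
          iv <- homozygous_intervals(ch, jb[, "start_min_mb"],
                                     jb[, "start_max_mb"],
                                     jb[, "end_min_mb"], jb[, "end_max_mb"])
          rc <- recombinant_chromosome(K[K$chrom == ch, ], iv)
          lens[ch] <- rc$consub_length_mb
          bmin[ch] <- sum(jb[, "end_min_mb"] - jb[, "start_max_mb"])
          bmax[ch] <- sum(jb[, "end_max_mb"] - jb[, "start_min_mb"])
          pcls[ch] <- rc$position_class
          intervals[[length(intervals) + 1L]] <-
            data.frame(male_id = id, chrom = ch,
                       start_min_mb = jb[, "start_min_mb"],
                       start_max_mb = jb[, "start_max_mb"],
                       end_min_mb = jb[, "end_min_mb"],
                       end_max_mb = jb[, "end_max_mb"],
                       stringsAsFactors = FALSE)
        } else {
          pcls[ch] <- "none"
        }
      }
    } else {
      pcls[] <- "none"
    }
    consub_len[[id]] <- lens
    consub_bounds[[id]] <- list(min = bmin, max = bmax, class = pcls)
  }
  intervals <- if (length(intervals)) {
    do.call(rbind, intervals)
  } else {
    data.frame(male_id = character(), chrom = character(),
               start_min_mb = numeric(), start_max_mb = numeric(),
               end_min_mb = numeric(), end_max_mb = numeric())
  }
  rownames(intervals) <- NULL

  # latent per-male intercepts and per-chromosome true rates
  u <- stats::setNames(stats::rnorm(nrow(males), 0, config$sigma_u),
                       males$male_id)
  rate_rows <- list()
  p_all <- stats::setNames(numeric(nrow(males)), males$male_id)
  for (i in seq_len(nrow(males))) {
    id <- males$male_id[i]
    chroms <- scored_of[[id]]
    base <- vapply(chroms, function(ch)
      .true_rate(consub_len[[id]][[ch]], ch, config), numeric(1))
    f1_base <- config$f1_max_asynapsis[chroms]
    rates <- vapply(seq_along(chroms), function(j) {
      others <- base[-j]
      delta <- if (length(others)) mean(others) - mean(f1_base[-j]) else 0
      stats::plogis(stats::qlogis(base[j]) + u[[id]] + config$gamma * delta)
    }, numeric(1))
    names(rates) <- chroms
    p_all[id] <- prod(1 - rates)
    rate_rows[[i]] <- data.frame(male_id = id, chrom = chroms,
                                 consub_length_mb = unname(consub_len[[id]][chroms]),
                                 base_rate = unname(base),
                                 rate = unname(rates),
                                 stringsAsFactors = FALSE)
  }
  rates_df <- do.call(rbind, rate_rows)
  rownames(rates_df) <- NULL

  # pachytene scoring counts; 4-chr males are scored only for a subset chosen
  # to include both sperm-positive and aspermic animals
  sperm <- stats::setNames(numeric(nrow(males)), males$male_id)
  for (id in ids_4chr) {
    sperm[id] <- if (p_all[[id]] < config$tau) 0 else
      round(stats::rlnorm(1, config$sperm_meanlog, config$sperm_sdlog) *
              p_all[[id]], 2)
  }
  pos <- ids_4chr[sperm[ids_4chr] > 0]
  asp <- ids_4chr[sperm[ids_4chr] == 0]
  n_pos <- min(length(pos), ceiling(config$n_scored_males_4chr * 13 / 18))
  n_asp <- min(length(asp), config$n_scored_males_4chr - n_pos)
  scored_4chr <- c(if (n_pos) sample(pos, n_pos),
                   if (n_asp) sample(asp, n_asp))
  scored_ids <- c(f1_ids, ids_2chr, scored_4chr)

  score_rows <- list()
  for (id in scored_ids) {
    chroms <- scored_of[[id]]
    rr <- rates_df[rates_df$male_id == id, ]
    n_sc <- pmax(20L, stats::rpois(length(chroms), config$n_scored_mean))
    n_asyn <- stats::rbinom(length(chroms), n_sc, rr$rate[match(chroms, rr$chrom)])
    cls <- vapply(n_asyn, function(k)
      as.integer(stats::rmultinom(1, k, config$class_split)), integer(3))
    b <- consub_bounds[[id]]
    score_rows[[length(score_rows) + 1L]] <- data.frame(
      male_id = id,
      cross = males$cross[males$male_id == id],
      chrom = chroms,
      consub_length_mb = unname(consub_len[[id]][chroms]),
      consub_length_min_mb = unname(b$min[chroms]),
      consub_length_max_mb = unname(b$max[chroms]),
      position_class = unname(b$class[chroms]),
      n_scored = n_sc,
      n_asynapsed = n_asyn,
      n_complete = cls[1, ],
      n_partial = cls[2, ],
      n_intermingled = cls[3, ],
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL

  fertility <- data.frame(
    male_id = ids_4chr,
    cross = "4chr",
    sperm_million = unname(sperm[ids_4chr]),
    testis_weight_mg = round(50 + 100 * unname(p_all[ids_4chr]) +
                               stats::rnorm(length(ids_4chr), 0, 8), 1),
    stringsAsFactors = FALSE)

  truth <- list(
    seed = config$seed,
    psi_true_mb = config$psi_true_mb,
    sigma_u = config$sigma_u,
    gamma = config$gamma,
    asyn_floor = config$asyn_floor,
    tau = config$tau,
    f1_max_asynapsis = as.list(config$f1_max_asynapsis),
    slope_below = as.list(config$slope_below),
    animal_intercepts = as.list(u),
    p_all_synapsed = as.list(p_all),
    rates = rates_df,
    scored_4chr = scored_4chr
  )
  structure(list(karyotype = K, intervals = intervals, scores = scores,
                 fertility = fertility, truth = truth, config = config),
            class = "synthetic_cross_data")
}

#' @export
print.synthetic_cross_data <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cross dataset (seed %d): %d scored males, ",
                     "%d score rows, %d fertility records\n"),
              x$config$seed, length(unique(x$scores$male_id)),
              nrow(x$scores), nrow(x$fertility)))
  invisible(x)
}
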