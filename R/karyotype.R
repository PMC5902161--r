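#' Construct a karyotype of autosomes
#'
#' A karyotype holds the autosome labels, their physical lengths (Mb) and the
#' per-autosome share of total SPO11-oligo counts, which acts as the DSB
#' allocation weight in the symmetric-DSB simulator. Mouse meiotic DSB totals
#' are modelled per cell across autosomes only; the X chromosome is excluded
#' throughout.
#'
#' @param name character vector of autosome labels ("1".."19" for mouse).
#' @param length_mb positive physical lengths in megabases.
#' @param spo11_count nonnegative SPO11-oligo counts (any scale); normalised
#'   internally to shares summing to one.
#' @param f1_asynapsis_rate optional baseline asynapsis proportion of each
#'   autosome in nonrecombinant F1 hybrids, in \[0, 1\].
#' @return A data frame of class `"karyotype"` with columns `chrom`,
#'   `length_mb`, `spo11_share` and (optionally) `f1_asynapsis_rate`, ordered
#'   by chromosome label (numerically where labels are numeric).
#' @export
karyotype <- function(name, length_mb, spo11_count,
                      f1_asynapsis_rate = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (length(length_mb) != length(name) || length(spo11_count) != length(name)) {
    stop("name, length_mb and spo11_count must have equal length")
  }
  if (any(!is.finite(length_mb)) || any(length_mb <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (any(!is.finite(spo11_count)) || any(spo11_count < 0)) {
    stop("SPO11 counts must be nonnegative")
  }
  if (sum(spo11_count) <= 0) {
    stop("at least one SPO11 count must be positive")
  }
  k <- data.frame(
    chrom = name,
    length_mb = as.numeric(length_mb),
    spo11_share = spo11_count / sum(spo11_count),
    stringsAsFactors = FALSE
  )
  if (!is.null(f1_asynapsis_rate)) {
    if (any(f1_asynapsis_rate < 0 | f1_asynapsis_rate > 1, na.rm = TRUE)) {
      stop("f1_asynapsis_rate must lie in [0, 1]")
    }
    k$f1_asynapsis_rate <- as.numeric(f1_asynapsis_rate)
  }
  # numeric labels sort numerically ("2" before "10")
  num <- suppressWarnings(as.numeric(k$chrom))
  ord <- if (anyNA(num)) order(k$chrom) else order(num)
  k <- k[ord, , drop = FALSE]
  rownames(k) <- NULL
  class(k) <- c("karyotype", "data.frame")
  k
}

#' Load a karyotype from a tab-separated table
#'
#' Expects columns `chrom`, `length_mb`, `spo11_count` and optionally
#' `f1_asynapsis_rate`.
#'
#' @param path path to a TSV file, or a data frame with the same columns.
#' @return A [karyotype()] object.
#' @export
load_karyotype <- function(path) {
  tab <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("chrom", "length_mb", "spo11_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("karyotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  karyotype(tab$chrom, tab$length_mb, tab$spo11_count,
            f1_asynapsis_rate = tab[["f1_asynapsis_rate"]])
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Karyotype: %d autosomes, %.0f Mb total\n",
              nrow(x), sum(x$length_mb)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Marker-bounded homozygous (consubspecific) intervals
#'
#' Recombinant chromosomes carry stretches where both homologs derive from the
#' same subspecies. Breakpoints are localised only between flanking genotyped
#' markers, so each boundary is carried as a (min, max) pair; lengths are
#' resolved by the midpoint convention. Coordinates are megabase positions on
#' the chromosome, treated internally as half-open intervals so that abutting
#' intervals do not overlap.
#'
#' @param chrom chromosome label (recycled).
#' @param start_min_mb,start_max_mb,end_min_mb,end_max_mb marker bounds, Mb.
#' @return data frame of class `"homozygous_intervals"`.
#' @export
homozygous_intervals <- function(chrom, start_min_mb, start_max_mb,
                                 end_min_mb, end_max_mb) {
  d <- data.frame(chrom = as.character(chrom),
                  start_min_mb = as.numeric(start_min_mb),
                  start_max_mb = as.numeric(start_max_mb),
                  end_min_mb = as.numeric(end_min_mb),
                  end_max_mb = as.numeric(end_max_mb),
                  stringsAsFactors = FALSE)
  bad <- with(d, start_min_mb < 0 | start_min_mb > start_max_mb |
                start_max_mb > end_min_mb | end_min_mb > end_max_mb)
  if (any(bad)) {
    stop("interval bounds must satisfy 0 <= start_min <= start_max <= ",
         "end_min <= end_max (row ", which(bad)[1], ")")
  }
  class(d) <- c("homozygous_intervals", "data.frame")
  d
}

#' A recombinant chromosome: consubspecific intervals on one autosome
#'
#' @param chrom_spec one row of a [karyotype()] (or a list with `chrom` and
#'   `length_mb`).
#' @param intervals a [homozygous_intervals()] frame for this chromosome; may
#'   have zero rows.
#' @return list of class `"recombinant_chromosome"` with the resolved
#'   consubspecific length, homozygous fraction and position class.
#' @export
recombinant_chromosome <- function(chrom_spec, intervals = NULL) {
  len <- chrom_spec$length_mb
  lab <- as.character(chrom_spec$chrom)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- homozygous_intervals(character(), numeric(), numeric(),
                                      numeric(), numeric())
  } else {
    if (!all(intervals$chrom == lab)) {
      stop("intervals refer to a different chromosome than ", lab)
    }
    if (any(intervals$end_max_mb > len + 1e-9)) {
      stop("interval coordinates exceed chromosome length on ", lab)
    }
  }
  sm <- (intervals$start_min_mb + intervals$start_max_mb) / 2
  em <- (intervals$end_min_mb + intervals$end_max_mb) / 2
  if (nrow(intervals) > 1L) {
    o <- order(sm)
    sm <- sm[o]; em <- em[o]
    intervals <- intervals[o, , drop = FALSE]
    if (any(sm[-1] < em[-length(em)] - 1e-9)) {
      stop("intervals overlap after midpoint resolution on ", lab)
    }
  }
  consub <- sum(em - sm)
  rc <- list(
    chrom = lab,
    length_mb = len,
    intervals = intervals,
    start_mid_mb = sm,
    end_mid_mb = em,
    consub_length_mb = consub,
    f_homo = consub / len,
    position_class = .position_class(sm, em, len, consub / len)
  )
  class(rc) <- "recombinant_chromosome"
  rc
}

# proximal: an interval starts (midpoint) within the first 10% of the
# chromosome; distal: one ends within the last 10%; both_ends when both occur;
# whole when the homozygous fraction is ~1; none when there is no interval.
.position_class <- function(start_mid, end_mid, length_mb, f_homo) {
  if (length(start_mid) == 0L) return("none")
  if (f_homo >= 1 - 1e-9) return("whole")
  prox <- any(start_mid < 0.10 * length_mb)
  dist <- any(end_mid > 0.90 * length_mb)
  if (prox && dist) "both_ends"
  else if (prox) "proximal"
  else if (dist) "distal"
  else "interstitial"
}

#' Summarise a recombinant chromosome
#'
#' @param rc a [recombinant_chromosome()].
#' @return list with `consub_length_mb` (midpoint-convention total length of
#'   consubspecific sequence), `f_homo` (fraction of the chromosome that is
#'   consubspecific) and `position_class`.
#' @export
summarize_recombinant <- function(rc) {
  stopifnot(inherits(rc, "recombinant_chromosome"))
  list(consub_length_mb = rc$consub_length_mb,
       f_homo = rc$f_homo,
       position_class = rc$position_class)
}

#' @export
print.recombinant_chromosome <- function(x, ...) {
  cat(sprintf("Chr %s (%.1f Mb): %.2f Mb consubspecific (f_homo = %.3f, %s)\n",
              x$chrom, x$length_mb, x$consub_length_mb, x$f_homo,
              x$position_class))
  invisible(x)
}
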