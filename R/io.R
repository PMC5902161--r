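#' Analysis configuration
#'
#' Collects input paths, simulator and segmented-fit settings, and the two
#' biological thresholds used downstream: the asynapsis baseline below which a
#' chromosome counts as rescued (default 5 percent) and the full-synapsis
#' probability above which spermatogenesis is expected to proceed (default
#' 0.7).
#'
#' @param karyotype,scores,intervals,fertility input table paths (TSV for the
#'   karyotype, CSV otherwise); any may be `NULL` when a subcommand does not
#'   need it.
#' @param dsb_params list of arguments for [dsb_sim_params()].
#' @param segmented list of arguments for [segmented_options()].
#' @param generator list of arguments for [generator_config()] (used by the
#'   `synth-generate` subcommand).
#' @param baseline_asynapsis rescue baseline, in (0, 1).
#' @param synapsis_threshold fertility rule-of-thumb threshold, in (0, 1).
#' @param out_dir output directory for reports.
#' @param seed integer seed applied to every stochastic stage.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(karyotype = NULL, scores = NULL, intervals = NULL,
                            fertility = NULL, dsb_params = list(),
                            segmented = list(), generator = list(),
                            baseline_asynapsis = 0.05,
                            synapsis_threshold = 0.7,
                            out_dir = "synapsim_out", seed = 1L) {
  stopifnot(baseline_asynapsis > 0, baseline_asynapsis < 1,
            synapsis_threshold > 0, synapsis_threshold < 1)
  structure(list(karyotype = karyotype, scores = scores,
                 intervals = intervals, fertility = fertility,
                 dsb_params = dsb_params, segmented = segmented,
                 generator = generator,
                 baseline_asynapsis = baseline_asynapsis,
                 synapsis_threshold = synapsis_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' @param path configuration file; format decided by extension (`.yml`/`.yaml`
#'   vs `.json`).
#' @return an [analysis_config()].
#' @export
load_analysis_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(analysis_config, raw)
}

# aggregate row-level validation failures, citing 1-based file lines
# (line 1 is the header, so data row i is file line i + 1)
.validate_rows <- function(df, checks, file) {
  msgs <- character(0)
  for (ck in checks) {
    bad <- which(ck$fails(df))
    if (length(bad)) {
      msgs <- c(msgs, sprintf("%s: line %d: %s", file, bad + 1L, ck$msg))
    }
  }
  if (length(msgs)) stop(paste(msgs, collapse = "\n"), call. = FALSE)
  invisible(df)
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(file, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a pachytene scoring table (CSV)
#'
#' @param path CSV with columns `male_id`, `chrom`, `n_scored`, `n_asynapsed`
#'   and optionally `cross`, `consub_length_mb` (or min/max bounds),
#'   `position_class` and per-class counts.
#' @return validated data frame.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("male_id", "chrom", "n_scored", "n_asynapsed"), path)
  df$chrom <- as.character(df$chrom)
  .validate_rows(df, list(
    list(fails = function(d) d$n_scored < 1,
         msg = "n_scored must be at least 1"),
    list(fails = function(d) d$n_asynapsed < 0 | d$n_asynapsed > d$n_scored,
         msg = "n_asynapsed must lie in [0, n_scored]")
  ), path)
}

#' Read a recombinant-interval table (CSV)
#'
#' @param path CSV with columns `male_id`, `chrom`, `start_min_mb`,
#'   `start_max_mb`, `end_min_mb`, `end_max_mb`.
#' @return validated data frame.
#' @export
read_intervals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("male_id", "chrom", "start_min_mb", "start_max_mb",
                      "end_min_mb", "end_max_mb"), path)
  df$chrom <- as.character(df$chrom)
  .validate_rows(df, list(
    list(fails = function(d) d$start_min_mb < 0,
         msg = "start_min_mb must be nonnegative"),
    list(fails = function(d) d$start_min_mb > d$start_max_mb |
           d$start_max_mb > d$end_min_mb | d$end_min_mb > d$end_max_mb,
         msg = "bounds must satisfy start_min <= start_max <= end_min <= end_max")
  ), path)
}

#' Read a fertility table (CSV)
#'
#' @param path CSV with columns `male_id`, `sperm_million` and optionally
#'   `cross`, `testis_weight_mg`.
#' @return validated data frame.
#' @export
read_fertility_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("male_id", "sperm_million"), path)
  .validate_rows(df, list(
    list(fails = function(d) d$sperm_million < 0,
         msg = "sperm_million must be nonnegative")
  ), path)
}

#' Read and cross-validate all configured tables
#'
#' @param config an [analysis_config()].
#' @return list with whichever of `karyotype`, `scores`, `intervals`,
#'   `fertility` are configured, after validation (including unknown
#'   chromosome labels against the karyotype).
#' @export
read_tables <- function(config) {
  out <- list()
  if (!is.null(config$karyotype)) out$karyotype <- load_karyotype(config$karyotype)
  if (!is.null(config$scores)) out$scores <- read_scores_csv(config$scores)
  if (!is.null(config$intervals)) out$intervals <- read_intervals_csv(config$intervals)
  if (!is.null(config$fertility)) out$fertility <- read_fertility_csv(config$fertility)
  if (!is.null(out$karyotype)) {
    for (nm in c("scores", "intervals")) {
      if (is.null(out[[nm]])) next
      unknown <- setdiff(unique(out[[nm]]$chrom), out$karyotype$chrom)
      if (length(unknown)) {
        stop(nm, ": unknown chromosome label(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' @param dataset a `"synthetic_cross_data"` from [generate_cross_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cross_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_cross_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    karyotype = file.path(dir, "karyotype.tsv"),
    intervals = file.path(dir, "intervals.csv"),
    scores = file.path(dir, "scores.csv"),
    fertility = file.path(dir, "fertility.csv"),
    truth = file.path(dir, "truth.json")
  )
  k <- dataset$karyotype
  k$spo11_count <- k$spo11_share
  utils::write.table(k[c("chrom", "length_mb", "spo11_count")],
                     paths["karyotype"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(dataset$intervals, paths["intervals"], row.names = FALSE)
  utils::write.csv(dataset$scores, paths["scores"], row.names = FALSE)
  utils::write.csv(dataset$fertility, paths["fertility"], row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(paths)
}

#' Build a mixed-logit formula from a declarative model block
#'
#' The block (typically parsed from YAML or JSON) names the response count
#' columns, the fixed-effect columns and the animal grouping column.
#'
#' @param spec list with `response = c(successes, trials)`, `fixed` (character
#'   vector, possibly empty for an intercept-only model) and `group`.
#' @return list with `formula` and `group`, ready for [fit_mixed_logit()].
#' @export
mixed_logit_spec <- function(spec) {
  stopifnot(length(spec$response) == 2, !is.null(spec$group))
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  f <- stats::as.formula(sprintf("cbind(%s, %s - %s) ~ %s",
                                 spec$response[1], spec$response[2],
                                 spec$response[1], rhs))
  list(formula = f, group = spec$group)
}

.provenance <- function(config) {
  list(tool = "synapsim",
       version = as.character(utils::packageVersion("synapsim")),
       seed = config$seed,
       config = config[setdiff(names(config), "karyotype")])
}

.emit_json <- function(results, name, config, quiet) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir, paste0(name, ".json"))
  payload <- c(.provenance(config), list(results = results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  if (!quiet) message("wrote ", path)
  path
}

.emit_tsv <- function(df, name, config, quiet) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!quiet) message("wrote ", path)
  path
}

# plain-list report of a segmented fit (JSON-friendly)
.segfit_report <- function(fit, ci = NULL) {
  list(breakpoint_mb = fit$breakpoint_mb,
       breakpoint_ci = if (!is.null(ci)) as.list(stats::setNames(ci, c("low", "high"))),
       intercepts = as.list(fit$intercepts),
       slopes_below = as.list(fit$slopes_below),
       slope_change = as.list(fit$slope_change),
       slopes_above = as.list(fit$slopes_above),
       residual_ss = fit$residual_ss,
       n_obs = fit$n_obs,
       converged = fit$converged)
}

#' Run a pipeline stage
#'
#' Subcommands: `synth-generate` (write a synthetic dataset into `out_dir`),
#' `simulate-dsb` (per-chromosome symmetric-DSB pmf under the F1
#' configuration), `infer-threshold` (threshold scan of F1 asynapsis rates
#' against simulated probabilities), `fit-segmented` (change-point fit of the
#' recombinant-cross scores), `cross-analysis` (rate tables, full-synapsis
#' expectations, fertility summary, sperm-vs-synapsis test), `trans-effect`
#' (log-log elasticity on the 4-chr scores), and `report` (all of the above).
#' Every stage writes a JSON report embedding the tool version, resolved
#' configuration and seed, plus TSV tables where tabular output is natural.
#'
#' @param config an [analysis_config()].
#' @param subcommand one of the stage names above.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config,
                         subcommand = c("report", "synth-generate",
                                        "simulate-dsb", "infer-threshold",
                                        "fit-segmented", "cross-analysis",
                                        "trans-effect"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  subcommand <- match.arg(subcommand)
  results <- list()

  if (subcommand == "synth-generate") {
    gen_args <- config$generator
    if (is.null(gen_args$seed)) gen_args$seed <- config$seed
    ds <- generate_cross_dataset(do.call(generator_config, gen_args))
    paths <- write_cross_dataset(ds, config$out_dir)
    .emit_json(list(files = as.list(paths)), "synth_generate", config, quiet)
    return(invisible(list(dataset = ds, paths = paths)))
  }

  tabs <- read_tables(config)
  run_all <- subcommand == "report"

  if (run_all || subcommand == "simulate-dsb") {
    if (is.null(tabs$karyotype)) stop("simulate-dsb requires a karyotype")
    params <- do.call(dsb_sim_params, c(config$dsb_params,
                                        if (is.null(config$dsb_params$seed))
                                          list(seed = config$seed)))
    dists <- simulate_symmetric_pmf(tabs$karyotype, NULL, params)
    results$dsb <- dists
    .emit_tsv(dsb_pmf_table(dists), "dsb_pmf", config, quiet)
    .emit_json(list(params = unclass(params),
                    mean_symmetric = vapply(dists, function(d) {
                      k <- length(d$pmf) - 1L
                      sum((0:k) * d$pmf)  # tail treated as k_max + 1
                    }, numeric(1))),
               "dsb_summary", config, quiet)
  }

  if (run_all || subcommand == "infer-threshold") {
    if (is.null(tabs$karyotype) || is.null(tabs$scores)) {
      stop("infer-threshold requires a karyotype and scores")
    }
    f1 <- if ("cross" %in% names(tabs$scores)) {
      tabs$scores[tabs$scores$cross == "F1", ]
    } else {
      tabs$scores
    }
    if (nrow(f1) == 0) stop("infer-threshold: no F1 rows in scores")
    rates <- asynapsis_rate_table(f1)$pooled
    asyn <- stats::setNames(rates$rate, rates$chrom)
    params <- do.call(dsb_sim_params, c(config$dsb_params,
                                        if (is.null(config$dsb_params$seed))
                                          list(seed = config$seed)))
    kar <- tabs$karyotype[tabs$karyotype$chrom %in% names(asyn), ]
    class(kar) <- class(tabs$karyotype)
    kar$spo11_share <- kar$spo11_share / sum(kar$spo11_share)
    dists <- simulate_symmetric_pmf(kar, NULL, params)
    scan <- infer_threshold_k(asyn, dists)
    results$threshold <- scan
    .emit_tsv(scan$table, "threshold_scan", config, quiet)
    .emit_json(list(selected_k = scan$selected_k,
                    slope_at_selected = scan$slope_at_selected,
                    table = scan$table),
               "threshold_verdict", config, quiet)
  }

  if (run_all || subcommand == "fit-segmented") {
    if (is.null(tabs$scores)) stop("fit-segmented requires scores")
    seg_rows <- if ("cross" %in% names(tabs$scores)) {
      tabs$scores[tabs$scores$cross != "F1", ]
    } else {
      tabs$scores
    }
    if (nrow(seg_rows) < 6) stop("fit-segmented: too few recombinant rows")
    opts <- do.call(segmented_options, c(config$segmented,
                                         if (is.null(config$segmented$seed))
                                           list(seed = config$seed)))
    fit <- fit_segmented(seg_rows, opts)
    ci <- breakpoint_ci(fit, opts)
    results$segmented <- fit
    results$segmented_ci <- ci
    xs <- seq(0, max(seg_rows$consub_length_mb), length.out = 200)
    curve <- data.frame(consub_length_mb = xs,
                        fitted_rate = predict(fit, data.frame(
                          consub_length_mb = xs,
                          chrom = names(fit$intercepts)[1])))
    .emit_tsv(curve, "segmented_curve", config, quiet)
    .emit_json(.segfit_report(fit, ci), "segmented_fit", config, quiet)
  }

  if (run_all || subcommand == "cross-analysis") {
    if (is.null(tabs$scores)) stop("cross-analysis requires scores")
    rt <- asynapsis_rate_table(tabs$scores)
    results$rates <- rt
    .emit_tsv(rt$pooled, "asynapsis_rates", config, quiet)
    out <- list()
    if ("cross" %in% names(tabs$scores) &&
        any(tabs$scores$cross == "F1")) {
      f1 <- asynapsis_rate_table(tabs$scores[tabs$scores$cross == "F1", ])$pooled
      syn <- stats::setNames(1 - f1$rate, f1$chrom)
      out$expected_full_synapsis_f1 <- expected_full_synapsis(syn)
    }
    if (!is.null(tabs$fertility)) {
      fs <- fertility_summary(tabs$fertility)
      out$fertility <- fs
      .emit_tsv(fs, "fertility_summary", config, quiet)
      scored <- intersect(tabs$fertility$male_id, tabs$scores$male_id)
      if (length(scored) >= 4) {
        sub <- tabs$scores[tabs$scores$male_id %in% scored, ]
        p_all <- vapply(scored, function(m) {
          r <- sub[sub$male_id == m, ]
          prod(1 - r$n_asynapsed / r$n_scored)
        }, numeric(1))
        names(p_all) <- scored
        sv <- sperm_presence_vs_synapsis(
          tabs$fertility[tabs$fertility$male_id %in% scored, ],
          p_all, config$synapsis_threshold)
        out$sperm_vs_synapsis <- list(
          degenerate = sv$degenerate,
          U = if (!sv$degenerate) sv$test$U,
          p_value = if (!sv$degenerate) sv$test$p_value,
          frac_above_threshold = if (!sv$degenerate)
            as.list(sv$frac_above_threshold))
        results$sperm_vs_synapsis <- sv
      }
    }
    results$cross_summary <- out
    .emit_json(out, "cross_analysis", config, quiet)
  }

  if (run_all || subcommand == "trans-effect") {
    if (is.null(tabs$scores)) stop("trans-effect requires scores")
    rows <- if ("cross" %in% names(tabs$scores)) {
      tabs$scores[tabs$scores$cross == "4chr", ]
    } else {
      tabs$scores
    }
    if (nrow(rows) == 0) stop("trans-effect: no 4-chr rows in scores")
    te <- trans_effect_loglog(rows)
    results$trans_effect <- te
    .emit_json(list(loglog_slope = te$loglog_slope,
                    ci = as.list(stats::setNames(te$ci, c("low", "high"))),
                    pct_change_per_10pct = te$pct_change_per_10pct,
                    p_value = te$p_value,
                    per_chromosome = te$per_chromosome),
               "trans_effect", config, quiet)
  }

  invisible(results)
}
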