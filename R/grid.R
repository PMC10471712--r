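#' Aggregate a cycle log over replicates
#'
#' @param log a `cycle_log` / `rrgs_sim` data frame with a `rep` column.
#' @return Data frame of mean and standard deviation of every tracked
#'   statistic per (method, t, s).
#' @export
aggregate_cycle_log <- function(log) {
  metrics <- setdiff(names(log), c("rep", "method", "t", "s", "scenario",
                                   "reml_converged"))
  key <- log[, intersect(c("method", "t", "s"), names(log))]
  mean_df <- aggregate(log[metrics], key, function(v) mean(v, na.rm = TRUE))
  sd_df <- aggregate(log[metrics], key, function(v)
    if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_)
  names(sd_df)[match(metrics, names(sd_df))] <- paste0(metrics, "_sd")
  out <- merge(mean_df, sd_df, by = intersect(c("method", "t", "s"),
                                              names(log)), sort = FALSE)
  out[order(out$method, out$t, out$s), ]
}

#' Run a grid of RRGS scenarios
#'
#' Executes each scenario configuration with the given replicate count. The
#' replicate seeds are `seed + replicate - 1`, shared across scenarios and
#' methods (paired comparisons). When an output directory is given, one raw
#' log per scenario is written as a tab-separated file and scenarios with an
#' existing output file are skipped (resumable); a failing scenario is
#' recorded and the grid continues.
#'
#' @param scenarios named list of [rrgs_config] objects.
#' @param replicates replicates per scenario.
#' @param seed master seed.
#' @param out_dir optional output directory for raw and aggregated logs.
#' @param verbose print progress.
#' @return Named list with `raw` (per-scenario cycle logs, long format with a
#'   `scenario` column) and `aggregate` (per-scenario aggregates); failed
#'   scenarios carry the error message instead of a log.
#' @export
run_grid <- function(scenarios, replicates = 2, seed = 1, out_dir = NULL,
                     verbose = FALSE) {
  stopifnot(is.list(scenarios), length(names(scenarios)) == length(scenarios))
  raw <- list(); agg <- list()
  for (nm in names(scenarios)) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(nm, "_raw.tsv"))
      if (file.exists(path)) {
        if (verbose) message("skipping existing scenario: ", nm)
        raw[[nm]] <- read.table(path, header = TRUE, sep = "\t")
        agg[[nm]] <- aggregate_cycle_log(raw[[nm]])
        next
      }
    }
    res <- tryCatch({
      lg <- run_rrgs(scenarios[[nm]], replicates = replicates, seed = seed,
                     verbose = verbose)
      lg$scenario <- nm
      lg
    }, error = function(e) e)
    if (inherits(res, "error")) {
      raw[[nm]] <- conditionMessage(res)
      warning("scenario ", nm, " failed: ", conditionMessage(res))
      next
    }
    raw[[nm]] <- res
    agg[[nm]] <- aggregate_cycle_log(res)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(res, file.path(out_dir, paste0(nm, "_raw.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(agg[[nm]], file.path(out_dir, paste0(nm, "_aggregate.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(raw = raw, aggregate = agg)
}

#' Compare the two breeding methods within one scenario
#'
#' @param log a `cycle_log` containing both methods with paired replicates.
#' @return Data frame per (t, s): mean cumulative gain of each method, the
#'   percent difference 100 * (FS - HS) / HS, the paired standard error of
#'   the FS - HS difference, and the fraction of replicates in which FS beat
#'   HS.
#' @export
compare_methods <- function(log) {
  stopifnot(all(c("HS", "FS") %in% log$method))
  hs <- log[log$method == "HS", c("rep", "t", "s", "sum_dg")]
  fs <- log[log$method == "FS", c("rep", "t", "s", "sum_dg")]
  m <- merge(hs, fs, by = c("rep", "t", "s"), suffixes = c("_hs", "_fs"))
  agg <- aggregate(cbind(sum_dg_hs, sum_dg_fs) ~ t + s, m, mean)
  d <- m$sum_dg_fs - m$sum_dg_hs
  se <- aggregate(d ~ m$t + m$s, data.frame(d = d), function(v)
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  names(se) <- c("t", "s", "paired_se")
  frac <- aggregate(d > 0 ~ m$t + m$s, data.frame(d = d), mean)
  names(frac) <- c("t", "s", "frac_fs_better")
  out <- merge(merge(agg, se, by = c("t", "s")), frac, by = c("t", "s"))
  out$pct_diff <- ifelse(abs(out$sum_dg_hs) > 1e-12,
                         100 * (out$sum_dg_fs - out$sum_dg_hs) /
                           abs(out$sum_dg_hs), NA_real_)
  out[order(out$t, out$s), ]
}

#' Write a cycle log in long (tidy) format
#'
#' One row per (replicate, method, t, s, metric, value).
#'
#' @param log a `cycle_log`.
#' @param path output path (tab-separated).
#' @export
write_cycle_log <- function(log, path) {
  metrics <- setdiff(names(log), c("rep", "method", "scenario", "t", "s"))
  id <- intersect(c("rep", "method", "scenario", "t", "s"), names(log))
  long <- do.call(rbind, lapply(metrics, function(mt) {
    cbind(log[id], data.frame(metric = mt, value = as.numeric(log[[mt]])))
  }))
  long <- long[order(long$rep, long$method, long$t, long$s), ]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
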