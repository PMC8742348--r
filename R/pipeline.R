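#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit hash of (master seed, stage name, item index), so
#' every stochastic stage of a pipeline run has its own reproducible seed
#' independent of execution order.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @param index item index within the stage (default 0).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  h <- (h * 31 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

fit_params_row <- function(condition, cell, fr) {
  p <- fr$params
  data.frame(condition = condition, cell = cell,
             N = p$N, f_D = p$f_D, f_short = p$f_short, f_long = p$f_long,
             tau_D = p$tau_D, tau_short = p$tau_short, tau_long = p$tau_long,
             k_off_short = fr$k_off_short, k_off_long = fr$k_off_long,
             se_N = fr$se[["N"]], se_f_D = fr$se[["f_D"]],
             se_f_short = fr$se[["f_short"]], se_f_long = fr$se[["f_long"]],
             se_tau_D = fr$se[["tau_D"]], se_tau_short = fr$se[["tau_short"]],
             se_tau_long = fr$se[["tau_long"]],
             rss = fr$rss, converged = fr$converged,
             stringsAsFactors = FALSE)
}

comparison_row <- function(cmp, metric) {
  data.frame(group1 = cmp$pair[1], group2 = cmp$pair[2], metric = metric,
             delta = cmp$delta, z = cmp$z, p = cmp$p_value,
             significant = cmp$significant, stringsAsFactors = FALSE)
}

compare_vs_control <- function(table, metrics, control, mode, alpha,
                               n_boot, master_seed, group_column = "condition") {
  comparisons <- list()
  for (metric in metrics) {
    stats <- summarize_groups(table, metric, group_column, mode = mode,
                              n_boot = n_boot,
                              seed = derive_seed(master_seed, paste0("summ_", metric)))
    for (g in setdiff(names(stats), control)) {
      cmp <- median_test(stats[[g]], stats[[control]], alpha = alpha)
      comparisons[[length(comparisons) + 1]] <- comparison_row(cmp, metric)
    }
  }
  do.call(rbind, comparisons)
}

#' Run the FCS analysis pipeline
#'
#' For every cell of every condition: autocorrelate the photon trace
#' ([autocorrelate]) and fit the diffusion + two-binding-population model
#' ([fit_acf]); one measurement per cell. Per-condition summaries
#' ([summarize_groups]) and treatment-versus-control comparisons
#' ([median_test]) are then computed for every fitted parameter. Unfittable
#' cells are excluded with a recorded reason, never silently dropped.
#'
#' @param conditions named list; each element is a list of cells, where a
#'   cell is an [intensity_trace], a [trace_sim_config] (simulated on the
#'   fly with a seed derived from `master_seed`), or a pre-computed
#'   [correlation_curve].
#' @param control name of the control condition (present in `conditions`).
#' @param master_seed integer; every stochastic stage derives its seed from
#'   it (see [derive_seed]).
#' @param correlator list of [autocorrelate] options (`m`, `ratio`,
#'   `max_lag`).
#' @param fit list of [fit_acf] options (`omega`, `components`, ...).
#' @param alpha significance level for the comparisons (default 0.01, the
#'   convention for the FCS parameters).
#' @param summary_mode `"mean"` (default for FCS parameters) or `"median"`.
#' @param n_boot bootstrap replicates for group summaries.
#' @param out_dir optional directory; per-cell table, comparisons and a JSON
#'   report are written there.
#' @return List: `table` (per-cell parameter data.frame), `comparisons`
#'   (data.frame), `summaries` (list of [group_stats] per metric),
#'   `excluded` (data.frame of dropped cells and reasons).
#' @export
run_fcs_pipeline <- function(conditions, control, master_seed = 1L,
                             correlator = list(), fit = list(),
                             alpha = 0.01, summary_mode = "mean",
                             n_boot = 1000L, out_dir = NULL) {
  stopifnot(is.list(conditions), !is.null(names(conditions)),
            control %in% names(conditions))
  rows <- list()
  excluded <- list()
  for (cond in names(conditions)) {
    cells <- conditions[[cond]]
    for (i in seq_along(cells)) {
      cell_id <- sprintf("%s_%02d", cond, i)
      item <- cells[[i]]
      res <- tryCatch({
        if (inherits(item, "trace_sim_config")) {
          item$seed <- derive_seed(master_seed, paste0("trace_", cond), i)
          item <- simulate_trace(item)$trace
        }
        curve <- if (inherits(item, "correlation_curve")) item
          else do.call(autocorrelate, c(list(item), correlator))
        do.call(fit_acf, c(list(curve), fit))
      }, error = function(e) e)
      if (inherits(res, "error") || !isTRUE(res$converged)) {
        reason <- if (inherits(res, "error")) conditionMessage(res)
                  else "fit did not converge"
        message("excluding ", cell_id, ": ", reason)
        excluded[[length(excluded) + 1]] <-
          data.frame(condition = cond, cell = cell_id, reason = reason)
        next
      }
      rows[[length(rows) + 1]] <- fit_params_row(cond, cell_id, res)
    }
  }
  if (length(rows) == 0) stop("no cell could be fitted")
  table <- do.call(rbind, rows)
  metrics <- c("N", "f_D", "f_short", "f_long", "tau_D", "tau_short", "tau_long")
  comparisons <- compare_vs_control(table, metrics, control, summary_mode,
                                    alpha, n_boot, master_seed)
  excluded <- if (length(excluded)) do.call(rbind, excluded)
    else data.frame(condition = character(), cell = character(),
                    reason = character())
  out <- list(table = table, comparisons = comparisons, excluded = excluded)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, "fcs", master_seed)
  out
}

#' Run the 3D morphometry pipeline
#'
#' For every stack of every condition: denoise ([denoise]), segment
#' ([segment_nuclei]), and measure ([measure]). Per-nucleus records are
#' pooled per condition; border-flagged (truncated) nuclei are kept in the
#' table but excluded from statistics. Volume and sphericity are compared
#' treatment-versus-control with the bootstrap median test, and the
#' cube-root radius increment ([radius_increment]) of the median volume is
#' reported for every treated condition.
#'
#' @param conditions named list; each element is a list of stacks, where a
#'   stack is a [nucleus_image] or a [nucleus_shape_spec] (generated on the
#'   fly with a derived seed).
#' @param control name of the control condition.
#' @param master_seed integer master seed.
#' @param denoise_opts list of [denoise] options.
#' @param segmentation list of [segment_nuclei] options.
#' @param alpha significance level (default 0.05, the morphometry
#'   convention).
#' @param n_boot bootstrap replicates.
#' @param out_dir optional output directory.
#' @return List: `table` (per-nucleus data.frame), `comparisons`,
#'   `radius_increments` (data.frame per treated condition), `skipped`
#'   (stacks with no segmentable nuclei).
#' @export
run_morphometry_pipeline <- function(conditions, control, master_seed = 1L,
                                     denoise_opts = list(),
                                     segmentation = list(),
                                     alpha = 0.05, n_boot = 1000L,
                                     out_dir = NULL) {
  stopifnot(is.list(conditions), !is.null(names(conditions)),
            control %in% names(conditions))
  rows <- list()
  skipped <- list()
  for (cond in names(conditions)) {
    stacks <- conditions[[cond]]
    for (i in seq_along(stacks)) {
      stack_id <- sprintf("%s_%02d", cond, i)
      item <- stacks[[i]]
      rec <- tryCatch({
        if (inherits(item, "nucleus_shape_spec")) {
          item$seed <- derive_seed(master_seed, paste0("nucleus_", cond), i)
          item <- generate_nucleus_image(item)$image
        }
        img <- do.call(denoise, c(list(item), denoise_opts))
        msk <- do.call(segment_nuclei, c(list(img), segmentation))
        measure(msk)
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        message("skipping ", stack_id, ": ", conditionMessage(rec))
        skipped[[length(skipped) + 1]] <-
          data.frame(condition = cond, stack = stack_id,
                     reason = conditionMessage(rec))
        next
      }
      rec$condition <- cond
      rec$stack <- stack_id
      rows[[length(rows) + 1]] <- rec
    }
  }
  if (length(rows) == 0) stop("no stack produced segmentable nuclei")
  table <- do.call(rbind, rows)
  stats_table <- table[!table$border_flag, , drop = FALSE]
  comparisons <- compare_vs_control(stats_table,
                                    c("volume_um3", "sphericity"),
                                    control, "median", alpha, n_boot,
                                    master_seed)
  med_vol <- vapply(split(stats_table$volume_um3, stats_table$condition),
                    median, 0)
  treated <- setdiff(names(med_vol), control)
  radius_increments <- data.frame(
    condition = treated,
    radius_increment_pct = radius_increment(med_vol[[control]],
                                            unname(med_vol[treated])))
  skipped <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(condition = character(), stack = character(),
                    reason = character())
  out <- list(table = table, comparisons = comparisons,
              radius_increments = radius_increments, skipped = skipped)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, "morpho", master_seed)
  out
}

write_pipeline_outputs <- function(out, out_dir, prefix, master_seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$table, file.path(out_dir, paste0(prefix, "_table.csv")),
            row.names = FALSE)
  write.csv(out$comparisons,
            file.path(out_dir, paste0(prefix, "_comparisons.csv")),
            row.names = FALSE)
  report <- list(pipeline = prefix, master_seed = master_seed,
                 package_version = as.character(utils::packageVersion("fcsmorph")),
                 n_rows = nrow(out$table),
                 comparisons = out$comparisons)
  if (!is.null(out$radius_increments))
    report$radius_increments <- out$radius_increments
  jsonlite::write_json(report, file.path(out_dir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
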