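#!/usr/bin/env Rscript
# Group-level inference over the tables produced by 02 and 03: bootstrap
# mean comparisons of the FCS parameters (alpha = 0.01) and bootstrap median
# comparisons of volume and sphericity (alpha = 0.05), each treatment versus
# its control, plus the cube-root radius increments.

suppressPackageStartupMessages(library(fcsmorph))

master_seed <- 20260927L

## FCS parameters: mean +/- bootstrap SE, treatment vs control
fcs <- read.csv("results/fcs/fit_table.csv")
metrics <- c("N", "f_D", "f_short", "f_long", "tau_D", "tau_short", "tau_long")
cmp_rows <- list()
for (m in metrics) {
  gs <- summarize_groups(fcs, m, "condition", mode = "mean", n_boot = 1000,
                         seed = derive_seed(master_seed, paste0("fcs_", m)))
  for (g in setdiff(names(gs), "control")) {
    cmp <- median_test(gs[[g]], gs[["control"]], alpha = 0.01)
    cmp_rows[[length(cmp_rows) + 1]] <- data.frame(
      group1 = g, group2 = "control", metric = m, delta = cmp$delta,
      z = cmp$z, p = cmp$p_value, significant = cmp$significant)
  }
}
fcs_cmp <- do.call(rbind, cmp_rows)
write.csv(fcs_cmp, "results/fcs/comparisons.csv", row.names = FALSE)
message("FCS comparisons (alpha = 0.01):")
print(fcs_cmp[, c("metric", "delta", "z", "p", "significant")])

## morphometry: median +/- bootstrap SE and radius increments
morpho <- read.csv("results/morpho/morpho_table.csv")
morpho <- morpho[!morpho$border_flag, ]
for (m in c("volume_um3", "sphericity")) {
  gs <- summarize_groups(morpho, m, "condition", mode = "median",
                         n_boot = 1000,
                         seed = derive_seed(master_seed, paste0("mor_", m)))
  for (g in names(gs))
    message(sprintf("%s %s: median %.4g +/- %.3g (n = %d)",
                    g, m, gs[[g]]$center, gs[[g]]$se, gs[[g]]$n))
}
med_vol <- vapply(split(morpho$volume_um3, morpho$condition), median, 0)
for (g in setdiff(names(med_vol), "control"))
  message(sprintf("%s: %.1f%% median-volume change -> %.2f%% radius increment",
                  g, 100 * (med_vol[[g]] / med_vol[["control"]] - 1),
                  radius_increment(med_vol[["control"]], med_vol[[g]])))

jsonlite::write_json(
  list(master_seed = master_seed,
       fcs_comparisons = fcs_cmp,
       median_volumes_um3 = as.list(med_vol)),
  "results/summary_report.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
message("wrote results/summary_report.json")
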