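#!/usr/bin/env Rscript
# Aggregates the trajectories from 03_run_experiments.R into summary tables
# (mean accuracy / AUC on a common removed-fraction grid) and, when ggplot2
# is installed, degradation plots, under results/report/.
# Usage: Rscript analysis/04_report.R [--experiments results/experiments]
#                                     [--out results/report]

suppressPackageStartupMessages(library(bnsens))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i)) args[i + 1] else default
}
exp_dir <- arg("--experiments", "results/experiments")
out_dir <- arg("--out", "results/report")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

has_ggplot <- requireNamespace("ggplot2", quietly = TRUE)
for (nm in list.dirs(exp_dir, recursive = FALSE, full.names = FALSE)) {
  combined <- utils::read.csv(file.path(exp_dir, nm,
                                        "trajectories_combined.csv"))
  summ <- summarize_trajectories(combined)
  utils::write.csv(summ, file.path(out_dir, paste0(nm, "_summary.csv")),
                   row.names = FALSE)
  if (has_ggplot) {
    for (metric in c("auc", "acc")) {
      p <- plot_degradation(summ, metric = metric)
      ggplot2::ggsave(file.path(out_dir,
                                paste0(nm, "_", metric, ".png")),
                      p, width = 8, height = 5, dpi = 120)
    }
  }
  cat(sprintf("%-24s summary written (%d grid rows)\n", nm, nrow(summ)))
}
cat("wrote", out_dir, if (!has_ggplot) "(plots skipped: no ggplot2)" else "",
    "\n")
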