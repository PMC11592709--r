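#!/usr/bin/env Rscript
# Ranks nodes by value of information and edges by Euclidean arc strength for
# every gold network produced by 01_generate_gold.R, writing one CSV per
# ranking under results/rankings/.
# Usage: Rscript analysis/02_rank_targets.R [--gold results/gold]
#                                           [--out results/rankings]

suppressPackageStartupMessages(library(bnsens))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i)) args[i + 1] else default
}
gold_dir <- arg("--gold", "results/gold")
out_dir <- arg("--out", "results/rankings")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (f in list.files(gold_dir, pattern = "\\.xmlbif$", full.names = TRUE)) {
  nm <- sub("\\.xmlbif$", "", basename(f))
  net <- read_xmlbif(f)
  nodes <- rank_nodes(net, "class", "descending")
  write_ranking_csv(nodes, file.path(out_dir, paste0(nm, "_nodes.csv")))
  if (nrow(net$edges)) {
    edges <- rank_edges(net, "descending")
    write_ranking_csv(edges, file.path(out_dir, paste0(nm, "_edges.csv")))
  }
  cat(sprintf("%-24s top node: %-8s (VOI %.4f bits)\n", nm,
              nodes$variable[1], nodes$voi[1]))
}
cat("wrote", out_dir, "\n")
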