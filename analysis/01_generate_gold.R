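#!/usr/bin/env Rscript
# Generates the gold-standard networks and datasets for every scenario preset
# and writes them under results/gold/ (XMLBIF for networks, CSV for data).
# Usage: Rscript analysis/01_generate_gold.R [--out results/gold]

suppressPackageStartupMessages(library(bnsens))

args <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(i <- which(args == "--out"))) args[i + 1] else
  "results/gold"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

presets <- scenario_presets()
manifest <- data.frame()
for (nm in names(presets)) {
  spec <- presets[[nm]]
  net <- generate_gold_network(spec)
  data <- replace_missing(generate_dataset(net, spec))
  gold <- fit_parameters(bayes_net(bn_domains(data), net$edges), data,
                         fit_config(1))
  write_xmlbif(gold, file.path(out_dir, paste0(nm, ".xmlbif")))
  write_bn_csv(data, file.path(out_dir, paste0(nm, ".csv")))
  manifest <- rbind(manifest, data.frame(
    preset = nm, n_nodes = length(gold$variables),
    n_edges = nrow(gold$edges), n_records = nrow(data),
    n_classes = length(bn_domains(data)$class),
    prevalence = max(table(data$class)) / nrow(data)))
  cat(sprintf("%-24s %2d nodes %2d edges %5d records\n", nm,
              length(gold$variables), nrow(gold$edges), nrow(data)))
}
utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                 row.names = FALSE)
cat("wrote", out_dir, "\n")
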