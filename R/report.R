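# ---- experiment driver and reporting ------------------------------------------

#' Run the structural-error experiments
#'
#' For every requested combination of experiment mode, removal/reversal
#' order, and seed, builds one degradation trajectory (refit + evaluate after
#' every edit) and returns them as one long-format data.frame. Optionally
#' writes one CSV per trajectory, a combined CSV, and a reproducibility
#' manifest to `out_dir`.
#'
#' @param gold a fitted gold-standard [bayes_net()].
#' @param data the complete original [bn_data()].
#' @param class_var class variable name.
#' @param modes subset of `c("node-removal", "edge-removal",
#'   "edge-reversal")`.
#' @param orders subset of `c("descending", "ascending", "random")`.
#' @param seeds integer vector of seeds (one trajectory per seed for random
#'   order; deterministic orders are seed-invariant but are still labelled).
#' @param cfg a [fit_config()].
#' @param out_dir optional output directory for CSVs and the manifest.
#' @return long-format data.frame of all trajectories (including step-0
#'   baselines).
#' @export
run_experiment <- function(gold, data, class_var,
                           modes = c("node-removal", "edge-removal",
                                     "edge-reversal"),
                           orders = c("descending", "ascending", "random"),
                           seeds = 1L, cfg = fit_config(), out_dir = NULL) {
  runner <- list(`node-removal` = run_node_removal,
                 `edge-removal` = run_edge_removal,
                 `edge-reversal` = run_edge_reversal)
  out <- NULL
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (mode in modes) {
    for (ord in orders) {
      for (sd in seeds) {
        traj <- runner[[mode]](gold, data, class_var, order_mode = ord,
                               seed = sd, cfg = cfg)
        df <- trajectory_to_df(traj)
        out <- rbind(out, df)
        if (!is.null(out_dir)) {
          utils::write.csv(df, file.path(out_dir,
            sprintf("trajectory_%s_%s_seed%d.csv", mode, ord, sd)),
            row.names = FALSE, quote = FALSE)
        }
        if (ord != "random") break      # deterministic orders: one run
      }
    }
  }
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "trajectories_combined.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("bnsens"))),
      sprintf("r_version: %s", R.version.string),
      sprintf("class_var: %s", class_var),
      sprintf("modes: %s", paste(modes, collapse = ",")),
      sprintf("orders: %s", paste(orders, collapse = ",")),
      sprintf("seeds: %s", paste(seeds, collapse = ",")),
      sprintf("prior_ess: %g", cfg$prior_ess),
      sprintf("n_records: %d", nrow(data)),
      sprintf("n_variables: %d", length(gold$variables)),
      sprintf("n_edges: %d", nrow(gold$edges)))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  out
}

#' Summarize trajectories into degradation-curve tables
#'
#' Aggregates a long-format trajectory table (from [run_experiment()] or
#' re-read from its CSVs) into per-mode curves: mean and sd of ACC and AUC
#' over seeds at every (order, fraction) grid point.
#'
#' @param df long-format trajectory data.frame.
#' @return data.frame with columns `mode`, `order_mode`, `step`, `fraction`,
#'   `n_seeds`, `acc_mean`, `acc_sd`, `auc_mean`, `auc_sd`.
#' @export
summarize_trajectories <- function(df) {
  need <- c("mode", "order_mode", "seed", "step", "fraction", "acc", "auc")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed trajectory table; missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(df$mode, df$order_mode, df$step, drop = TRUE)
  agg <- lapply(split(df, key), function(g) {
    data.frame(mode = g$mode[1], order_mode = g$order_mode[1],
               step = g$step[1], fraction = g$fraction[1],
               n_seeds = length(unique(g$seed)),
               acc_mean = mean(g$acc), acc_sd = stats::sd(g$acc),
               auc_mean = mean(g$auc), auc_sd = stats::sd(g$auc))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$mode, out$order_mode, out$step), ]
  rownames(out) <- NULL
  out
}

#' Plot degradation curves
#'
#' AUC (or ACC) as a function of the fraction of structural edits, one line
#' per removal/reversal order, faceted by experiment mode. Requires ggplot2.
#'
#' @param summary a [summarize_trajectories()] table.
#' @param metric `"auc"` or `"acc"`.
#' @return a ggplot object.
#' @export
plot_degradation <- function(summary, metric = c("auc", "acc")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ycol <- paste0(metric, "_mean")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$fraction, y = .data[[ycol]],
                               colour = .data$order_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "fraction of structural edits",
                  y = toupper(metric), colour = "order") +
    ggplot2::theme_minimal()
}
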