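test_that("generated gold networks are valid, seeded, and class-rooted", {
  spec <- small_scenario()
  net <- generate_gold_network(spec)
  expect_length(validate_network(net), 0)
  expect_length(bn_parents(net, "class"), 0)
  expect_equal(net$cpts$class$table[1, ], spec$prevalence,
               ignore_attr = TRUE)
  net2 <- generate_gold_network(spec)
  expect_identical(net, net2)

  dense <- scenario_spec(n_nodes = 4, n_classes = 2, prevalence = c(0.6, 0.4),
                         edge_density = 5)
  expect_error(generate_gold_network(dense), "infeasible")
})

test_that("zero effect strength produces a fully uninformative model", {
  spec <- scenario_spec(n_nodes = 6, n_classes = 2, prevalence = c(0.7, 0.3),
                        effect_strength = 0, n_records = 100, seed = 9)
  net <- generate_gold_network(spec)
  for (v in setdiff(names(net$variables), "class")) {
    tab <- net$cpts[[v]]$table
    expect_lt(max(abs(sweep(tab, 2, tab[1, ]))), 1e-12)
    expect_lt(cross_entropy_voi(net, "class", v), 1e-9)
  }
  for (i in seq_len(nrow(net$edges))) {
    expect_lt(arc_strength(net, net$edges[i, ]), 1e-9)
  }
})

test_that("edge density lands near its target over many seeds", {
  # shape matched to a mid-sized monitoring data set: 22 nodes, mean
  # in-degree 2.86
  degs <- vapply(1:50, function(s) {
    spec <- scenario_spec(n_nodes = 22, n_classes = 3,
                          prevalence = c(0.778, 0.139, 0.083),
                          cardinality_range = c(2, 4), edge_density = 2.86,
                          n_records = 10, seed = s)
    net <- generate_gold_network(spec)
    nrow(net$edges) / length(net$variables)
  }, 1)
  expect_lt(abs(mean(degs) - 2.86), 0.3)
})

test_that("generate_dataset controls missingness and matches prevalence", {
  spec <- scenario_spec(n_nodes = 6, n_classes = 2, prevalence = c(0.7, 0.3),
                        n_records = 10000, missing_rate = 0.05, seed = 12)
  net <- generate_gold_network(spec)
  d <- generate_dataset(net, spec)
  feats <- setdiff(names(d), "class")
  cells <- unlist(as.data.frame(d)[feats])
  expect_lt(abs(mean(cells == "?") - 0.05), 0.01)
  expect_false(any(d$class == "?"))
  expect_lt(abs(mean(d$class == "c1") - 0.7), 0.02)

  spec0 <- scenario_spec(n_nodes = 6, n_classes = 2,
                         prevalence = c(0.7, 0.3), n_records = 500,
                         missing_rate = 0, seed = 12)
  d0 <- generate_dataset(net, spec0)
  expect_false(any(as.matrix(as.data.frame(d0)) == "?"))
})

test_that("replace_missing appends a dedicated state only where needed", {
  d <- bn_data(data.frame(a = c("t", "f", "t"), b = c("x", "?", "x")),
               domains = list(a = c("t", "f"), b = c("x", "y")))
  r <- replace_missing(d)
  expect_identical(bn_domains(r)$a, c("t", "f"))           # untouched
  expect_identical(bn_domains(r)$b, c("x", "y", "absent_or_normal"))
  expect_false(any(as.matrix(as.data.frame(r)) == "?"))

  clean <- replace_missing(bn_data(data.frame(a = c("t", "f"))))
  expect_identical(bn_domains(clean)$a, c("f", "t"))
})

test_that("a breast-cancer-shaped table gets the documented post-replacement cardinalities", {
  # 9 features with 6,3,11,7,2,3,2,5,2 observed states; features 5 and 8
  # carry missing cells, so replacement lifts them to 3 and 6 states
  set.seed(55)
  n <- 286
  base_cards <- c(6, 3, 11, 7, 2, 3, 2, 5, 2)
  df <- as.data.frame(lapply(seq_along(base_cards), function(i) {
    k <- base_cards[i]
    # guarantee every state is observed
    c(paste0("v", seq_len(k)),
      paste0("v", sample.int(k, n - k, replace = TRUE)))
  }), col.names = sprintf("x%d", seq_along(base_cards)))
  df$x5[2] <- "?"
  df$x8[c(3, 9)] <- "?"
  d <- replace_missing(bn_data(df))
  cards <- lengths(bn_domains(d))
  expect_identical(unname(cards), c(6L, 3L, 11L, 7L, 3L, 3L, 2L, 6L, 2L))
  expect_equal(prod(cards), 299376)
})

test_that("the eight presets mirror the benchmark shapes", {
  ps <- scenario_presets()
  expect_length(ps, 8)
  hep <- ps[["hepatitis-like"]]
  expect_identical(hep$n_nodes, 20)
  expect_identical(hep$n_classes, 2)
  expect_equal(hep$prevalence, c(0.792, 0.208), tolerance = 1e-6)
  expect_identical(hep$n_records, 155)
  expect_identical(ps[["primary-tumor-like"]]$n_classes, 20)
  for (p in ps) {
    expect_equal(sum(p$prevalence), 1, tolerance = 1e-6)
    expect_lte(p$missing_rate, 0.05)
  }
})

test_that("stronger effects do not weaken the gold standard's AUC (trend)", {
  auc_at <- function(strength) {
    mean(vapply(1:20, function(s) {
      spec <- scenario_spec(n_nodes = 7, n_classes = 2,
                            prevalence = c(0.7, 0.3),
                            cardinality_range = c(2, 3), edge_density = 1.5,
                            effect_strength = strength, n_records = 300,
                            seed = 300 + s)
      gd <- make_gold(spec)
      evaluate_model(gd$gold, gd$data, "class")$auc
    }, 1))
  }
  aucs <- vapply(c(0, 1, 4), auc_at, 1)
  expect_true(all(diff(aucs) > -0.02))   # nondecreasing in expectation
  expect_gt(aucs[3], aucs[1])
})

test_that("the full three-experiment pipeline runs end-to-end on a preset", {
  spec <- scenario_presets()[["breast-cancer-like"]]
  gd <- make_gold(spec)
  df <- run_experiment(gd$gold, gd$data, "class",
                       orders = c("descending", "random"), seeds = 1L)
  expect_true(all(c("node-removal", "edge-removal", "edge-reversal") %in%
                  df$mode))
  prev <- max(table(gd$data$class)) / nrow(gd$data)
  ends <- df[df$fraction == 1 & df$mode != "edge-reversal", ]
  expect_true(all(abs(ends$acc - prev) < 1e-12))
  expect_true(all(abs(ends$auc - 0.5) < 1e-12))
  sm <- summarize_trajectories(df)
  expect_true(all(c("acc_mean", "auc_sd") %in% names(sm)))
  expect_error(summarize_trajectories(df[, 1:3]), "malformed")
})
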