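test_that("remove_node deletes incident edges without bridging", {
  net <- chain_net()
  s <- remove_node(net, "b")
  expect_setequal(names(s$variables), c("a", "c"))
  expect_identical(nrow(s$edges), 0L)
  expect_null(s$cpts)

  s2 <- remove_node(net, "c")   # a leaf with in-degree 1
  expect_identical(nrow(s2$edges), 1L)

  b <- remove_node(net, "b", bridge = TRUE)
  expect_identical(unname(b$edges[1, ]), c("a", "c"))

  expect_error(remove_node(net, "c", class_var = "c"), "class")
  expect_error(remove_node(net, "zz"), "not in network")
})

test_that("removing every non-class node leaves the lone class node", {
  gd <- make_gold(small_scenario())
  s <- gd$gold
  for (v in setdiff(names(s$variables), "class")) {
    s <- remove_node(s, v, class_var = "class")
  }
  expect_identical(names(s$variables), "class")
  expect_identical(nrow(s$edges), 0L)
})

test_that("remove_edge removes exactly one edge", {
  net <- chain_net()
  s <- remove_edge(net, c("a", "b"))
  expect_identical(nrow(s$edges), 1L)
  expect_identical(unname(s$edges[1, ]), c("b", "c"))
  expect_error(remove_edge(net, c("a", "c")), "not in network")
})

test_that("removal that disconnects a feature from the class kills its VOI", {
  net <- copy_net()
  d <- sample_records(net, 2000, seed = 19, class_var = "c")
  cut <- fit_parameters(remove_edge(net, c("c", "f1")), d, fit_config(1))
  expect_lt(cross_entropy_voi(cut, "c", "f1"), 1e-9)
})

test_that("reverse_edge flips when acyclic and rejects 3-cycles", {
  lone <- bayes_net(list(a = "t", b = "t"), rbind(c("a", "b")))
  r <- reverse_edge(lone, c("a", "b"))
  expect_identical(unname(r$edges[1, ]), c("b", "a"))

  tri <- bayes_net(list(a = "t", b = "t", c = "t"),
                   rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_null(reverse_edge(tri, c("a", "c")))       # a->b->c->a cycle
  ok <- reverse_edge(tri, c("a", "b"))              # stays acyclic
  expect_false(is.null(ok))
  expect_silent(topological_order(ok))
})

test_that("the postponement queue yields the hand-simulated schedule", {
  tri <- bayes_net(list(a = "t", b = "t", c = "t"),
                   rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ranked <- data.frame(parent = c("a", "a", "b"), child = c("c", "b", "c"))
  sched <- reversal_schedule(tri, ranked)
  expect_identical(paste(sched$parent, sched$child),
                   c("a b", "a c", "b c"))   # a->c postponed once

  lone <- bayes_net(list(a = "t", b = "t"), rbind(c("a", "b")))
  s1 <- reversal_schedule(lone, data.frame(parent = "a", child = "b"))
  expect_identical(nrow(s1), 1L)

  expect_error(reversal_schedule(tri, ranked[1:2, ]), "cover")
})

test_that("reversal schedules terminate with the fully reversed DAG", {
  for (seed in 1:25) {
    net <- random_dag(12, 24, seed = seed)
    e <- as.data.frame(net$edges, stringsAsFactors = FALSE)
    ranked <- e[sample(nrow(e)), ]
    sched <- reversal_schedule(net, ranked)
    expect_identical(nrow(sched), nrow(e))
    # apply cumulatively: every intermediate graph acyclic, final reversed
    cur <- net
    for (i in seq_len(nrow(sched))) {
      cur <- reverse_edge(cur, c(sched$parent[i], sched$child[i]))
      expect_false(is.null(cur))
    }
    expect_setequal(paste(cur$edges[, 1], cur$edges[, 2]),
                    paste(e$child, e$parent))
  }
})

test_that("node-removal trajectories follow the dynamic-ranking contract", {
  gd <- make_gold(small_scenario())
  n_steps <- length(gd$gold$variables) - 1L

  tr <- run_node_removal(gd$gold, gd$data, "class", "descending", seed = 1,
                         keep_models = TRUE)
  expect_identical(nrow(tr$steps), n_steps)
  expect_true(all(tr$steps$fraction > 0 & tr$steps$fraction <= 1))
  expect_true(all(tr$steps$acc >= 0 & tr$steps$acc <= 1))
  expect_true(all(tr$steps$auc >= 0 & tr$steps$auc <= 1))
  # dynamic ranking: recomputed at every step, on ever-shrinking models
  expect_length(tr$rank_history, n_steps)
  expect_identical(vapply(tr$rank_history, nrow, 1L),
                   rev(seq_len(n_steps)))
  # every intermediate model valid
  for (m in tr$models) expect_length(validate_network(m), 0)

  # endpoint identities: prevalence accuracy, midrank-0.5 AUC
  prev <- max(table(gd$data$class)) / nrow(gd$data)
  expect_equal(tr$steps$acc[n_steps], prev)
  expect_equal(tr$steps$auc[n_steps], 0.5)

  # random order: one up-front permutation, reproducible
  tr1 <- run_node_removal(gd$gold, gd$data, "class", "random", seed = 5)
  tr2 <- run_node_removal(gd$gold, gd$data, "class", "random", seed = 5)
  expect_identical(tr1$steps$edit_target, tr2$steps$edit_target)
  expect_length(tr1$rank_history, 0)
})

test_that("edge-removal trajectories use one static ranking and end disconnected", {
  gd <- make_gold(small_scenario())
  tr <- run_edge_removal(gd$gold, gd$data, "class", "ascending", seed = 2,
                         keep_models = TRUE)
  expect_identical(nrow(tr$steps), nrow(gd$gold$edges))
  # static: the one gold-standard ranking is recorded, never recomputed
  expect_identical(nrow(tr$edge_ranking), nrow(gd$gold$edges))
  expect_identical(nrow(tr$models[[length(tr$models)]]$edges), 0L)
  prev <- max(table(gd$data$class)) / nrow(gd$data)
  expect_equal(tr$steps$acc[nrow(tr$steps)], prev)
  expect_equal(tr$steps$auc[nrow(tr$steps)], 0.5)
})

test_that("removing an inert edge first barely moves the AUC", {
  # gold with one null edge: u -> f3 whose rows are identical
  vars <- list(class = c("c1", "c2"), f1 = c("t", "f"), f2 = c("t", "f"),
               f3 = c("t", "f"))
  net <- bayes_net(vars, rbind(c("class", "f1"), c("class", "f2"),
                               c("f1", "f3")), list(
    class = cpt("class", character(0), list(), vars$class,
                matrix(c(0.7, 0.3), 1)),
    f1 = cpt("f1", "class", vars["class"], vars$f1,
             matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)),
    f2 = cpt("f2", "class", vars["class"], vars$f2,
             matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)),
    f3 = cpt("f3", "f1", vars["f1"], vars$f3,
             matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE))))
  d <- sample_records(net, 5000, seed = 23, class_var = "class")
  gold <- fit_parameters(bayes_net(vars, net$edges), d, fit_config(1))
  tr <- run_edge_removal(gold, d, "class", "ascending", seed = 1)
  expect_identical(tr$steps$edit_target[1], "f1->f3")
  expect_lt(abs(tr$steps$auc[1] - tr$baseline_auc), 0.01)
})

test_that("edge-reversal trajectories stay acyclic and end fully reversed", {
  gd <- make_gold(small_scenario())
  tr <- run_edge_reversal(gd$gold, gd$data, "class", "descending", seed = 3,
                          keep_models = TRUE)
  expect_identical(nrow(tr$steps), nrow(gd$gold$edges))
  for (m in tr$models) expect_length(validate_network(m), 0)
  final <- tr$models[[length(tr$models)]]
  expect_setequal(paste(final$edges[, 1], final$edges[, 2]),
                  paste(gd$gold$edges[, 2], gd$gold$edges[, 1]))
})

test_that("reversing a naive Bayes explodes the class CPT into one row per feature configuration", {
  # class -> f1..f9 with 500 records: after full reversal the class node is
  # conditioned on every feature, one CPT row per feature configuration
  set.seed(29)
  vars <- c(list(class = c("c1", "c2")),
            setNames(rep(list(c("t", "f")), 9), sprintf("f%d", 1:9)))
  feats <- setdiff(names(vars), "class")
  cpts <- c(list(class = cpt("class", character(0), list(), vars$class,
                             matrix(c(0.65, 0.35), 1))),
            lapply(feats, function(f) {
              p <- runif(1, 0.7, 0.95)
              cpt(f, "class", vars["class"], vars[[f]],
                  matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE))
            }))
  names(cpts) <- c("class", feats)
  nb <- bayes_net(vars, cbind("class", feats), cpts)
  d <- sample_records(nb, 500, seed = 30, class_var = "class")
  gold <- fit_parameters(bayes_net(vars, nb$edges), d, fit_config(1))
  tr <- run_edge_reversal(gold, d, "class", "ascending", seed = 4,
                          keep_models = TRUE)
  final <- tr$models[[length(tr$models)]]
  expect_identical(nrow(final$cpts$class$table), 512L)
  # most parent configurations are never observed in the 500 records and are
  # estimated from the prior alone
  expect_gt(fit_report(final, d)$smoothed_fraction[1], 0.4)
})

test_that("full reversal of an augmented-naive-Bayes-shaped gold degrades AUC", {
  # once every edge points into the class, only the class's direct parents
  # carry information at prediction time and the exploded class CPT is
  # learned from sparse counts; on the ANB-shaped preset this costs AUC
  spec <- scenario_presets()[["breast-cancer-like"]]
  gd <- make_gold(spec)
  tr <- run_edge_reversal(gd$gold, gd$data, "class", "descending", seed = 4)
  expect_lt(tr$steps$auc[nrow(tr$steps)], tr$baseline_auc)
})

test_that("trajectory tables round-trip through CSV", {
  gd <- make_gold(small_scenario())
  tr <- run_edge_removal(gd$gold, gd$data, "class", "descending", seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(tr$steps) + 1L)   # + baseline row
  expect_equal(back$auc, trajectory_to_df(tr)$auc, tolerance = 1e-12)
})
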