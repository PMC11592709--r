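test_that("entropy has the right anchors and is permutation invariant", {
  expect_equal(entropy(c(1, 0)), 0)
  expect_equal(entropy(c(0.5, 0.5)), 1)
  expect_equal(entropy(rep(0.25, 4)), 2)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(entropy(p), entropy(rev(p)))
  expect_equal(entropy(cat_dist(c("x", "y"), c(0.3, 0.7))),
               entropy(c(0.7, 0.3)))
})

test_that("value of information equals mutual information from the joint", {
  net <- copy_net()
  # marginally independent pair
  expect_equal(cross_entropy_voi(net, "c", "f2"), 0, tolerance = 1e-9)
  # deterministic copy of a uniform binary class: full bit
  expect_equal(cross_entropy_voi(net, "c", "f1"), 1, tolerance = 1e-9)

  for (seed in 1:8) {
    rnet <- random_net(5, max_card = 3, seed = seed)
    vars <- names(rnet$variables)
    got <- cross_entropy_voi(rnet, vars[1], vars[4])
    expect_equal(got, oracle_mi(rnet, vars[1], vars[4]), tolerance = 1e-9)
    expect_gte(got, -1e-9)
    expect_lte(got, min(entropy(posterior(rnet, vars[1])),
                        entropy(posterior(rnet, vars[4]))) + 1e-9)
  }
})

test_that("rank_nodes orders by VOI with lexicographic ties and seeded shuffles", {
  net <- copy_net()
  rk <- rank_nodes(net, "c", "descending")
  expect_identical(rk$variable, c("f1", "f2"))
  expect_identical(rank_nodes(net, "c", "ascending")$variable,
                   c("f2", "f1"))

  # two exactly tied features -> lexicographic
  vars <- list(c = c("t", "f"), f1 = c("t", "f"), f2 = c("t", "f"))
  tied <- bayes_net(vars, NULL, list(
    c = cpt("c", character(0), list(), vars$c, matrix(c(0.5, 0.5), 1)),
    f1 = cpt("f1", character(0), list(), vars$f1, matrix(c(0.4, 0.6), 1)),
    f2 = cpt("f2", character(0), list(), vars$f2, matrix(c(0.4, 0.6), 1))))
  expect_identical(rank_nodes(tied, "c", "descending")$variable,
                   c("f1", "f2"))

  r1 <- rank_nodes(net, "c", "random", seed = 99)
  r2 <- rank_nodes(net, "c", "random", seed = 99)
  expect_identical(r1$variable, r2$variable)
  expect_false("c" %in% r1$variable)
})

test_that("arc_strength matches hand computations", {
  # child rows identical across the parent's states -> zero
  vars <- list(u = c("u1", "u2"), v = c("v1", "v2"))
  same <- bayes_net(vars, rbind(c("u", "v")), list(
    u = cpt("u", character(0), list(), vars$u, matrix(c(0.5, 0.5), 1)),
    v = cpt("v", "u", vars["u"], vars$v,
            matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE))))
  expect_equal(arc_strength(same, c("u", "v")), 0)

  # maximally opposed rows -> sqrt(2)
  flip <- bayes_net(vars, rbind(c("u", "v")), list(
    u = cpt("u", character(0), list(), vars$u, matrix(c(0.5, 0.5), 1)),
    v = cpt("v", "u", vars["u"], vars$v,
            matrix(c(1, 0, 0, 1), 2, byrow = TRUE))))
  expect_equal(arc_strength(flip, c("u", "v")), sqrt(2), tolerance = 1e-12)

  # 2-parent child: direct summation over the co-parent's states
  vars3 <- list(u = c("u1", "u2"), z = c("z1", "z2"), v = c("v1", "v2"))
  tab <- rbind(c(0.9, 0.1),   # u1 z1
               c(0.6, 0.4),   # u1 z2
               c(0.2, 0.8),   # u2 z1
               c(0.5, 0.5))   # u2 z2
  net3 <- bayes_net(vars3, rbind(c("u", "v"), c("z", "v")), list(
    u = cpt("u", character(0), list(), vars3$u, matrix(c(0.5, 0.5), 1)),
    z = cpt("z", character(0), list(), vars3$z, matrix(c(0.3, 0.7), 1)),
    v = cpt("v", c("u", "z"), vars3[c("u", "z")], vars3$v, tab)))
  d_z1 <- sqrt(sum((tab[1, ] - tab[3, ])^2))
  d_z2 <- sqrt(sum((tab[2, ] - tab[4, ])^2))
  expect_equal(arc_strength(net3, c("u", "v")), 0.3 * d_z1 + 0.7 * d_z2,
               tolerance = 1e-12)
})

test_that("arc_strength ignores CPTs outside the child's family except via P(Z)", {
  vars <- list(w = c("t", "f"), u = c("u1", "u2"), v = c("v1", "v2"))
  build <- function(pw) {
    bayes_net(vars, rbind(c("w", "u"), c("u", "v")), list(
      w = cpt("w", character(0), list(), vars$w, matrix(c(pw, 1 - pw), 1)),
      u = cpt("u", "w", vars["w"], vars$u,
              matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE)),
      v = cpt("v", "u", vars["u"], vars$v,
              matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE))))
  }
  # v has no co-parents, so changing w's prior cannot move the strength
  expect_equal(arc_strength(build(0.2), c("u", "v")),
               arc_strength(build(0.9), c("u", "v")), tolerance = 1e-12)
})

test_that("rank_edges is complete, static in form, and deterministic", {
  gd <- make_gold(small_scenario())
  rk <- rank_edges(gd$gold, "ascending")
  expect_setequal(paste(rk$parent, rk$child),
                  paste(gd$gold$edges[, 1], gd$gold$edges[, 2]))
  expect_true(all(diff(rk$strength) >= -1e-12))
  rkd <- rank_edges(gd$gold, "descending")
  expect_true(all(diff(rkd$strength) <= 1e-12))
  expect_identical(rank_edges(gd$gold, "random", seed = 7),
                   rank_edges(gd$gold, "random", seed = 7))

  # a null edge (identical rows) sorts first ascending
  vars <- list(u = c("t", "f"), v = c("t", "f"), w = c("t", "f"))
  net <- bayes_net(vars, rbind(c("u", "v"), c("u", "w")), list(
    u = cpt("u", character(0), list(), vars$u, matrix(c(0.5, 0.5), 1)),
    v = cpt("v", "u", vars["u"], vars$v,
            matrix(c(0.4, 0.6, 0.4, 0.6), 2, byrow = TRUE)),
    w = cpt("w", "u", vars["u"], vars$w,
            matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))))
  ra <- rank_edges(net, "ascending")
  expect_identical(ra$child[1], "v")
  expect_equal(ra$strength[1], 0)
})
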