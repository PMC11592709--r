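# ---- entropy and value of information ---------------------------------------

#' Shannon entropy of a categorical distribution, in bits
#'
#' `-sum p_i log2 p_i` with the convention `0 log 0 = 0`. Zero when the
#' distribution is degenerate, `log2 n` when uniform over `n` states.
#'
#' @param dist a [cat_dist()] or bare probability vector.
#' @return entropy in bits, in `[0, log2 n]`.
#' @export
entropy <- function(dist) {
  p <- if (inherits(dist, "bn_dist")) dist$probs else as.numeric(dist)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Value of information of observing one variable about the class
#'
#' The expected reduction in the class variable's entropy upon observing
#' `obs_var`: `H(P(c)) - sum_i P(y_i) H(P(c | y_i))`, with every distribution
#' obtained from the model by exact inference. For distributions read off one
#' consistent joint this equals the mutual information between the class and
#' the observed variable, and is therefore nonnegative.
#'
#' @param net a fitted [bayes_net()].
#' @param class_var class variable name.
#' @param obs_var candidate observation, different from `class_var`.
#' @return value of information in bits.
#' @export
cross_entropy_voi <- function(net, class_var, obs_var) {
  stopifnot(obs_var != class_var)
  pc <- posterior(net, class_var)
  py <- posterior(net, obs_var)
  h0 <- entropy(pc)
  hcond <- 0
  for (i in seq_along(py$states)) {
    if (py$probs[i] <= 0) next
    pci <- posterior(net, class_var,
                     stats::setNames(py$states[i], obs_var))
    hcond <- hcond + py$probs[i] * entropy(pci)
  }
  h0 - hcond
}

# ---- node ranking ------------------------------------------------------------

#' Rank non-class nodes by value of information
#'
#' Ascending/descending orders sort by [cross_entropy_voi()] with lexicographic
#' tie-breaks; random mode is a seeded uniform shuffle that ignores the values
#' (they are still reported).
#'
#' @param net a fitted [bayes_net()].
#' @param class_var class variable name.
#' @param order_mode one of `"ascending"`, `"random"`, `"descending"`.
#' @param seed integer seed (used by random mode).
#' @return an object of class `bn_node_ranking`: data.frame with columns
#'   `rank`, `variable`, `voi`, plus attributes `order_mode`, `class_var`,
#'   `seed`.
#' @export
rank_nodes <- function(net, class_var,
                       order_mode = c("descending", "ascending", "random"),
                       seed = 1L) {
  order_mode <- match.arg(order_mode)
  vars <- sort(setdiff(names(net$variables), class_var))
  voi <- vapply(vars, function(v) cross_entropy_voi(net, class_var, v), 1)
  idx <- switch(order_mode,
    ascending  = order(voi, vars),
    descending = order(-voi, vars),
    random     = with_local_seed(seed, sample.int(length(vars)))
  )
  structure(data.frame(rank = seq_along(vars), variable = vars[idx],
                       voi = unname(voi[idx])),
            order_mode = order_mode, class_var = class_var, seed = seed,
            class = c("bn_node_ranking", "data.frame"))
}

# ---- arc strength -------------------------------------------------------------

#' Euclidean arc strength of one edge
#'
#' Measures how much the child's conditional distribution moves as the
#' parent's state changes: with `Z` the child's other parents,
#' `sum_z P(Z = z) * mean over unordered state pairs {a, b} of u of
#' || P(v | u = a, Z = z) - P(v | u = b, Z = z) ||_2`. The co-parent weights
#' `P(Z = z)` come from the model's joint marginal; the conditionals are the
#' child's CPT rows. Zero when the child's rows do not depend on the parent.
#'
#' @param net a fitted [bayes_net()].
#' @param edge length-2 character vector `(parent, child)`.
#' @return a nonnegative strength.
#' @export
arc_strength <- function(net, edge) {
  u <- edge[1]; v <- edge[2]
  if (!any(net$edges[, 1] == u & net$edges[, 2] == v)) {
    stop(sprintf("edge %s -> %s not in network", u, v), call. = FALSE)
  }
  cp <- net$cpts[[v]]
  z_vars <- setdiff(cp$parents, u)
  u_states <- net$variables[[u]]
  if (length(u_states) < 2) return(0)
  pairs <- utils::combn(length(u_states), 2)
  cards <- vapply(cp$parent_states, length, 1L)
  if (length(z_vars)) {
    pz <- joint_marginal(net, z_vars)
    zgrid <- config_grid(pz$states)
    names(zgrid) <- pz$vars
    wz <- as.vector(aperm(pz$values, rev(seq_along(pz$vars))))
    # aperm + as.vector linearizes with the LAST variable fastest, matching
    # config_grid's row order
  } else {
    zgrid <- data.frame(row.names = 1)
    wz <- 1
  }
  total <- 0
  for (zi in seq_along(wz)) {
    if (wz[zi] <= 0) next
    rows <- vapply(seq_along(u_states), function(a) {
      codes <- matrix(vapply(cp$parents, function(p) {
        if (p == u) a else match(zgrid[zi, p], cp$parent_states[[p]])
      }, 1L), nrow = 1)
      cp$table[config_index(codes, cards), ]
    }, numeric(length(cp$states)))
    d <- mean(apply(pairs, 2, function(ab)
      sqrt(sum((rows[, ab[1]] - rows[, ab[2]])^2))))
    total <- total + wz[zi] * d
  }
  total
}

#' Rank all edges by arc strength
#'
#' Arc strength is a static measure: it is computed once on the gold-standard
#' network and never recomputed along a mutilation trajectory. Ties break
#' lexicographically by `(parent, child)`; random mode is a seeded shuffle.
#'
#' @param net a fitted [bayes_net()] with at least one edge.
#' @param order_mode one of `"descending"`, `"ascending"`, `"random"`.
#' @param seed integer seed (used by random mode).
#' @return an object of class `bn_edge_ranking`: data.frame with columns
#'   `rank`, `parent`, `child`, `strength`.
#' @export
rank_edges <- function(net,
                       order_mode = c("descending", "ascending", "random"),
                       seed = 1L) {
  order_mode <- match.arg(order_mode)
  if (nrow(net$edges) == 0) stop("network has no edges", call. = FALSE)
  e <- as.data.frame(net$edges, stringsAsFactors = FALSE)
  e <- e[order(e$parent, e$child), , drop = FALSE]
  s <- vapply(seq_len(nrow(e)), function(i)
    arc_strength(net, c(e$parent[i], e$child[i])), 1)
  idx <- switch(order_mode,
    ascending  = order(s, e$parent, e$child),
    descending = order(-s, e$parent, e$child),
    random     = with_local_seed(seed, sample.int(nrow(e)))
  )
  structure(data.frame(rank = seq_len(nrow(e)), parent = e$parent[idx],
                       child = e$child[idx], strength = unname(s[idx])),
            order_mode = order_mode, seed = seed,
            class = c("bn_edge_ranking", "data.frame"))
}

#' Export a node or edge ranking as CSV
#' @param ranking a `bn_node_ranking` or `bn_edge_ranking`.
#' @param path output path.
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$order_mode <- attr(ranking, "order_mode")
  df$seed <- attr(ranking, "seed")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
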