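# ---- structural edits ---------------------------------------------------------

#' Remove a node from a network structure
#'
#' Deletes the node and every incident edge; parents are not bridged to
#' children (refitting on the original data re-absorbs lost dependencies
#' where the remaining structure allows). CPTs are invalidated: the caller
#' must refit parameters.
#'
#' @param net a [bayes_net()].
#' @param node variable to remove.
#' @param class_var optional class designation; removing it is an error.
#' @param bridge if `TRUE`, add parent-to-child edges around the removed node
#'   (off by default).
#' @return an unfitted structure.
#' @export
remove_node <- function(net, node, class_var = NULL, bridge = FALSE) {
  if (!node %in% names(net$variables)) {
    stop(sprintf("node '%s' not in network", node), call. = FALSE)
  }
  if (!is.null(class_var) && node == class_var) {
    stop("the class node cannot be removed", call. = FALSE)
  }
  keep <- net$edges[, 1] != node & net$edges[, 2] != node
  edges <- net$edges[keep, , drop = FALSE]
  if (bridge) {
    pa <- net$edges[net$edges[, 2] == node, 1]
    ch <- net$edges[net$edges[, 1] == node, 2]
    for (p in pa) for (c0 in ch) {
      if (!any(edges[, 1] == p & edges[, 2] == c0)) {
        edges <- rbind(edges, c(p, c0))
      }
    }
  }
  bayes_net(net$variables[setdiff(names(net$variables), node)], edges)
}

#' Remove an edge from a network structure
#'
#' @param net a [bayes_net()].
#' @param edge length-2 character vector `(parent, child)`.
#' @return an unfitted structure; only the named edge is removed.
#' @export
remove_edge <- function(net, edge) {
  hit <- net$edges[, 1] == edge[1] & net$edges[, 2] == edge[2]
  if (!any(hit)) {
    stop(sprintf("edge %s -> %s not in network", edge[1], edge[2]),
         call. = FALSE)
  }
  bayes_net(net$variables, net$edges[!hit, , drop = FALSE])
}

#' Reverse an edge, rejecting reversals that create a cycle
#'
#' @param net a [bayes_net()].
#' @param edge length-2 character vector `(parent, child)`.
#' @return the edited (unfitted) structure, or `NULL` when the reversal
#'   would create a directed cycle (the input is never mutated).
#' @export
reverse_edge <- function(net, edge) {
  hit <- net$edges[, 1] == edge[1] & net$edges[, 2] == edge[2]
  if (!any(hit)) {
    stop(sprintf("edge %s -> %s not in network", edge[1], edge[2]),
         call. = FALSE)
  }
  edges <- net$edges
  edges[hit, ] <- c(edge[2], edge[1])
  if (!is_dag(net$variables, edges)) return(NULL)
  bayes_net(net$variables, edges)
}

#' Cycle-avoiding schedule of edge reversals
#'
#' Processes a queue seeded with the ranking: the front-most edge whose
#' reversal keeps the current graph acyclic is reversed; edges that cannot
#' yet be reversed stay at the front of the queue and are retried after every
#' accepted reversal. The procedure always terminates with every edge
#' reversed exactly once (reversing all edges of a DAG yields a DAG, so a
#' reversible edge always exists).
#'
#' @param net a [bayes_net()].
#' @param ranked a [rank_edges()] ranking covering exactly the network's
#'   edges.
#' @return data.frame of accepted reversals in order, columns `parent`,
#'   `child` (original orientation).
#' @export
reversal_schedule <- function(net, ranked) {
  key <- function(p, c0) paste(p, c0, sep = "\r")
  net_keys <- sort(key(net$edges[, 1], net$edges[, 2]))
  rank_keys <- sort(key(ranked$parent, ranked$child))
  if (!identical(net_keys, rank_keys)) {
    stop("ranking does not cover exactly the network's edges", call. = FALSE)
  }
  queue <- ranked[, c("parent", "child")]
  cur <- net
  out <- NULL
  while (nrow(queue)) {
    accepted <- FALSE
    for (i in seq_len(nrow(queue))) {
      cand <- reverse_edge(cur, c(queue$parent[i], queue$child[i]))
      if (!is.null(cand)) {
        out <- rbind(out, queue[i, ])
        queue <- queue[-i, , drop = FALSE]
        cur <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) stop("no reversible edge found; graph is not a DAG",
                        call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# ---- trajectories -------------------------------------------------------------

new_trajectory <- function(mode, order_mode, seed, baseline, steps,
                           models = NULL, rank_history = NULL,
                           edge_ranking = NULL) {
  structure(list(mode = mode, order_mode = order_mode, seed = seed,
                 baseline_acc = baseline$acc, baseline_auc = baseline$auc,
                 designated_class = baseline$designated_class,
                 steps = steps, models = models,
                 rank_history = rank_history, edge_ranking = edge_ranking),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %s order, %d steps, baseline ACC %.3f / AUC %.3f>\n",
              x$mode, x$order_mode, nrow(x$steps), x$baseline_acc,
              x$baseline_auc))
  invisible(x)
}

step_row <- function(i, total, kind, target, ev) {
  data.frame(step = i, fraction = i / total, edit_kind = kind,
             edit_target = target, acc = ev$acc, auc = ev$auc,
             n_fallbacks = ev$n_zero_evidence_fallbacks)
}

refit_and_eval <- function(structure0, data, class_var, positive, cfg) {
  dd <- bn_restrict(data, names(structure0$variables))
  model <- fit_parameters(structure0, dd, cfg)
  stopifnot(length(validate_network(model)) == 0)
  list(model = model,
       ev = evaluate_model(model, dd, class_var, positive))
}

#' Node-removal degradation trajectory
#'
#' Starting from the gold standard, repeatedly: (1) rank the remaining
#' non-class nodes by value of information on the *current* refitted model
#' (the ranking is dynamic — removals change it); (2) remove the first node
#' in the requested order; (3) refit parameters on the original data
#' restricted to the remaining columns; (4) record resubstitution ACC and
#' one-vs-rest AUC for the designated class. Random order draws one
#' permutation up front from the seed. The trajectory ends when only the
#' class node remains.
#'
#' @param gold a fitted gold-standard [bayes_net()].
#' @param data the complete original [bn_data()].
#' @param class_var class variable name.
#' @param order_mode `"descending"` (highest VOI first), `"ascending"`, or
#'   `"random"`.
#' @param seed integer seed (random order and logging).
#' @param cfg a [fit_config()].
#' @param keep_models retain each step's refitted model in the result.
#' @return a `bn_trajectory` with `#variables - 1` steps.
#' @export
run_node_removal <- function(gold, data, class_var,
                             order_mode = c("descending", "ascending",
                                            "random"),
                             seed = 1L, cfg = fit_config(),
                             keep_models = FALSE) {
  order_mode <- match.arg(order_mode)
  positive <- most_prevalent_class(data, class_var)
  base <- refit_and_eval(gold, data, class_var, positive, cfg)
  current <- base$model
  total <- length(gold$variables) - 1L
  perm <- if (order_mode == "random") {
    vars <- sort(setdiff(names(gold$variables), class_var))
    with_local_seed(seed, sample(vars))
  }
  steps <- NULL
  models <- if (keep_models) list()
  rank_history <- list()
  for (i in seq_len(total)) {
    if (order_mode == "random") {
      victim <- perm[i]
    } else {
      rk <- rank_nodes(current, class_var, order_mode, seed)
      rank_history[[i]] <- as.data.frame(rk)
      victim <- rk$variable[1]
    }
    structure0 <- remove_node(current, victim, class_var)
    fe <- refit_and_eval(structure0, data, class_var, positive, cfg)
    current <- fe$model
    if (keep_models) models[[i]] <- current
    steps <- rbind(steps, step_row(i, total, "remove-node", victim, fe$ev))
  }
  new_trajectory("node-removal", order_mode, seed, base$ev, steps, models,
                 rank_history = rank_history)
}

#' Edge-removal degradation trajectory
#'
#' Edges are ranked once by arc strength on the gold standard (a static
#' measure) and removed one by one in the requested order, refitting on the
#' original data and recording ACC/AUC after each removal. After the last
#' step the model is fully disconnected.
#'
#' @inheritParams run_node_removal
#' @return a `bn_trajectory` with `#gold edges` steps.
#' @export
run_edge_removal <- function(gold, data, class_var,
                             order_mode = c("descending", "ascending",
                                            "random"),
                             seed = 1L, cfg = fit_config(),
                             keep_models = FALSE) {
  order_mode <- match.arg(order_mode)
  positive <- most_prevalent_class(data, class_var)
  base <- refit_and_eval(gold, data, class_var, positive, cfg)
  ranked <- rank_edges(base$model, order_mode, seed)
  current <- base$model
  total <- nrow(ranked)
  steps <- NULL
  models <- if (keep_models) list()
  for (i in seq_len(total)) {
    edge <- c(ranked$parent[i], ranked$child[i])
    structure0 <- remove_edge(current, edge)
    fe <- refit_and_eval(structure0, data, class_var, positive, cfg)
    current <- fe$model
    if (keep_models) models[[i]] <- current
    steps <- rbind(steps, step_row(i, total, "remove-edge",
                                   paste(edge, collapse = "->"), fe$ev))
  }
  new_trajectory("edge-removal", order_mode, seed, base$ev, steps, models,
                 edge_ranking = ranked)
}

#' Edge-reversal degradation trajectory
#'
#' Edges are ranked once by arc strength on the gold standard and reversed
#' cumulatively following the cycle-avoiding [reversal_schedule()], refitting
#' and evaluating after each accepted reversal. The final structure is the
#' gold structure with every edge flipped.
#'
#' @inheritParams run_node_removal
#' @return a `bn_trajectory` with `#gold edges` steps.
#' @export
run_edge_reversal <- function(gold, data, class_var,
                              order_mode = c("descending", "ascending",
                                             "random"),
                              seed = 1L, cfg = fit_config(),
                              keep_models = FALSE) {
  order_mode <- match.arg(order_mode)
  positive <- most_prevalent_class(data, class_var)
  base <- refit_and_eval(gold, data, class_var, positive, cfg)
  ranked <- rank_edges(base$model, order_mode, seed)
  sched <- reversal_schedule(base$model, ranked)
  current <- base$model
  total <- nrow(sched)
  steps <- NULL
  models <- if (keep_models) list()
  for (i in seq_len(total)) {
    edge <- c(sched$parent[i], sched$child[i])
    structure0 <- reverse_edge(current, edge)
    stopifnot(!is.null(structure0))   # schedule guarantees acyclicity
    fe <- refit_and_eval(structure0, data, class_var, positive, cfg)
    current <- fe$model
    if (keep_models) models[[i]] <- current
    steps <- rbind(steps, step_row(i, total, "reverse-edge",
                                   paste(edge, collapse = "->"), fe$ev))
  }
  new_trajectory("edge-reversal", order_mode, seed, base$ev, steps, models,
                 edge_ranking = ranked)
}

#' Trajectory as a long-format data.frame
#'
#' Includes a step-0 baseline row; columns `mode`, `order_mode`, `seed`,
#' `step`, `fraction`, `edit_kind`, `edit_target`, `acc`, `auc`.
#'
#' @param traj a `bn_trajectory`.
#' @return a data.frame.
#' @export
trajectory_to_df <- function(traj) {
  base <- data.frame(step = 0L, fraction = 0, edit_kind = "baseline",
                     edit_target = "", acc = traj$baseline_acc,
                     auc = traj$baseline_auc, n_fallbacks = NA_integer_)
  df <- rbind(base, traj$steps)
  cbind(data.frame(mode = traj$mode, order_mode = traj$order_mode,
                   seed = traj$seed), df)
}

#' Write a trajectory to CSV
#' @param traj a `bn_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(trajectory_to_df(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
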