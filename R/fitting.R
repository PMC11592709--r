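# ---- parameter learning -----------------------------------------------------

#' Fitting configuration
#'
#' @param prior_ess Dirichlet equivalent sample size for CPT smoothing
#'   (default 1). `prior_ess = 0` gives pure maximum likelihood; any positive
#'   value spreads `prior_ess` uniformly over the child's states in every
#'   parent configuration, so unseen configurations get a uniform row and
#'   inference never meets a hard zero created by sampling noise alone.
#' @param state_policy `"declared"` to take each variable's states from the
#'   structure's declared domain, `"observed"` to take them from the data's
#'   declared domains (which include every observed value).
#' @return a list of class `bn_fit_config`.
#' @export
fit_config <- function(prior_ess = 1.0, state_policy = c("declared",
                                                         "observed")) {
  stopifnot(prior_ess >= 0)
  structure(list(prior_ess = prior_ess,
                 state_policy = match.arg(state_policy)),
            class = "bn_fit_config")
}

#' Fit CPT parameters for a fixed structure
#'
#' Smoothed relative-frequency estimation: each CPT row is
#' `(N(x, pa) + ess/r) / (N(pa) + ess)` where `r` is the child's state count.
#' Parent configurations never seen in the data get a uniform row when
#' `ess > 0` (and also when `ess = 0`, so the CPT invariants always hold).
#'
#' @param structure a [bayes_net()]; existing CPTs are ignored.
#' @param data a complete [bn_data()] covering every structure variable.
#' @param cfg a [fit_config()].
#' @return the structure as a fitted [bayes_net()].
#' @export
fit_parameters <- function(structure, data, cfg = fit_config()) {
  vars <- names(structure$variables)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop(sprintf("data lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  domains <- if (cfg$state_policy == "observed") {
    bn_domains(data)[vars]
  } else {
    structure$variables
  }
  dd <- bn_data(as.data.frame(data)[, vars, drop = FALSE],
                domains = domains,
                missing_token = attr(data, "missing_token") %||% "?")
  codes <- bn_codes(dd, vars)
  ess <- cfg$prior_ess
  cpts <- list()
  for (v in vars) {
    pa <- bn_parents(structure, v)
    st <- domains[[v]]
    r <- length(st)
    cards <- vapply(domains[pa], length, 1L)
    n_cfg <- if (length(pa)) prod(cards) else 1L
    ri <- if (length(pa)) {
      config_index(codes[, pa, drop = FALSE], cards)
    } else {
      rep.int(1L, nrow(codes))
    }
    cnt <- matrix(tabulate((ri - 1L) * r + codes[, v], nbins = n_cfg * r),
                  nrow = n_cfg, byrow = TRUE)
    den <- rowSums(cnt) + ess
    tab <- (cnt + ess / r) / den
    tab[den == 0, ] <- 1 / r        # unseen configuration, ess = 0
    cpts[[v]] <- cpt(v, pa, domains[pa], st, tab)
  }
  bayes_net(domains, structure$edges, cpts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-node fitting report
#'
#' @param net a fitted [bayes_net()].
#' @param data the fitting data.
#' @return data.frame with one row per variable: parent-configuration count,
#'   number of configurations observed in the data, and the fraction of rows
#'   estimated from the prior alone.
#' @export
fit_report <- function(net, data) {
  codes <- bn_codes(bn_restrict(data, names(net$variables)))
  out <- lapply(names(net$variables), function(v) {
    cp <- net$cpts[[v]]
    cards <- vapply(cp$parent_states, length, 1L)
    n_cfg <- if (length(cp$parents)) prod(cards) else 1L
    ri <- if (length(cp$parents)) {
      config_index(codes[, cp$parents, drop = FALSE], cards)
    } else {
      rep.int(1L, nrow(codes))
    }
    seen <- length(unique(ri))
    data.frame(variable = v, n_configs = n_cfg, n_observed = seen,
               smoothed_fraction = 1 - seen / n_cfg)
  })
  do.call(rbind, out)
}

# ---- empirical information measures ----------------------------------------

#' Empirical (conditional) mutual information from a data table
#'
#' Plug-in estimate in bits from joint relative frequencies; `0 log 0 = 0`.
#' With `given = NULL` this is plain mutual information; this utility is a
#' data-side cross-check for the model-based [cross_entropy_voi()].
#'
#' @param data a complete [bn_data()].
#' @param x,y column names.
#' @param given optional conditioning column name.
#' @return value in bits.
#' @export
empirical_mutual_info <- function(data, x, y, given = NULL) {
  n <- nrow(data)
  cols <- c(x, y, given)
  codes <- bn_codes(bn_restrict(data, cols))
  doms <- bn_domains(data)[cols]
  f <- lapply(cols, function(v)
    factor(codes[, v], levels = seq_along(doms[[v]])))
  tab <- table(f) / n
  if (is.null(given)) {
    px <- rowSums(tab); py <- colSums(tab)
    e <- tab * log2(tab / outer(px, py))
  } else {
    e <- array(0, dim(tab))
    for (k in seq_len(dim(tab)[3])) {
      sl <- tab[, , k]
      pc <- sum(sl)
      if (pc == 0) next
      px <- rowSums(sl); py <- colSums(sl)
      e[, , k] <- sl * log2(sl * pc / outer(px, py))
    }
  }
  sum(e[is.finite(e) & e != 0])
}

# ---- augmented naive Bayes --------------------------------------------------

#' Learn an augmented naive Bayes classifier
#'
#' Starts from a naive Bayes skeleton (class -> every feature) and augments
#' it with a tree of feature-feature edges: the maximum-spanning tree over
#' pairwise conditional mutual information given the class, rooted at the
#' lexicographically first feature and directed away from the root. Tree
#' edges whose conditional mutual information falls below `cmi_threshold`
#' are dropped, so weakly dependent features revert to plain naive Bayes.
#'
#' @param data a complete [bn_data()].
#' @param class_var class column name.
#' @param cfg a [fit_config()].
#' @param cmi_threshold minimum conditional mutual information (bits) for an
#'   augmenting edge to be kept (default 0: keep the whole tree).
#' @return a fitted [bayes_net()] in which the class node has no parents and
#'   an out-edge to every feature.
#' @export
learn_anb <- function(data, class_var, cfg = fit_config(),
                      cmi_threshold = 0) {
  stopifnot(class_var %in% names(data), ncol(data) >= 2)
  feats <- sort(setdiff(names(data), class_var))
  edges <- cbind(class_var, feats)
  if (length(feats) >= 2) {
    pairs <- utils::combn(feats, 2)
    w <- apply(pairs, 2, function(pr)
      empirical_mutual_info(data, pr[1], pr[2], given = class_var))
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[1, ], to = pairs[2, ], weight = -w),
      directed = FALSE, vertices = feats)
    tree <- igraph::mst(g, weights = igraph::E(g)$weight)
    te <- igraph::as_edgelist(tree)
    tw <- -igraph::E(tree)$weight
    keep <- tw >= cmi_threshold
    te <- te[keep, , drop = FALSE]
    if (nrow(te)) {
      # orient away from the lexicographically first feature via BFS on the
      # retained forest; isolated components root at their own first vertex
      adj <- split(c(te[, 2], te[, 1]), c(te[, 1], te[, 2]))
      visited <- character(0)
      directed <- NULL
      for (root in feats) {
        if (root %in% visited || is.null(adj[[root]])) next
        queue <- root
        visited <- c(visited, root)
        while (length(queue)) {
          u <- queue[1]; queue <- queue[-1]
          for (v in sort(adj[[u]] %||% character(0))) {
            if (v %in% visited) next
            directed <- rbind(directed, c(u, v))
            visited <- c(visited, v)
            queue <- c(queue, v)
          }
        }
      }
      edges <- rbind(edges, directed)
    }
  }
  structure0 <- bayes_net(bn_domains(data)[c(class_var, feats)], edges)
  fit_parameters(structure0, data, cfg)
}
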