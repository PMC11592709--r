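# ---- categorical distributions -------------------------------------------

#' Categorical distribution over named states
#'
#' A probability vector over the ordered states of one discrete variable.
#' State order is fixed at construction and all probability vectors index by
#' it, which keeps every downstream computation deterministic.
#'
#' @param states character vector of unique, non-empty state labels.
#' @param probs numeric vector of the same length; nonnegative, summing to 1
#'   within `1e-9`.
#' @return an object of class `bn_dist` with fields `states` and `probs`.
#' @export
cat_dist <- function(states, probs) {
  states <- as.character(states)
  probs <- as.numeric(probs)
  if (length(states) != length(probs)) {
    stop("states and probs must have equal length", call. = FALSE)
  }
  if (anyDuplicated(states) || any(!nzchar(states))) {
    stop("states must be unique and non-empty", call. = FALSE)
  }
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9) {
    stop("probs must be nonnegative and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  structure(list(states = states, probs = pmax(probs, 0)), class = "bn_dist")
}

#' @export
print.bn_dist <- function(x, ...) {
  cat("<categorical distribution>\n")
  print(stats::setNames(round(x$probs, 6), x$states))
  invisible(x)
}

# ---- CPTs -----------------------------------------------------------------

# Parent configurations are indexed row-major with the LAST parent cycling
# fastest; this is also the XMLBIF 0.3 TABLE convention used by the readers
# and writers, so a CPT's rows map one-to-one onto the file layout.

#' Conditional probability table
#'
#' One categorical distribution over the child's states per configuration of
#' the parents' states. Rows are ordered row-major over parent configurations
#' with the last parent cycling fastest.
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param parent_states named list of state-label vectors, one per parent.
#' @param states child state labels.
#' @param table numeric matrix, `n_configs x n_states`; each row a
#'   distribution over the child's states.
#' @return an object of class `bn_cpt`.
#' @export
cpt <- function(child, parents, parent_states, states, table) {
  table <- as.matrix(table)
  parents <- as.character(parents)
  n_cfg <- prod(vapply(parent_states, length, 1L))
  if (length(parents) == 0L) n_cfg <- 1L
  if (!identical(sort(names(parent_states)), sort(parents)) &&
      length(parents) > 0L) {
    stop("parent_states must be named by the parents", call. = FALSE)
  }
  parent_states <- parent_states[parents]
  if (nrow(table) != n_cfg || ncol(table) != length(states)) {
    stop(sprintf("CPT for '%s' must be %d x %d", child, n_cfg,
                 length(states)), call. = FALSE)
  }
  structure(list(child = child, parents = parents,
                 parent_states = parent_states,
                 states = as.character(states), table = table),
            class = "bn_cpt")
}

# strides for config indexing (last parent fastest)
config_strides <- function(cards) {
  k <- length(cards)
  if (k == 0L) return(integer(0))
  rev(cumprod(c(1, rev(cards)[-k])))
}

#' Row index of a parent configuration
#'
#' @param codes integer matrix (`n x k`) of 1-based parent state codes, in
#'   parent order.
#' @param cards integer vector of parent cardinalities.
#' @return integer vector of 1-based row indices (last parent fastest).
#' @keywords internal
config_index <- function(codes, cards) {
  if (length(cards) == 0L) return(rep.int(1L, max(1L, nrow(codes))))
  s <- config_strides(cards)
  as.integer(1 + (codes - 1L) %*% s)
}

# all parent configurations in row order; data.frame of labels
config_grid <- function(parent_states) {
  if (length(parent_states) == 0L) return(data.frame())
  g <- expand.grid(rev(parent_states), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(parent_states)), drop = FALSE]
  names(g) <- names(parent_states)
  g
}

# ---- Bayesian networks ----------------------------------------------------

#' Discrete Bayesian network
#'
#' A directed acyclic graph over categorical variables plus one CPT per
#' variable. A network may be a bare structure (`cpts = NULL`), e.g. after a
#' structural edit and before parameters are refitted.
#'
#' @param variables named list mapping each variable to its ordered state
#'   labels.
#' @param edges two-column character matrix (parent, child); may have zero
#'   rows.
#' @param cpts named list of [cpt()] objects (one per variable), or `NULL`
#'   for an unfitted structure.
#' @return an object of class `bn`.
#' @export
bayes_net <- function(variables, edges = NULL, cpts = NULL) {
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  net <- structure(list(variables = variables, edges = edges, cpts = cpts),
                   class = "bn")
  net
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("<bn: %d variables, %d edges, %s>\n", length(x$variables),
              nrow(x$edges), if (is.null(x$cpts)) "structure only" else
                "fitted"))
  invisible(x)
}

#' Parents of a variable
#' @param net a [bayes_net()].
#' @param var variable name.
#' @return character vector of parent names, in lexicographic order.
#' @export
bn_parents <- function(net, var) {
  unname(sort(net$edges[net$edges[, 2] == var, 1]))
}

#' Children of a variable
#' @inheritParams bn_parents
#' @return character vector of child names.
#' @export
bn_children <- function(net, var) {
  unname(sort(net$edges[net$edges[, 1] == var, 2]))
}

#' Validate a Bayesian network
#'
#' Checks every structural and numerical invariant: acyclicity, in-domain
#' edges, CPT coverage, CPT parent sets matching the graph, and row
#' normalization. Validation never raises; it returns a character vector of
#' violation descriptions (empty when the network is valid).
#'
#' @param net a [bayes_net()].
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_network <- function(net) {
  bad <- character(0)
  vars <- names(net$variables)
  if (anyDuplicated(vars)) bad <- c(bad, "duplicate variable names")
  for (v in vars) {
    st <- net$variables[[v]]
    if (anyDuplicated(st) || any(!nzchar(st))) {
      bad <- c(bad, sprintf("variable '%s': states not unique/non-empty", v))
    }
  }
  if (nrow(net$edges) > 0) {
    off <- !(net$edges[, 1] %in% vars) | !(net$edges[, 2] %in% vars)
    if (any(off)) bad <- c(bad, "edge endpoints outside variable set")
    if (anyDuplicated(paste(net$edges[, 1], net$edges[, 2], sep = "\r"))) {
      bad <- c(bad, "duplicate edges")
    }
  }
  ord <- tryCatch(topological_order(net), error = function(e) NULL)
  if (is.null(ord)) bad <- c(bad, "edge set contains a directed cycle")
  if (!is.null(net$cpts)) {
    missing_cpt <- setdiff(vars, names(net$cpts))
    if (length(missing_cpt)) {
      bad <- c(bad, sprintf("no CPT for variable '%s'", missing_cpt))
    }
    for (v in intersect(vars, names(net$cpts))) {
      cp <- net$cpts[[v]]
      if (!identical(sort(cp$parents), bn_parents(net, v))) {
        bad <- c(bad, sprintf("CPT parents of '%s' differ from graph in-edges", v))
        next
      }
      if (!identical(cp$states, net$variables[[v]])) {
        bad <- c(bad, sprintf("CPT states of '%s' differ from declared domain", v))
        next
      }
      rs <- rowSums(cp$table)
      off <- which(abs(rs - 1) > 1e-9 | apply(cp$table < -1e-12, 1, any))
      for (i in off) {
        bad <- c(bad, sprintf("CPT row %d of '%s' is not a distribution (sum %.6g)",
                              i, v, rs[i]))
      }
    }
  }
  bad
}

#' Topological order of the network's variables
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is
#' deterministic across runs and platforms.
#'
#' @param net a [bayes_net()].
#' @return character vector: every parent precedes every child.
#' @export
topological_order <- function(net) {
  vars <- sort(names(net$variables))
  indeg <- stats::setNames(integer(length(vars)), vars)
  if (nrow(net$edges) > 0) {
    tc <- table(net$edges[, 2])
    indeg[names(tc)] <- as.integer(tc)
  }
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  remaining <- indeg
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    remaining <- remaining[names(remaining) != v]
    out <- c(out, v)
    ch <- net$edges[net$edges[, 1] == v, 2]
    for (c0 in ch) {
      remaining[c0] <- remaining[c0] - 1L
      if (remaining[c0] == 0L) avail <- sort(c(avail, c0))
    }
  }
  if (length(out) != length(vars)) {
    stop("cycle detected: edge set is not a DAG", call. = FALSE)
  }
  out
}

is_dag <- function(variables, edges) {
  !inherits(tryCatch(
    topological_order(bayes_net(variables, edges)),
    error = function(e) e), "error")
}

# ---- evidence -------------------------------------------------------------

check_evidence <- function(net, evidence) {
  if (length(evidence) == 0L) return(invisible(TRUE))
  for (v in names(evidence)) {
    if (!v %in% names(net$variables)) {
      stop(sprintf("evidence variable '%s' not in network", v), call. = FALSE)
    }
    if (!evidence[[v]] %in% net$variables[[v]]) {
      stop(sprintf("state '%s' not in the domain of '%s'", evidence[[v]], v),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- joint probability and enumeration ------------------------------------

#' Probability of one full assignment
#'
#' Chain-rule factorization: the product over variables of the CPT entry for
#' the variable's state given its parents' states.
#'
#' @param net a fitted [bayes_net()].
#' @param assignment named character vector covering every variable.
#' @return a probability.
#' @export
joint_probability <- function(net, assignment) {
  vars <- names(net$variables)
  miss <- setdiff(vars, names(assignment))
  if (length(miss)) {
    stop(sprintf("assignment is partial; missing: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_evidence(net, assignment[vars])
  p <- 1
  for (v in vars) {
    cp <- net$cpts[[v]]
    cards <- vapply(cp$parent_states, length, 1L)
    codes <- matrix(vapply(cp$parents, function(u)
      match(assignment[[u]], cp$parent_states[[u]]), 1L), nrow = 1)
    ri <- config_index(codes, cards)
    p <- p * cp$table[ri, match(assignment[[v]], cp$states)]
  }
  unname(p)
}

#' Enumerate the full joint distribution
#'
#' Builds the complete joint table by brute force; intended as a testing
#' oracle on small networks.
#'
#' @param net a fitted [bayes_net()].
#' @param cap maximum number of joint cells (default `1e6`).
#' @return data.frame with one column per variable plus a `prob` column;
#'   probabilities sum to 1 within `1e-9`.
#' @export
enumerate_joint <- function(net, cap = 1e6) {
  vars <- topological_order(net)
  sz <- prod(vapply(net$variables, length, 1L))
  if (sz > cap) {
    stop(sprintf("joint table too large (%g cells > cap %g)", sz, cap),
         call. = FALSE)
  }
  grid <- config_grid(net$variables[vars])
  codes <- vapply(vars, function(v)
    match(grid[[v]], net$variables[[v]]), integer(nrow(grid)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(grid))
  colnames(codes) <- vars
  grid$prob <- exp(log_joint_codes(net, codes))
  grid
}

# log joint probability for a matrix of coded records (columns named by
# variable); vectorized over records; `vars` restricts to a subset of CPTs
log_joint_codes <- function(net, codes, vars = names(net$variables)) {
  n <- nrow(codes)
  lp <- numeric(n)
  for (v in vars) {
    cp <- net$cpts[[v]]
    cards <- vapply(cp$parent_states, length, 1L)
    if (length(cp$parents)) {
      ri <- config_index(codes[, cp$parents, drop = FALSE], cards)
    } else {
      ri <- rep.int(1L, n)
    }
    lp <- lp + log(cp$table[cbind(ri, codes[, v])])
  }
  lp
}

# ---- potentials (factors) for variable elimination ------------------------

pot_from_cpt <- function(cp) {
  cards <- vapply(cp$parent_states, length, 1L)
  # CPT rows: last parent fastest; flattened child-fastest gives array dims
  # (child, last parent, ..., first parent)
  vars <- c(cp$child, rev(cp$parents))
  states <- c(list(cp$states), rev(cp$parent_states))
  vals <- as.vector(t(cp$table))
  dims <- vapply(states, length, 1L)
  list(vars = vars, states = states,
       values = array(vals, dim = dims))
}

pot_expand <- function(f, vars, states) {
  extra <- setdiff(vars, f$vars)
  ord <- c(f$vars, extra)
  dims <- vapply(states[match(ord, vars)], length, 1L)
  a <- array(f$values, dim = dims)   # recycles over trailing dims
  aperm(a, match(vars, ord))
}

pot_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  states <- c(f$states, g$states[match(setdiff(g$vars, f$vars), g$vars)])
  names(states) <- NULL
  list(vars = vars, states = states,
       values = pot_expand(f, vars, states) * pot_expand(g, vars, states))
}

pot_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(list(vars = character(0), states = list(),
                values = array(sum(f$values), dim = 1L)))
  }
  vals <- apply(f$values, keep, sum)
  dims <- vapply(f$states[keep], length, 1L)
  list(vars = f$vars[keep], states = f$states[keep],
       values = array(vals, dim = dims))
}

pot_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  idx <- as.list(rep(TRUE, length(f$vars)))
  idx[[i]] <- match(state, f$states[[i]])
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(list(vars = character(0), states = list(),
                values = array(as.vector(vals), dim = 1L)))
  }
  dims <- vapply(f$states[keep], length, 1L)
  list(vars = f$vars[keep], states = f$states[keep],
       values = array(as.vector(vals), dim = dims))
}

# ancestors of a variable set (inclusive)
bn_ancestors <- function(net, vars) {
  anc <- unique(vars)
  repeat {
    pa <- unique(net$edges[net$edges[, 2] %in% anc, 1])
    new <- setdiff(pa, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  anc
}

# variable elimination over relevant potentials; returns the normalized
# potential over `targets` (in that order), or raises bn_zero_evidence
ve_query <- function(net, targets, evidence = character(0)) {
  check_evidence(net, evidence)
  if (any(targets %in% names(evidence))) {
    stop("target variables must not appear in the evidence", call. = FALSE)
  }
  relevant <- bn_ancestors(net, c(targets, names(evidence)))
  pots <- lapply(relevant, function(v) pot_from_cpt(net$cpts[[v]]))
  for (v in names(evidence)) {
    pots <- lapply(pots, pot_reduce, var = v, state = evidence[[v]])
  }
  hidden <- sort(setdiff(relevant, c(targets, names(evidence))))
  while (length(hidden)) {
    # min-degree: fewest distinct neighbors in the current factor graph
    deg <- vapply(hidden, function(h) {
      nb <- unique(unlist(lapply(pots, function(p)
        if (h %in% p$vars) p$vars else character(0))))
      length(setdiff(nb, h))
    }, 1L)
    v <- hidden[order(deg, hidden)][1]     # ties lexicographic
    hidden <- setdiff(hidden, v)
    inv <- vapply(pots, function(p) v %in% p$vars, TRUE)
    if (!any(inv)) next
    prod <- Reduce(pot_product, pots[inv])
    pots <- c(pots[!inv], list(pot_marginalize(prod, v)))
  }
  out <- Reduce(pot_product, pots)
  z <- sum(out$values)
  if (!is.finite(z) || z <= 0) {
    stop(structure(class = c("bn_zero_evidence", "error", "condition"),
                   list(message = "evidence has probability zero under the network",
                        call = NULL)))
  }
  out$values <- out$values / z
  if (length(out$vars) > 1L || !identical(out$vars, targets)) {
    perm <- match(targets, out$vars)
    out$values <- aperm(array(out$values,
                              vapply(out$states, length, 1L)), perm)
    out$states <- out$states[perm]
    out$vars <- targets
  }
  out
}

#' Exact posterior distribution of one variable
#'
#' Computes `P(target | evidence)` exactly by variable elimination with a
#' min-degree elimination heuristic (ties broken lexicographically).
#'
#' @param net a fitted [bayes_net()].
#' @param target variable name (must not be observed).
#' @param evidence named character vector of observed states (possibly
#'   empty).
#' @return a [cat_dist()] over the target's states.
#' @export
posterior <- function(net, target, evidence = character(0)) {
  if (!target %in% names(net$variables)) {
    stop(sprintf("unknown variable '%s'", target), call. = FALSE)
  }
  out <- ve_query(net, target, evidence)
  cat_dist(net$variables[[target]], as.vector(out$values))
}

#' Exact joint marginal over several variables
#'
#' @inheritParams posterior
#' @param targets character vector of variable names.
#' @return a potential-like list with `vars`, `states`, `values` (array over
#'   the targets, normalized).
#' @export
joint_marginal <- function(net, targets, evidence = character(0)) {
  ve_query(net, targets, evidence)
}

# ---- forward sampling -----------------------------------------------------

#' Forward (ancestral) sampling from a network
#'
#' Draws complete records in topological order; reproducible for a fixed
#' seed. The seed is applied locally and the caller's RNG state is restored.
#'
#' @param net a fitted [bayes_net()].
#' @param n number of records (`>= 1`).
#' @param seed integer seed.
#' @param class_var optional class-column designation carried into the
#'   returned table.
#' @return a [bn_data()] table of `n` complete records.
#' @export
sample_records <- function(net, n, seed, class_var = NULL) {
  stopifnot(n >= 1)
  ord <- topological_order(net)
  codes <- matrix(0L, nrow = n, ncol = length(ord),
                  dimnames = list(NULL, ord))
  with_local_seed(seed, {
    for (v in ord) {
      cp <- net$cpts[[v]]
      cards <- vapply(cp$parent_states, length, 1L)
      if (length(cp$parents)) {
        ri <- config_index(codes[, cp$parents, drop = FALSE], cards)
      } else {
        ri <- rep.int(1L, n)
      }
      cum <- t(apply(cp$table, 1, cumsum))
      u <- stats::runif(n)
      code <- rowSums(u > cum[ri, , drop = FALSE]) + 1L
      codes[, v] <- pmin(code, length(cp$states))
    }
  })
  df <- as.data.frame(lapply(ord, function(v)
    net$variables[[v]][codes[, v]]), col.names = ord,
    stringsAsFactors = FALSE)
  bn_data(df, domains = net$variables[ord], class_var = class_var)
}

# run code under a local seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
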