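# fixture builders shared across the suite; everything is constructed in code

# a -> b -> c chain with fixed CPTs
chain_net <- function() {
  vars <- list(a = c("t", "f"), b = c("t", "f"), c = c("t", "f"))
  edges <- rbind(c("a", "b"), c("b", "c"))
  cpts <- list(
    a = cpt("a", character(0), list(), vars$a, matrix(c(0.3, 0.7), 1)),
    b = cpt("b", "a", vars["a"], vars$b,
            matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)),
    c = cpt("c", "b", vars["b"], vars$c,
            matrix(c(0.6, 0.4, 0.25, 0.75), 2, byrow = TRUE)))
  bayes_net(vars, edges, cpts)
}

# class c uniform binary; f1 a deterministic copy of c; f2 independent
copy_net <- function() {
  vars <- list(c = c("t", "f"), f1 = c("t", "f"), f2 = c("t", "f"))
  edges <- rbind(c("c", "f1"))
  cpts <- list(
    c = cpt("c", character(0), list(), vars$c, matrix(c(0.5, 0.5), 1)),
    f1 = cpt("f1", "c", vars["c"], vars$f1,
             matrix(c(1, 0, 0, 1), 2, byrow = TRUE)),
    f2 = cpt("f2", character(0), list(), vars$f2,
             matrix(c(0.7, 0.3), 1)))
  bayes_net(vars, edges, cpts)
}

# random fitted net: random sparse DAG over n_vars variables with 2..max_card
# states and Dirichlet(1) CPT rows
random_net <- function(n_vars, max_card = 3, seed = 1, max_parents = 3) {
  set.seed(seed)
  vars_n <- sprintf("v%02d", seq_len(n_vars))
  domains <- lapply(vars_n, function(v)
    paste0("s", seq_len(1L + sample.int(max_card - 1L, 1))))
  names(domains) <- vars_n
  edges <- NULL
  for (i in seq_len(n_vars)[-1]) {
    k <- sample(0:min(i - 1, max_parents), 1)
    if (k > 0) {
      for (p in sample(vars_n[seq_len(i - 1)], k)) {
        edges <- rbind(edges, c(p, vars_n[i]))
      }
    }
  }
  net0 <- bayes_net(domains, edges)
  cpts <- lapply(vars_n, function(v) {
    pa <- bn_parents(net0, v)
    r <- length(domains[[v]])
    n_cfg <- if (length(pa)) prod(lengths(domains[pa])) else 1L
    tab <- t(vapply(seq_len(n_cfg), function(i) {
      g <- rgamma(r, 1)
      g / sum(g)
    }, numeric(r)))
    cpt(v, pa, domains[pa], domains[[v]], tab)
  })
  names(cpts) <- vars_n
  bayes_net(domains, edges, cpts)
}

# random connected-ish DAG structure (no CPTs) with exactly m edges
random_dag <- function(n_vars, m, seed = 1) {
  set.seed(seed)
  vars_n <- sprintf("v%02d", seq_len(n_vars))
  pairs <- t(combn(n_vars, 2))           # i < j: edge v_i -> v_j is acyclic
  pick <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  edges <- cbind(vars_n[pick[, 1]], vars_n[pick[, 2]])
  bayes_net(setNames(rep(list(c("t", "f")), n_vars), vars_n), edges)
}

# oracle: posterior of `target` given evidence, from the enumerated joint
oracle_posterior <- function(net, target, evidence = character(0)) {
  ej <- enumerate_joint(net)
  keep <- rep(TRUE, nrow(ej))
  for (v in names(evidence)) keep <- keep & ej[[v]] == evidence[[v]]
  sl <- ej[keep, ]
  m <- tapply(sl$prob, factor(sl[[target]], levels = net$variables[[target]]),
              sum)
  m[is.na(m)] <- 0
  as.numeric(m / sum(m))
}

# oracle: mutual information between two variables, by direct summation over
# the enumerated joint's (x, y) margin
oracle_mi <- function(net, x, y) {
  ej <- enumerate_joint(net)
  pxy <- tapply(ej$prob, list(factor(ej[[x]], levels = net$variables[[x]]),
                              factor(ej[[y]], levels = net$variables[[y]])),
                sum)
  pxy[is.na(pxy)] <- 0
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log2(pxy / outer(px, py))
  sum(terms[is.finite(terms) & pxy > 0])
}

# scenario used by several simulation tests: small, binary-ish, informative
small_scenario <- function(seed = 42L, n_records = 500L) {
  scenario_spec(n_nodes = 8, n_classes = 2, prevalence = c(0.7, 0.3),
                cardinality_range = c(2, 3), edge_density = 1.5,
                effect_strength = 2, n_records = n_records, seed = seed)
}

make_gold <- function(spec) {
  net <- generate_gold_network(spec)
  data <- replace_missing(generate_dataset(net, spec))
  gold <- fit_parameters(bayes_net(bn_domains(data), net$edges), data,
                         fit_config(1))
  list(net = net, data = data, gold = gold)
}
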