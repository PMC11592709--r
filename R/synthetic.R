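# ---- synthetic diagnostic scenarios -------------------------------------------

#' Scenario specification for synthetic gold standards
#'
#' Describes the shape of a diagnostic problem: one class (diagnosis) node
#' with a skewed prevalence over `n_classes` states, plus categorical feature
#' (symptom/finding) nodes. The defaults of the eight [scenario_presets()]
#' mirror the shapes of small public medical data sets: 10-35 variables with
#' 2-6 states, 100-2200 records, 2-20 classes, and at most 5% missing values.
#'
#' @param n_nodes total variable count including the class node (`>= 2`).
#' @param n_classes number of class states.
#' @param prevalence probability vector over classes (normalized if needed).
#' @param cardinality_range integer `(min, max)` states per feature
#'   (`min >= 2`).
#' @param edge_density target mean in-degree (edges per node).
#' @param effect_strength nonnegative sharpness of feature CPTs: 0 makes all
#'   rows of a CPT identical (completely uninformative features); larger
#'   values make rows sharper and more distinct, hence more informative.
#' @param n_records number of sampled records.
#' @param missing_rate fraction of feature cells replaced by the missing
#'   token, in `[0, 0.05]`.
#' @param max_parents per-feature parent cap (keeps CPTs tractable).
#' @param seed integer seed; the whole scenario is reproducible from it.
#' @return a list of class `bn_scenario`.
#' @export
scenario_spec <- function(n_nodes, n_classes, prevalence,
                          cardinality_range = c(2, 4), edge_density = 1.5,
                          effect_strength = 2, n_records = 500,
                          missing_rate = 0, max_parents = 4, seed = 1L) {
  stopifnot(n_nodes >= 2, n_classes >= 2,
            length(prevalence) == n_classes,
            all(prevalence > 0),
            cardinality_range[1] >= 2,
            cardinality_range[2] >= cardinality_range[1],
            edge_density >= 0, effect_strength >= 0, n_records >= 1,
            missing_rate >= 0, missing_rate <= 0.05, max_parents >= 1)
  prevalence <- prevalence / sum(prevalence)
  structure(list(n_nodes = n_nodes, n_classes = n_classes,
                 prevalence = prevalence,
                 cardinality_range = cardinality_range,
                 edge_density = edge_density,
                 effect_strength = effect_strength, n_records = n_records,
                 missing_rate = missing_rate, max_parents = max_parents,
                 seed = as.integer(seed)),
            class = "bn_scenario")
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))   # degenerate tiny-alpha draw
  g / sum(g)
}

#' Generate a synthetic gold-standard diagnostic network
#'
#' The class node is a root with the specified prevalence as its prior.
#' Features are layered in index order (a valid topological order by
#' construction); parent slots are drawn without replacement from the
#' candidate (predecessor, feature) pairs until the target edge count
#' `round(edge_density * n_nodes)` is reached, with class-to-feature
#' candidates weighted three times higher than feature-to-feature ones
#' (symptoms depend primarily on the diagnosis) and a per-feature parent cap.
#' Feature CPT rows are a mixture `(1 - w) * base + w * sharp` with
#' `w = s / (1 + s)`: at `effect_strength s = 0` every row equals the
#' CPT's base row (no information flows anywhere), and as `s` grows the rows
#' are dominated by sharp Dirichlet draws with concentration `1 / (1 + s)`.
#'
#' @param spec a [scenario_spec()].
#' @return a fitted [bayes_net()] whose first variable is `"class"`.
#' @export
generate_gold_network <- function(spec) {
  n_feat <- spec$n_nodes - 1L
  feats <- sprintf("f%02d", seq_len(n_feat))
  vars <- c("class", feats)
  n_edges <- round(spec$edge_density * spec$n_nodes)
  capacity <- sum(pmin(seq_len(n_feat), spec$max_parents))
  if (n_edges > capacity) {
    stop(sprintf("edge_density %.2f infeasible: %d edges requested, %d possible",
                 spec$edge_density, n_edges, capacity), call. = FALSE)
  }
  with_local_seed(spec$seed, {
    card_pool <- seq(spec$cardinality_range[1], spec$cardinality_range[2])
    # index-based draw: sample(x, ...) on a length-1 pool would draw from 1:x
    cards <- card_pool[sample.int(length(card_pool), n_feat, replace = TRUE)]
    domains <- c(list(class = paste0("c", seq_len(spec$n_classes))),
                 stats::setNames(lapply(cards, function(r)
                   paste0("s", seq_len(r))), feats))
    # candidate (predecessor, feature) pairs, class-child pairs upweighted
    cand <- do.call(rbind, lapply(seq_len(n_feat), function(i) {
      preds <- c("class", feats[seq_len(i - 1L)])
      data.frame(parent = preds, child = feats[i],
                 w = ifelse(preds == "class", 3, 1),
                 stringsAsFactors = FALSE)
    }))
    npar <- stats::setNames(integer(n_feat), feats)
    edges <- matrix(character(0), ncol = 2)
    while (nrow(edges) < n_edges && nrow(cand) > 0) {
      i <- sample.int(nrow(cand), 1, prob = cand$w)
      edges <- rbind(edges, c(cand$parent[i], cand$child[i]))
      ch <- cand$child[i]
      npar[ch] <- npar[ch] + 1L
      cand <- cand[-i, , drop = FALSE]
      if (npar[ch] >= spec$max_parents) cand <- cand[cand$child != ch, ,
                                                     drop = FALSE]
    }
    net0 <- bayes_net(domains, edges)
    w <- spec$effect_strength / (1 + spec$effect_strength)
    a_sharp <- 1 / (1 + spec$effect_strength)
    cpts <- list(class = cpt("class", character(0), list(),
                             domains$class,
                             matrix(spec$prevalence, nrow = 1)))
    for (v in feats) {
      pa <- bn_parents(net0, v)
      r <- length(domains[[v]])
      n_cfg <- if (length(pa)) prod(vapply(domains[pa], length, 1L)) else 1L
      base <- rdirichlet1(rep(1, r))
      tab <- t(vapply(seq_len(n_cfg), function(k)
        (1 - w) * base + w * rdirichlet1(rep(a_sharp, r)),
        numeric(r)))
      cpts[[v]] <- cpt(v, pa, domains[pa], domains[[v]], tab)
    }
    net <- bayes_net(domains, edges, cpts)
    stopifnot(length(validate_network(net)) == 0)
    net
  })
}

#' Sample a record table from a gold standard, with optional missingness
#'
#' Forward-samples `spec$n_records` complete records and then blanks
#' `spec$missing_rate` of the feature cells completely at random (the class
#' column is never missing).
#'
#' @param net a fitted [bayes_net()] (typically [generate_gold_network()]).
#' @param spec the [scenario_spec()].
#' @return a [bn_data()] with `class_var = "class"`.
#' @export
generate_dataset <- function(net, spec) {
  data <- sample_records(net, spec$n_records, seed = spec$seed,
                         class_var = "class")
  if (spec$missing_rate > 0) {
    feats <- setdiff(names(data), "class")
    df <- as.data.frame(data)
    with_local_seed(spec$seed + 1L, {
      for (v in feats) {
        hit <- stats::runif(nrow(df)) < spec$missing_rate
        df[[v]][hit] <- attr(data, "missing_token")
      }
    })
    data <- bn_data(df, domains = bn_domains(data), class_var = "class",
                    missing_token = attr(data, "missing_token"))
  }
  data
}

#' Replace missing values by a dedicated absent/normal state
#'
#' Every missing cell becomes a per-variable state (default label
#' `"absent_or_normal"`), appended to the column's domain when the column
#' actually contains missing cells; columns without missing cells keep their
#' domains unchanged. The output has no missing cells and can be fitted
#' directly.
#'
#' @param data a [bn_data()].
#' @param label the replacement state label.
#' @return a complete [bn_data()].
#' @export
replace_missing <- function(data, label = "absent_or_normal") {
  miss <- attr(data, "missing_token")
  df <- as.data.frame(data)
  domains <- bn_domains(data)
  for (v in names(df)) {
    hit <- df[[v]] == miss
    if (any(hit)) {
      df[[v]][hit] <- label
      if (!label %in% domains[[v]]) domains[[v]] <- c(domains[[v]], label)
    }
  }
  bn_data(df, domains = domains, class_var = bn_class_var(data),
          missing_token = miss)
}

#' Preset scenarios shaped like small public medical data sets
#'
#' Eight presets whose node counts, class counts, record counts, prevalence
#' vectors, edge densities, and missing rates mirror widely used categorical
#' diagnostic benchmarks (breast cancer recurrence, cardiotocography,
#' dermatology, hepatitis C, hepatitis, lymphography, primary tumor, SPECT
#' heart). Structures and CPTs are synthetic; only the shapes are emulated.
#'
#' @return named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function() {
  list(
    `breast-cancer-like` = scenario_spec(
      n_nodes = 10, n_classes = 2, prevalence = c(0.703, 0.297),
      cardinality_range = c(2, 6), edge_density = 1.40, n_records = 286,
      missing_rate = 0.0031, seed = 101L),
    `cardiotocography-like` = scenario_spec(
      n_nodes = 22, n_classes = 3, prevalence = c(0.778, 0.139, 0.083),
      cardinality_range = c(2, 4), edge_density = 2.86, n_records = 2126,
      missing_rate = 0, seed = 102L),
    `dermatology-like` = scenario_spec(
      n_nodes = 35, n_classes = 6,
      prevalence = c(0.306, 0.197, 0.167, 0.142, 0.134, 0.055),
      cardinality_range = c(2, 5), edge_density = 0.83, n_records = 366,
      missing_rate = 0.0006, seed = 103L),
    `hcv-like` = scenario_spec(
      n_nodes = 13, n_classes = 5,
      prevalence = c(0.867, 0.049, 0.039, 0.034, 0.011),
      cardinality_range = c(2, 4), edge_density = 1.38, n_records = 615,
      missing_rate = 0.002, seed = 104L),
    `hepatitis-like` = scenario_spec(
      n_nodes = 20, n_classes = 2, prevalence = c(0.792, 0.208),
      cardinality_range = c(2, 3), edge_density = 1.90, n_records = 155,
      missing_rate = 0.05, seed = 105L),
    `lymphography-like` = scenario_spec(
      n_nodes = 19, n_classes = 4,
      prevalence = c(0.545, 0.411, 0.029, 0.015),
      cardinality_range = c(2, 4), edge_density = 1.05, n_records = 148,
      missing_rate = 0, seed = 106L),
    `primary-tumor-like` = scenario_spec(
      n_nodes = 18, n_classes = 20,
      prevalence = c(0.248, 0.115, 0.086, 0.083, 0.071, 0.071, 0.059,
                     0.047, 0.041, 0.041, 0.029, 0.027, 0.024, 0.021,
                     0.018, 0.006, 0.006, 0.003, 0.003, 0.003),
      cardinality_range = c(2, 3), edge_density = 1.83, n_records = 339,
      missing_rate = 0.037, seed = 107L),
    `spect-heart-like` = scenario_spec(
      n_nodes = 23, n_classes = 2, prevalence = c(0.794, 0.206),
      cardinality_range = c(2, 2), edge_density = 2.26, n_records = 267,
      missing_rate = 0, seed = 108L)
  )
}
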