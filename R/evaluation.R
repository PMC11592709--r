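# ---- diagnostic-accuracy measurement -----------------------------------------

#' Most prevalent class in a data table
#'
#' The class state with the highest empirical frequency; ties break
#' lexicographically. This state is the one-vs-rest positive class for every
#' AUC curve, fixed once from the gold-standard data so curves along a
#' trajectory stay comparable.
#'
#' @param data a nonempty [bn_data()].
#' @param class_var class column name.
#' @return a state label.
#' @export
most_prevalent_class <- function(data, class_var) {
  if (nrow(data) == 0) stop("empty data table", call. = FALSE)
  tab <- table(data[[class_var]])
  names(tab)[order(-tab, names(tab))][1]
}

#' Classify records with a (possibly mutilated) network
#'
#' For every record, the evidence is the record's value on every non-class
#' variable present in the current network (columns for removed nodes are
#' ignored). The prediction is the argmax of the exact class posterior, with
#' ties broken by higher prior then lexicographically; the score is the
#' posterior probability of the designated positive class. Records whose
#' evidence has probability zero under the network fall back to the class
#' prior (counted, never an error).
#'
#' Because the evidence instantiates every non-class variable, the class
#' posterior is proportional to the chain-rule joint, which is what is
#' computed here (in log space); it agrees with variable elimination exactly.
#'
#' @param net a fitted [bayes_net()] containing `class_var`.
#' @param data a complete [bn_data()] covering the network's variables.
#' @param class_var class variable name.
#' @param positive designated positive class; defaults to the most prevalent
#'   class of `data`.
#' @return data.frame of class `bn_scored` with columns `true_class`,
#'   `predicted_class`, `score`; attributes `positive` and `n_fallbacks`.
#' @export
predict_records <- function(net, data, class_var,
                            positive = most_prevalent_class(data, class_var)) {
  stopifnot(class_var %in% names(net$variables))
  vars <- names(net$variables)
  feats <- setdiff(vars, class_var)
  n <- nrow(data)
  cls_states <- net$variables[[class_var]]
  K <- length(cls_states)
  dd <- bn_data(cbind(as.data.frame(data)[, feats, drop = FALSE],
                      stats::setNames(data.frame(rep(cls_states[1], n),
                                                 stringsAsFactors = FALSE),
                                      class_var)),
                domains = net$variables[c(feats, class_var)],
                missing_token = attr(data, "missing_token") %||% "?")
  codes <- bn_codes(dd, vars)
  # only the CPTs of the class and of the class's children depend on the
  # class state; every other factor of the chain-rule joint cancels in the
  # posterior. Dropping them structurally (not numerically) makes records
  # with identical class posteriors bitwise-tied, which the midrank AUC
  # convention requires.
  dep_vars <- unique(c(class_var, net$edges[net$edges[, 1] == class_var, 2]))
  indep_vars <- setdiff(vars, dep_vars)
  lp0 <- log_joint_codes(net, codes, indep_vars)
  L <- matrix(-Inf, n, K)
  for (k in seq_len(K)) {
    codes[, class_var] <- k
    L[, k] <- log_joint_codes(net, codes, dep_vars)
  }
  finite <- is.finite(L)
  fallback <- !apply(finite, 1, any) | !is.finite(lp0)
  refk <- max.col(finite, ties.method = "first")
  ref <- L[cbind(seq_len(n), refk)]
  t0 <- L - ref
  t0[!finite] <- -Inf
  m <- apply(t0, 1, max)
  P <- exp(t0 - ifelse(is.finite(m), m, 0))
  P[fallback, ] <- 1
  prior <- posterior(net, class_var)$probs
  if (any(fallback)) {
    P[fallback, ] <- matrix(prior, sum(fallback), K, byrow = TRUE)
  }
  P <- P / rowSums(P)
  # argmax with ties to higher prior, then lexicographic: order the columns
  # that way once, then take the first maximum
  col_ord <- order(-prior, cls_states)
  pred <- cls_states[col_ord][max.col(P[, col_ord, drop = FALSE],
                                      ties.method = "first")]
  structure(data.frame(true_class = data[[class_var]],
                       predicted_class = pred,
                       score = P[, match(positive, cls_states)]),
            positive = positive, n_fallbacks = sum(fallback),
            class = c("bn_scored", "data.frame"))
}

#' Classification accuracy
#'
#' Proportion of records whose predicted class equals the true class.
#'
#' @param scored a [predict_records()] result (or any data.frame with
#'   `true_class` and `predicted_class`).
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(scored) {
  if (nrow(scored) == 0) stop("empty scored set", call. = FALSE)
  mean(scored$predicted_class == scored$true_class)
}

#' One-vs-rest ROC curve and AUC
#'
#' Labels are `true_class == positive`. The curve thresholds the scores with
#' ties grouped at one threshold, so it runs from (0,0) to (1,1); the AUC is
#' the trapezoidal area, which under this tie-grouping equals the
#' Mann-Whitney rank-sum statistic with ties contributing 1/2. A constant
#' scorer therefore yields exactly 0.5.
#'
#' @param scored a [predict_records()] result.
#' @param positive positive state label; defaults to the scored set's
#'   designated class.
#' @return an object of class `bn_roc`: list with `points` (data.frame of
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scored, positive = attr(scored, "positive")) {
  y <- scored$true_class == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("degenerate labels: both positive and non-positive records are required",
         call. = FALSE)
  }
  s <- scored$score
  ord <- order(-s)
  sy <- y[ord]; ss <- s[ord]
  grp <- cumsum(!duplicated(ss))           # tie groups, descending score
  tp <- cumsum(sy); fp <- cumsum(!sy)
  last <- which(grp != c(grp[-1], -1))     # last index of each group
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "bn_roc")
}

#' @export
print.bn_roc <- function(x, ...) {
  cat(sprintf("<ROC: %d points, AUC = %.6f>\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Evaluate a model on a data table (resubstitution)
#'
#' @inheritParams predict_records
#' @return list with `n_records`, `acc`, `designated_class`, `auc`,
#'   `n_zero_evidence_fallbacks`, and the `roc` object.
#' @export
evaluate_model <- function(net, data, class_var,
                           positive = most_prevalent_class(data, class_var)) {
  scored <- predict_records(net, data, class_var, positive)
  roc <- roc_and_auc(scored, positive)
  list(n_records = nrow(data), acc = accuracy(scored),
       designated_class = positive, auc = roc$auc,
       n_zero_evidence_fallbacks = attr(scored, "n_fallbacks"),
       roc = roc)
}
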