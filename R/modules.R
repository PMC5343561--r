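#' Cross-validated classifier AUC of a gene set
#'
#' Evaluates how well a module's genes separate cases from controls.
#' Leave-one-out cross-validation over samples: per fold, a linear
#' support-vector machine (cost 1) is trained on the module genes, with
#' features standardized using training-fold statistics; the held-out
#' decision values, pooled across folds and oriented so larger means more
#' case-like, are scored against the true labels with the rank-sum
#' (Mann-Whitney) AUC. Deterministic for a fixed input.
#'
#' @param genes Character vector of module gene ids (subset of the
#'   expression genes).
#' @param expr An [expression_dataset()].
#' @param labels Optional replacement label factor/vector (used by the
#'   permutation test); defaults to `expr$labels`.
#' @param cost SVM regularization constant; default 1.
#' @return AUC in `[0, 1]`, with the pooled held-out decision values as
#'   attribute `"decision_values"`.
#' @export
#' @examples
#' sim <- simulate_egonet_data(synthetic_config(n_genes = 50, seed = 3))
#' module_auc(sim$truth$planted_genes, sim$expression)
module_auc <- function(genes, expr, labels = NULL, cost = 1) {
  stopifnot(inherits(expr, "expression_dataset"))
  if (!length(genes)) stop("empty gene set")
  miss <- setdiff(genes, rownames(expr$values))
  if (length(miss))
    stop("module gene not in expression data: ",
         paste(head(miss, 5), collapse = ", "))
  if (is.null(labels)) labels <- expr$labels
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (any(table(labels) == 0))
    stop("both classes must be present to define an AUC")
  x <- t(expr$values[genes, , drop = FALSE])  # samples x genes
  n <- nrow(x)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(x[tr, , drop = FALSE])
    sdev <- apply(x[tr, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    xte <- (x[i, ] - mu) / sdev
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    d <- attr(predict(fit, matrix(xte, 1), decision.values = TRUE),
              "decision.values")
    # libsvm orients decision values toward the first training label;
    # flip so positive always means case-like
    dv[i] <- if (startsWith(colnames(d)[1], "case")) d[1] else -d[1]
  }
  auc <- rank_sum_auc(dv, labels == "case")
  attr(auc, "decision_values") <- setNames(dv, rownames(x))
  auc
}

# Mann-Whitney AUC of scores for the positive class (ties count 1/2)
rank_sum_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grow a candidate module around an ego gene
#'
#' Greedy expansion: starting from the ego gene alone, each step evaluates
#' every network neighbour of the current module and adds the one giving
#' the largest AUC change (ties broken by higher z-score, then gene id).
#' By default the expansion accepts AUC-neutral additions and stops only
#' when every available neighbour strictly drops the AUC (or the frontier
#' is empty, or the size cap is reached): with few samples the
#' cross-validated AUC is coarse and saturates quickly, and neutral
#' additions let the module absorb the rest of a tightly co-expressed
#' neighbourhood rather than freeze at the first saturating gene. Set
#' `allow_plateau = FALSE` to accept strictly improving additions only.
#'
#' @param ego Ego gene id; must be a network node.
#' @param den An [interaction_network()] (the DEN).
#' @param expr An [expression_dataset()] covering the network genes.
#' @param z Optional named numeric z-scores used for tie-breaking (from
#'   [topology_scores()]); missing genes count as 0.
#' @param size_cap Maximum module size; default 30.
#' @param allow_plateau Accept additions that keep the AUC unchanged;
#'   default `TRUE`.
#' @param module_id Identifier stored in the result; default `"M1"`.
#' @param cost SVM cost passed to [module_auc()].
#' @return An object of class `candidate_module`: list with `module_id`,
#'   `ego_gene`, `genes` (insertion order, ego first), `auc`, and `trace`
#'   (data frame of accepted steps: `gene`, `auc`).
#' @export
expand_ego <- function(ego, den, expr, z = NULL, size_cap = 30,
                       allow_plateau = TRUE, module_id = "M1", cost = 1) {
  stopifnot(inherits(den, "interaction_network"))
  if (!ego %in% den$nodes) stop("ego gene '", ego, "' is not a network node")
  if (is.null(z)) z <- setNames(numeric(0), character(0))
  zval <- function(g) ifelse(is.na(z[g]), 0, z[g])

  nbrs <- split(c(den$edges$b, den$edges$a), c(den$edges$a, den$edges$b))
  module <- ego
  auc <- as.numeric(module_auc(module, expr, cost = cost))
  trace <- data.frame(gene = ego, auc = auc, stringsAsFactors = FALSE)
  while (length(module) < size_cap) {
    frontier <- setdiff(unique(unlist(nbrs[module], use.names = FALSE)),
                        module)
    if (!length(frontier)) break
    aucs <- vapply(frontier, function(u)
      as.numeric(module_auc(c(module, u), expr, cost = cost)), 1)
    delta <- aucs - auc
    best <- order(-delta, -zval(frontier), frontier)[1]
    accept <- if (allow_plateau) delta[best] >= -1e-9 else delta[best] > 1e-9
    if (!accept) break
    module <- c(module, frontier[best])
    auc <- unname(aucs[best])
    trace <- rbind(trace, data.frame(gene = frontier[best], auc = auc,
                                     stringsAsFactors = FALSE))
  }
  structure(list(module_id = module_id, ego_gene = ego, genes = module,
                 auc = auc, trace = trace),
            class = "candidate_module")
}

#' @export
print.candidate_module <- function(x, ...) {
  cat(sprintf("candidate_module %s: ego %s, %d gene(s), AUC %.3f\n",
              x$module_id, x$ego_gene, length(x$genes), x$auc))
  invisible(x)
}

#' Filter candidate modules into ego modules
#'
#' Keeps candidates with `auc >= auc_threshold` and at least
#' `size_threshold` genes (both inclusive), preserving order.
#'
#' @param candidates List of `candidate_module` objects.
#' @param auc_threshold Minimum AUC; default 0.8.
#' @param size_threshold Minimum gene count; default 4.
#' @return The retained sublist.
#' @export
filter_modules <- function(candidates, auc_threshold = 0.8,
                           size_threshold = 4) {
  keep <- vapply(candidates, function(m)
    m$auc >= auc_threshold && length(m$genes) >= size_threshold, TRUE)
  candidates[keep]
}
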