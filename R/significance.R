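#' Permutation test of a module's classifier AUC
#'
#' Permutes the sample labels uniformly at random `B` times (module genes
#' fixed), recomputes the cross-validated AUC for each permutation, and
#' reports the add-one Monte-Carlo p-value
#' `(#\{permuted AUC >= observed\} + 1) / (B + 1)`. Deterministic for a
#' fixed seed.
#'
#' @param module A `candidate_module` from [expand_ego()] (or any list with
#'   `module_id`, `genes`, `auc`).
#' @param expr An [expression_dataset()].
#' @param B Number of permutations; default 1000.
#' @param seed Integer seed for the permutation stream.
#' @param cost SVM cost passed to [module_auc()].
#' @return List of class `permutation_result`: `module_id`, `observed_auc`,
#'   `permuted_aucs` (length `B`), `p_perm`, `seed`.
#' @export
permutation_test <- function(module, expr, B = 1000, seed = 1L, cost = 1) {
  stopifnot(B >= 1)
  genes <- module$genes
  observed <- module$auc %||% as.numeric(module_auc(genes, expr, cost = cost))
  labels <- expr$labels
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      as.numeric(module_auc(genes, expr, labels = sample(labels),
                            cost = cost))
    }, 1)
  })
  p <- (sum(perm >= observed - 1e-12) + 1) / (B + 1)
  structure(list(module_id = module$module_id, observed_auc = observed,
                 permuted_aucs = perm, p_perm = p, seed = seed),
            class = "permutation_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Flag significant modules
#'
#' Strict threshold: a module is significant when its adjusted p-value is
#' below `alpha` (adjusted p exactly equal to `alpha` is not significant).
#'
#' @param p_adj Numeric vector of adjusted p-values.
#' @param alpha Significance level; default 0.05.
#' @return Logical vector.
#' @export
call_significant <- function(p_adj, alpha = 0.05) {
  as.numeric(p_adj) < alpha
}
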