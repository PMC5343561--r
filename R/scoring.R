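#' Symmetrically normalized weighted adjacency of a network
#'
#' Computes `A = D^(-1/2) W D^(-1/2)` where `W` is the weighted adjacency
#' matrix (weights are `|pcc|` for a differential expression network) and
#' `D = diag(d_i)` with `d_i` the sum of incident edge weights. `A` is
#' symmetric with entries in `[0, 1]` and spectral radius at most 1.
#'
#' @param den An [interaction_network()], typically from [extract_den()];
#'   must have at least one edge (hence no isolated nodes).
#' @return A symmetric numeric matrix with node dimnames.
#' @export
normalized_adjacency <- function(den) {
  stopifnot(inherits(den, "interaction_network"))
  if (!nrow(den$edges)) stop("network has no edges")
  nodes <- den$nodes
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  w[cbind(den$edges$a, den$edges$b)] <- den$edges$weight
  w[cbind(den$edges$b, den$edges$a)] <- den$edges$weight
  d <- rowSums(w)
  inv_sqrt_d <- 1 / sqrt(d)
  a <- w * (inv_sqrt_d %o% inv_sqrt_d)
  a
}

#' Topology scores and z-scores for network genes
#'
#' Scores every network gene by `f_i = sum_{j in N(i)} A_ij * s_j`, where
#' `A` is the normalized weighted adjacency and `s_j` is the gene's base
#' importance — by default the absolute Welch t-statistic of differential
#' expression (case vs control). A node therefore scores highly when it has
#' many strongly connected, strongly differential neighbours. Scores are
#' standardized to z-scores (sample SD) across the network's nodes.
#'
#' @param den An [interaction_network()] (the DEN).
#' @param a Matrix from [normalized_adjacency()] for `den`; computed if
#'   `NULL`.
#' @param expr An [expression_dataset()] covering the network genes.
#' @param importance Optional named numeric vector overriding `s`; defaults
#'   to the absolute differential-expression Welch t-statistic.
#' @return A data frame (`gene`, `d`, `s`, `f`, `z`, `is_ego`) sorted by
#'   decreasing `z` (ties: higher `d`, then gene id); `is_ego` is `NA` until
#'   [select_ego_genes()] is applied.
#' @export
topology_scores <- function(den, a = NULL, expr, importance = NULL) {
  stopifnot(inherits(den, "interaction_network"))
  if (is.null(a)) a <- normalized_adjacency(den)
  nodes <- rownames(a)
  if (is.null(importance)) {
    miss <- setdiff(nodes, rownames(expr$values))
    if (length(miss))
      stop("network gene not in expression data: ",
           paste(head(miss, 5), collapse = ", "))
    importance <- abs(welch_t(expr$values[nodes, , drop = FALSE],
                              expr$labels == "case"))
  }
  s <- importance[nodes]
  f <- as.numeric(a %*% s)
  d <- rowSums_weights(den)[nodes]
  sd_f <- sd(f)
  if (length(f) > 1 && sd_f > 0) {
    z <- (f - mean(f)) / sd_f
  } else {
    warning("degenerate topology scores (all equal); z set to 0")
    z <- rep(0, length(f))
  }
  out <- data.frame(gene = nodes, d = as.numeric(d), s = as.numeric(s),
                    f = f, z = z, is_ego = NA, stringsAsFactors = FALSE)
  out <- out[order(-out$z, -out$d, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized Welch two-sample t statistic, rows of x split by 'case'
welch_t <- function(x, case) {
  n1 <- sum(case); n0 <- sum(!case)
  x1 <- x[, case, drop = FALSE]; x0 <- x[, !case, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  t <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  t[!is.finite(t)] <- 0
  t
}

rowSums_weights <- function(net) {
  d <- setNames(numeric(length(net$nodes)), net$nodes)
  agg_a <- tapply(net$edges$weight, net$edges$a, sum)
  agg_b <- tapply(net$edges$weight, net$edges$b, sum)
  d[names(agg_a)] <- d[names(agg_a)] + agg_a
  d[names(agg_b)] <- d[names(agg_b)] + agg_b
  d
}

#' Select ego genes from a score table
#'
#' Takes the top `max(1, floor(fraction * n))` genes by z-score; ties at the
#' cut are broken by higher weighted degree `d`, then lexicographic gene id
#' (the table's sort order). With the default 5% fraction a 149-node network
#' yields 7 ego genes.
#'
#' @param table Data frame from [topology_scores()].
#' @param fraction Top fraction to keep; default 0.05.
#' @return The input table with `is_ego` filled in; ego rows first.
#' @export
select_ego_genes <- function(table, fraction = 0.05) {
  if (!nrow(table)) stop("empty score table")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  k <- max(1L, floor(fraction * nrow(table)))
  ord <- order(-table$z, -table$d, table$gene)
  table <- table[ord, , drop = FALSE]
  table$is_ego <- seq_len(nrow(table)) <= k
  rownames(table) <- NULL
  table
}
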