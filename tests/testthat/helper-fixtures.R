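# Shared fixture builders: everything is generated in code, nothing on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_expr <- function(values, labels) {
  expression_dataset(values, labels)
}

# small two-group dataset where gene "SEP" separates the groups perfectly
separable_expr <- function(n_case = 5, n_control = 4, seed = 42) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("SEP", "N1", "N2"),
                              sprintf("S%02d", 1:n)))
  m["SEP", ] <- c(rnorm(n_case, 10, 0.2), rnorm(n_control, 0, 0.2))
  expression_dataset(m, c(rep("case", n_case), rep("control", n_control)))
}

# deterministic tiny network from a two-column matrix of edges
toy_net <- function(edges, weights = NULL, nodes = NULL) {
  df <- data.frame(a = edges[, 1], b = edges[, 2],
                   stringsAsFactors = FALSE)
  df$weight <- if (is.null(weights)) 1 else weights
  interaction_network(df, nodes = nodes)
}

# independent brute-force Mann-Whitney AUC by pair counting
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# independent hypergeometric upper-tail sum from binomial coefficients
tail_sum_fisher <- function(k, m, K, N) {
  xs <- k:min(m, K)
  sum(choose(K, xs) * choose(N - K, m - xs)) / choose(N, m)
}

# independent neighbour-sum topology score (loop form)
brute_force_f <- function(net, s) {
  nodes <- net$nodes
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    w[net$edges$a[r], net$edges$b[r]] <- net$edges$weight[r]
    w[net$edges$b[r], net$edges$a[r]] <- net$edges$weight[r]
  }
  d <- rowSums(w)
  f <- setNames(numeric(length(nodes)), nodes)
  for (i in nodes) {
    for (j in nodes) {
      if (w[i, j] > 0)
        f[i] <- f[i] + w[i, j] / sqrt(d[i] * d[j]) * s[j]
    }
  }
  f
}

random_weighted_net <- function(n_nodes, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # ensure no isolated node by adding a ring
  ring <- cbind(nodes, c(nodes[-1], nodes[1]))
  edges <- rbind(pairs[keep, , drop = FALSE], ring)
  toy_net(edges, weights = round(runif(nrow(edges), 0.1, 1), 3))
}
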