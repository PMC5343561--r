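#' Restrict an interaction network to the measured genes
#'
#' Intersects the interaction network's node set with the expression
#' dataset's genes, keeping only edges with both endpoints measured. The
#' result is the background protein-protein interaction network (background
#' PPIN) on which all later stages operate.
#'
#' @param expr An [expression_dataset()].
#' @param net An [interaction_network()].
#' @return An [interaction_network()] whose nodes are the intersection;
#'   edge weights are preserved.
#' @export
build_background_ppin <- function(expr, net) {
  stopifnot(inherits(expr, "expression_dataset"),
            inherits(net, "interaction_network"))
  common <- intersect(rownames(expr$values), net$nodes)
  if (!length(common))
    stop("expression genes and network nodes do not intersect")
  keep <- net$edges$a %in% common & net$edges$b %in% common
  interaction_network(net$edges[keep, , drop = FALSE], nodes = common)
}

#' Edge-wise co-expression statistics
#'
#' For every network edge, computes the pooled-sample Pearson correlation of
#' the two genes' expression profiles, and a p-value for a group difference
#' in per-sample co-expression. Two test methods are available:
#'
#' * `"tcontrast"` (default): per sample `s` the edge's co-expression
#'   contribution is `c_s = z_i(s) * z_j(s)`, the product of the two genes'
#'   expression standardized over all samples; the p-value is a one-sided
#'   two-sample t-test comparing case against control contributions
#'   (pooled-variance by default; Welch with `var_equal = FALSE`). Note
#'   that when a co-expressed module is shifted between groups, the pooled
#'   standardization concentrates these contributions in whichever group has
#'   *fewer* samples (those samples lie farther from the pooled mean); with
#'   a case-majority design the one-sided alternative that captures
#'   disease-coherent edges is therefore the control side, which is the
#'   default `direction`.
#' * `"fisherz"`: one-sided z-test on the difference of Fisher-transformed
#'   per-group correlations (a differential-correlation test).
#'
#' Edges touching a zero-variance gene get `pcc = 0`, `p = 1` and a warning.
#'
#' @param expr An [expression_dataset()] covering the network genes.
#' @param net An [interaction_network()] (typically the background PPIN).
#' @param method Test statistic; see Details.
#' @param direction Which group is hypothesised to carry the larger
#'   co-expression signal: `"control"`, `"case"`, or `"both"` (two-sided).
#' @param var_equal For `"tcontrast"`: pooled-variance Student t (default)
#'   or Welch when `FALSE`.
#' @return A data frame with columns `a`, `b`, `pcc`, `p_value`, one row per
#'   network edge.
#' @export
edge_statistics <- function(expr, net,
                            method = c("tcontrast", "fisherz"),
                            direction = c("control", "case", "both"),
                            var_equal = TRUE) {
  stopifnot(inherits(expr, "expression_dataset"),
            inherits(net, "interaction_network"))
  method <- match.arg(method)
  direction <- match.arg(direction)
  edges <- net$edges
  miss <- setdiff(net$nodes, rownames(expr$values))
  if (length(miss))
    stop("network gene not in expression data: ",
         paste(head(miss, 5), collapse = ", "))
  n <- ncol(expr$values)
  if (n < 3) stop("need at least 3 samples to compute correlations")
  if (!nrow(edges)) {
    return(data.frame(a = character(), b = character(),
                      pcc = numeric(), p_value = numeric()))
  }

  x <- expr$values[unique(c(edges$a, edges$b)), , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2) / (n - 1))
  flat <- sdev == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s); incident edges get pcc = 0, p = 1")
    sdev[flat] <- 1
  }
  z <- (x - mu) / sdev
  zi <- z[edges$a, , drop = FALSE]
  zj <- z[edges$b, , drop = FALSE]
  pcc <- rowSums(zi * zj) / (n - 1)

  case <- expr$labels == "case"
  n1 <- sum(case); n0 <- sum(!case)
  if (method == "tcontrast") {
    cs <- zi * zj
    m1 <- rowMeans(cs[, case, drop = FALSE])
    m0 <- rowMeans(cs[, !case, drop = FALSE])
    ss1 <- rowSums((cs[, case, drop = FALSE] - m1)^2)
    ss0 <- rowSums((cs[, !case, drop = FALSE] - m0)^2)
    if (var_equal) {
      sp2 <- (ss1 + ss0) / (n - 2)
      tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
      df <- rep(n - 2, length(tstat))
    } else {
      v1 <- ss1 / (n1 - 1)
      v0 <- ss0 / (n0 - 1)
      tstat <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
      df <- (v1 / n1 + v0 / n0)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    degenerate <- !is.finite(tstat)
    tstat[degenerate] <- 0
    df[degenerate] <- n - 2
    p <- switch(direction,
      case = pt(tstat, df, lower.tail = FALSE),
      control = pt(tstat, df, lower.tail = TRUE),
      both = 2 * pt(-abs(tstat), df))
    p[degenerate] <- 1
  } else {
    if (n1 < 4 || n0 < 4)
      stop("'fisherz' needs at least 4 samples per group")
    r_by_group <- function(sel) {
      xs <- x[, sel, drop = FALSE]
      ms <- rowMeans(xs)
      ss <- sqrt(rowSums((xs - ms)^2))
      ss[ss == 0] <- NA
      zz <- (xs - ms) / ss
      r <- rowSums(zz[edges$a, , drop = FALSE] * zz[edges$b, , drop = FALSE])
      pmin(pmax(r, -0.999999), 0.999999)
    }
    r1 <- r_by_group(case)
    r0 <- r_by_group(!case)
    dz <- (atanh(r1) - atanh(r0)) / sqrt(1 / (n1 - 3) + 1 / (n0 - 3))
    dz[!is.finite(dz)] <- 0
    p <- switch(direction,
      case = stats::pnorm(dz, lower.tail = FALSE),
      control = stats::pnorm(dz, lower.tail = TRUE),
      both = 2 * stats::pnorm(-abs(dz)))
  }

  bad <- edges$a %in% names(flat)[flat] | edges$b %in% names(flat)[flat]
  pcc[bad] <- 0
  p[bad] <- 1
  data.frame(a = edges$a, b = edges$b, pcc = as.numeric(pcc),
             p_value = as.numeric(p), stringsAsFactors = FALSE)
}

#' Extract the differential expression network
#'
#' Retains the edges whose pooled Pearson correlation and group-contrast
#' p-value pass the thresholds `|pcc| >= pcc_threshold` (inclusive) and
#' `p < p_threshold` (strict). Retained-edge weights become `|pcc|`; nodes
#' are exactly the endpoints of retained edges, so the result has no
#' isolated nodes.
#'
#' @param stats Data frame from [edge_statistics()].
#' @param pcc_threshold Absolute-correlation cutoff in `[0, 1]`; default 0.8.
#' @param p_threshold P-value cutoff in `(0, 1]`; default 0.05.
#' @return An [interaction_network()] with additional class `den` and
#'   attributes `node_count` and `edge_count`. An empty result (no
#'   surviving edges) is returned as a zero-edge network, not an error.
#' @export
extract_den <- function(stats, pcc_threshold = 0.8, p_threshold = 0.05) {
  if (pcc_threshold < 0 || pcc_threshold > 1)
    stop("'pcc_threshold' must be in [0, 1]")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("'p_threshold' must be in (0, 1]")
  keep <- abs(stats$pcc) >= pcc_threshold & stats$p_value < p_threshold
  kept <- stats[keep, , drop = FALSE]
  net <- interaction_network(
    data.frame(a = kept$a, b = kept$b, weight = abs(kept$pcc),
               stringsAsFactors = FALSE))
  class(net) <- c("den", class(net))
  attr(net, "node_count") <- length(net$nodes)
  attr(net, "edge_count") <- nrow(net$edges)
  if (!nrow(net$edges))
    message("empty differential expression network: no edges pass the filters")
  net
}
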