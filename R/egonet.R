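#' Tuning parameters for the ego-network pipeline
#'
#' All thresholds of the pipeline in one validated list. Defaults are the
#' standard operating point: `|PCC| >= 0.8` and `p < 0.05` for the
#' differential expression network, top 5% ego genes, module retention at
#' `AUC >= 0.8` and size `>= 4`, 1000 label permutations, `alpha = 0.05`,
#' background pathways of intersected size 5-100, and a module size cap of
#' 30.
#'
#' @param pcc Absolute-correlation edge threshold (inclusive).
#' @param edge_p Edge-test p-value threshold (strict).
#' @param edge_method,edge_direction Passed to [edge_statistics()].
#' @param ego_fraction Top fraction of nodes taken as ego genes.
#' @param auc Minimum module AUC (inclusive).
#' @param min_module_size Minimum module gene count (inclusive).
#' @param perm_B Number of label permutations per module.
#' @param alpha Significance level for modules and pathways (strict).
#' @param pathway_min,pathway_max Background-pathway intersection bounds
#'   (inclusive).
#' @param size_cap Greedy-expansion size cap.
#' @param allow_plateau Accept AUC-neutral expansion steps (see
#'   [expand_ego()]); default `TRUE`.
#' @param svm_cost SVM regularization constant.
#' @return A list of class `egonet_control`.
#' @export
egonet_control <- function(pcc = 0.8, edge_p = 0.05,
                           edge_method = "tcontrast",
                           edge_direction = "control",
                           ego_fraction = 0.05, auc = 0.8,
                           min_module_size = 4, perm_B = 1000,
                           alpha = 0.05, pathway_min = 5, pathway_max = 100,
                           size_cap = 30, allow_plateau = TRUE,
                           svm_cost = 1) {
  ctrl <- list(pcc = pcc, edge_p = edge_p, edge_method = edge_method,
               edge_direction = edge_direction, ego_fraction = ego_fraction,
               auc = auc, min_module_size = min_module_size,
               perm_B = as.integer(perm_B), alpha = alpha,
               pathway_min = as.integer(pathway_min),
               pathway_max = as.integer(pathway_max),
               size_cap = as.integer(size_cap),
               allow_plateau = isTRUE(allow_plateau), svm_cost = svm_cost)
  if (ctrl$pcc < 0 || ctrl$pcc > 1) stop("'pcc' must be in [0, 1]")
  if (ctrl$edge_p <= 0 || ctrl$edge_p > 1) stop("'edge_p' must be in (0, 1]")
  if (ctrl$ego_fraction <= 0 || ctrl$ego_fraction > 1)
    stop("'ego_fraction' must be in (0, 1]")
  if (ctrl$auc < 0 || ctrl$auc > 1) stop("'auc' must be in [0, 1]")
  if (ctrl$min_module_size < 1) stop("'min_module_size' must be >= 1")
  if (ctrl$perm_B < 1) stop("'perm_B' must be >= 1")
  if (ctrl$alpha <= 0 || ctrl$alpha > 1) stop("'alpha' must be in (0, 1]")
  if (ctrl$pathway_min < 1 || ctrl$pathway_max < ctrl$pathway_min)
    stop("invalid pathway size bounds")
  if (ctrl$size_cap < 1) stop("'size_cap' must be >= 1")
  class(ctrl) <- "egonet_control"
  ctrl
}

#' Fit the ego-network module pipeline
#'
#' Runs the full analysis on a two-group expression dataset and an
#' interaction network: (1) restrict the network to measured genes
#' (background PPIN); (2) score every edge by pooled Pearson correlation
#' and a one-sided group contrast, retaining the differential expression
#' network (DEN); (3) rank DEN genes by the topology score on the
#' normalized weighted adjacency and take the top fraction as ego genes;
#' (4) grow one candidate module per ego gene by greedy AUC-maximizing
#' expansion; (5) keep modules passing the AUC/size filter, assess each by
#' label permutation, and adjust p-values by Benjamini-Hochberg; (6) if a
#' pathway collection is supplied, call ego pathways per module by
#' one-sided Fisher tests against the background pathways.
#'
#' An empty DEN terminates the pipeline gracefully: the returned object
#' carries the stage counts computed so far and empty result slots.
#'
#' @param expr An [expression_dataset()].
#' @param network An [interaction_network()].
#' @param pathways Optional [pathway_collection()].
#' @param control An [egonet_control()].
#' @param seed Integer seed; fans out deterministic child seeds to the
#'   per-module permutation tests.
#' @return Object of class `egonet`: list with `background`, `den`,
#'   `edge_stats`, `scores`, `ego_genes`, `candidates`, `modules`,
#'   `enrichment`, `ego_pathways`, `summary` (named stage counts),
#'   `control`, `seed`. Supports `print()`, `summary()` and `plot()`.
#' @export
#' @examples
#' sim <- simulate_egonet_data(synthetic_config(n_genes = 120, seed = 2))
#' fit <- egonet(sim$expression, sim$network, sim$pathways,
#'               control = egonet_control(perm_B = 20), seed = 2)
#' print(fit)
egonet <- function(expr, network, pathways = NULL,
                   control = egonet_control(), seed = 1L) {
  stopifnot(inherits(expr, "expression_dataset"),
            inherits(network, "interaction_network"),
            inherits(control, "egonet_control"))
  counts <- list(expression_genes = nrow(expr$values),
                 samples = ncol(expr$values),
                 network_nodes = length(network$nodes),
                 network_edges = nrow(network$edges))

  background <- build_background_ppin(expr, network)
  counts$background_nodes <- length(background$nodes)
  counts$background_edges <- nrow(background$edges)

  stats <- edge_statistics(expr, background, method = control$edge_method,
                           direction = control$edge_direction)
  den <- extract_den(stats, pcc_threshold = control$pcc,
                     p_threshold = control$edge_p)
  counts$den_nodes <- length(den$nodes)
  counts$den_edges <- nrow(den$edges)

  fit <- list(background = background, edge_stats = stats, den = den,
              scores = NULL, ego_genes = character(), candidates = list(),
              modules = list(), enrichment = NULL,
              ego_pathways = list(), control = control, seed = seed)
  class(fit) <- "egonet"

  if (!nrow(den$edges)) {
    counts[c("ego_genes", "candidate_modules", "ego_modules",
             "significant_modules", "background_pathways",
             "ego_pathways")] <- 0
    fit$summary <- counts
    return(fit)
  }

  scores <- topology_scores(den, expr = expr)
  scores <- select_ego_genes(scores, fraction = control$ego_fraction)
  egos <- scores$gene[scores$is_ego]
  counts$ego_genes <- length(egos)
  fit$scores <- scores
  fit$ego_genes <- egos

  zvec <- setNames(scores$z, scores$gene)
  candidates <- lapply(seq_along(egos), function(i)
    expand_ego(egos[i], den, expr, z = zvec, size_cap = control$size_cap,
               allow_plateau = control$allow_plateau,
               module_id = paste0("M", i), cost = control$svm_cost))
  counts$candidate_modules <- length(candidates)
  fit$candidates <- candidates

  modules <- filter_modules(candidates, auc_threshold = control$auc,
                            size_threshold = control$min_module_size)
  counts$ego_modules <- length(modules)

  if (length(modules)) {
    perms <- lapply(seq_along(modules), function(i)
      permutation_test(modules[[i]], expr, B = control$perm_B,
                       seed = derive_seed(seed, i), cost = control$svm_cost))
    p_perm <- vapply(perms, `[[`, 1, "p_perm")
    p_adj <- bh_adjust(p_perm)
    sig <- call_significant(p_adj, control$alpha)
    for (i in seq_along(modules)) {
      modules[[i]]$p_perm <- p_perm[i]
      modules[[i]]$p_adj <- p_adj[i]
      modules[[i]]$significant <- sig[i]
      modules[[i]]$permutation <- perms[[i]]
    }
  }
  counts$significant_modules <- sum(vapply(modules, `[[`, TRUE, "significant"))
  fit$modules <- modules

  if (!is.null(pathways) && length(modules)) {
    universe <- background$nodes
    bg_pw <- build_background_pathways(pathways, universe,
                                       min_size = control$pathway_min,
                                       max_size = control$pathway_max)
    counts$background_pathways <- length(bg_pw)
    enr <- lapply(modules, function(m)
      fisher_enrichment(intersect(m$genes, universe), bg_pw, universe,
                        module_id = m$module_id, alpha = control$alpha))
    enr <- do.call(rbind, enr)
    rownames(enr) <- NULL
    fit$enrichment <- enr
    fit$ego_pathways <- select_ego_pathways(enr, alpha = control$alpha)
    counts$ego_pathways <- length(unique(
      enr$pathway_id[enr$is_ego_pathway]))
  } else {
    counts$background_pathways <- if (is.null(pathways)) NA_integer_ else
      length(build_background_pathways(pathways, background$nodes,
                                       min_size = control$pathway_min,
                                       max_size = control$pathway_max))
    counts$ego_pathways <- 0
  }

  fit$summary <- counts
  fit
}

#' @export
print.egonet <- function(x, ...) {
  s <- x$summary
  cat("Ego-network module analysis\n")
  cat(sprintf("  expression: %d genes x %d samples\n",
              s$expression_genes, s$samples))
  cat(sprintf("  background PPIN: %d nodes, %d edges\n",
              s$background_nodes, s$background_edges))
  cat(sprintf("  DEN: %d nodes, %d edges\n", s$den_nodes, s$den_edges))
  if (!s$den_edges) {
    cat("  pipeline stopped: empty differential expression network\n")
    return(invisible(x))
  }
  cat(sprintf("  ego genes: %d -> candidate modules: %d -> ego modules: %d (%d significant)\n",
              s$ego_genes, s$candidate_modules, s$ego_modules,
              s$significant_modules))
  if (!is.na(s$background_pathways))
    cat(sprintf("  background pathways: %d -> ego pathways: %d\n",
                s$background_pathways, s$ego_pathways))
  invisible(x)
}

#' @export
summary.egonet <- function(object, ...) {
  out <- list(counts = object$summary,
              ego_genes = if (!is.null(object$scores))
                object$scores[object$scores$is_ego, , drop = FALSE] else NULL,
              modules = module_table(object$modules),
              ego_pathways = object$ego_pathways)
  class(out) <- "summary.egonet"
  out
}

#' @export
print.summary.egonet <- function(x, ...) {
  cat("Stage counts:\n")
  counts <- x$counts[!vapply(x$counts, is.na, TRUE)]
  cat(paste0("  ", names(counts), ": ", unlist(counts), collapse = "\n"), "\n")
  if (!is.null(x$ego_genes) && nrow(x$ego_genes)) {
    cat("\nEgo genes:\n")
    print(x$ego_genes, digits = 3)
  }
  if (nrow(x$modules)) {
    cat("\nEgo modules:\n")
    print(x$modules, digits = 3)
  }
  if (length(x$ego_pathways)) {
    cat("\nEgo pathways:\n")
    for (m in names(x$ego_pathways))
      print(x$ego_pathways[[m]][, c("module_id", "pathway_id", "overlap",
                                    "p", "p_adj")], digits = 3)
  }
  invisible(x)
}

#' Plot the differential expression network of a fit
#'
#' Draws the DEN with ego genes highlighted and module memberships
#' indicated by vertex colour.
#'
#' @param x An `egonet` fit.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.egonet <- function(x, ...) {
  if (!nrow(x$den$edges)) {
    warning("empty DEN; nothing to plot")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(x$den$edges, directed = FALSE,
                                     vertices = x$den$nodes)
  cols <- rep("grey80", length(x$den$nodes))
  names(cols) <- x$den$nodes
  pal <- grDevices::hcl.colors(max(length(x$modules), 1), "Set 2")
  for (i in seq_along(x$modules))
    cols[intersect(x$modules[[i]]$genes, names(cols))] <- pal[i]
  cols[x$ego_genes] <- "gold"
  igraph::plot.igraph(g, vertex.color = cols[igraph::V(g)$name],
                      vertex.size = 8, vertex.label.cex = 0.6,
                      edge.width = 2 * x$den$edges$weight, ...)
  invisible(x)
}
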