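#' Construct an expression dataset
#'
#' Bundles a normalized (log-scale) gene-by-sample expression matrix with
#' binary sample labels. This is the raw material of every pipeline stage:
#' edge co-expression scores, differential-expression statistics, module
#' classifiers and permutation tests all read from it.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param labels Character or factor vector of `"case"` / `"control"`, named
#'   by sample id or given in column order. At least two samples per group.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix) and `labels` (a factor with levels
#'   `c("control", "case")` named by sample).
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' expression_dataset(m, c("case", "case", "case", "control", "control"))
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  lab <- setNames(as.character(labels), names(labels))
  if (is.null(names(lab))) {
    if (length(lab) != ncol(values))
      stop("'labels' length does not match the number of samples")
    names(lab) <- colnames(values)
  }
  unknown <- setdiff(names(lab), colnames(values))
  if (length(unknown))
    stop("label given for unknown sample: ", paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(values), names(lab))
  if (length(missing))
    stop("no label for sample: ", paste(missing, collapse = ", "))
  lab <- lab[colnames(values)]
  if (!all(lab %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  lab <- factor(lab, levels = c("control", "case"))
  if (any(table(lab) < 2))
    stop("at least 2 samples per group are required")
  structure(list(values = values, labels = lab),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Construct an undirected weighted interaction network
#'
#' Stores an undirected gene graph (a STRING-style protein-protein
#' interaction network, a background PPIN, or a differential expression
#' network) as a canonical edge table: each unordered pair once, endpoints
#' sorted lexicographically, non-negative weights, no self-loops.
#'
#' @param edges Data frame (or coercible) with columns `a`, `b`, `weight`
#'   (weight optional, defaults to 1). Duplicate pairs in either orientation
#'   are merged keeping the maximum weight; self-loops are dropped with a
#'   message.
#' @param nodes Optional character vector of node ids; defaults to the edge
#'   endpoints. Must cover all endpoints.
#'
#' @return An object of class `interaction_network`: list with `nodes`
#'   (character) and `edges` (data frame `a`, `b`, `weight`, with `a < b`).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2) edges$weight <- 1
  if (ncol(edges) < 3) stop("'edges' needs columns a, b and optionally weight")
  names(edges)[1:3] <- c("a", "b", "weight")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) stop("unparseable edge weight")
  if (any(edges$weight < 0)) stop("negative edge weight")
  loops <- edges$a == edges$b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    flip <- edges$a > edges$b
    tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
    key <- paste(edges$a, edges$b, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(edges$weight, key, max)
      first <- !duplicated(key)
      edges <- edges[first, , drop = FALSE]
      edges$weight <- as.numeric(w[paste(edges$a, edges$b, sep = "\r")])
    }
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  endpoints <- unique(c(edges$a, edges$b))
  if (is.null(nodes)) {
    nodes <- sort(endpoints)
  } else {
    nodes <- sort(unique(as.character(nodes)))
    stray <- setdiff(endpoints, nodes)
    if (length(stray))
      stop("edge endpoint not in 'nodes': ", paste(stray, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a pathway collection
#'
#' A named collection of gene sets, as read from a GMT file. Used both for
#' the background-pathway filter and for Fisher over-representation tests.
#'
#' @param sets Named list; each element is either a character vector of gene
#'   ids or a list with elements `description` and `genes`.
#'
#' @return Object of class `pathway_collection`: named list of
#'   `list(description =, genes =)` with unique, non-empty gene sets.
#' @export
pathway_collection <- function(sets) {
  if (!length(sets)) {
    return(structure(setNames(list(), character()),
                     class = "pathway_collection"))
  }
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every pathway must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway id: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  out <- lapply(sets, function(s) {
    if (is.list(s)) {
      list(description = as.character(s$description %||% ""),
           genes = unique(as.character(s$genes)))
    } else {
      list(description = "", genes = unique(as.character(s)))
    }
  })
  empty <- names(out)[vapply(out, function(s) length(s$genes) == 0, TRUE)]
  if (length(empty))
    stop("empty pathway gene set: ", paste(empty, collapse = ", "))
  structure(out, class = "pathway_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(unclass(x), function(s) length(s$genes), 1L)
  cat(sprintf("pathway_collection: %d pathways (set sizes %s)\n",
              length(x),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}
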