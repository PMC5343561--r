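#' Build the background pathway collection
#'
#' Intersects every pathway with the gene universe (the background PPIN
#' gene set) and keeps those whose intersection has between `min_size` and
#' `max_size` genes, inclusive. The retained sets are the intersections
#' themselves.
#'
#' @param pathways A [pathway_collection()].
#' @param universe Character vector of universe gene ids.
#' @param min_size,max_size Inclusive intersection-size bounds; defaults
#'   5 and 100.
#' @return A filtered [pathway_collection()].
#' @export
build_background_pathways <- function(pathways, universe, min_size = 5,
                                      max_size = 100) {
  stopifnot(inherits(pathways, "pathway_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  sets <- lapply(unclass(pathways), function(s) {
    list(description = s$description,
         genes = intersect(s$genes, universe))
  })
  sizes <- vapply(sets, function(s) length(s$genes), 1L)
  keep <- sizes >= min_size & sizes <= max_size
  pathway_collection(sets[keep])
}

#' Fisher over-representation of a module in background pathways
#'
#' For each background pathway, tests whether the module's genes overlap it
#' more than chance given the universe, via the one-sided Fisher's exact
#' test: with overlap `k`, module size `m`, pathway size `K` and universe
#' size `N`, the p-value is the hypergeometric upper tail `P(X >= k)`.
#' P-values are Benjamini-Hochberg adjusted across the pathways tested for
#' this module; `is_ego_pathway` flags `p_adj < 0.05` (strict).
#'
#' @param module_genes Character vector of module gene ids (must lie in the
#'   universe).
#' @param background A [pathway_collection()] from
#'   [build_background_pathways()].
#' @param universe Character vector of universe gene ids.
#' @param module_id Identifier copied into the result; default `"M1"`.
#' @param alpha Flagging threshold on adjusted p; default 0.05.
#' @return Data frame with one row per pathway: `module_id`, `pathway_id`,
#'   `overlap`, `module_size`, `pathway_size`, `universe`, `p`, `p_adj`,
#'   `is_ego_pathway`.
#' @export
fisher_enrichment <- function(module_genes, background, universe,
                              module_id = "M1", alpha = 0.05) {
  stopifnot(inherits(background, "pathway_collection"))
  universe <- unique(as.character(universe))
  module_genes <- unique(as.character(module_genes))
  stray <- setdiff(module_genes, universe)
  if (length(stray))
    stop("module gene outside the universe: ",
         paste(head(stray, 5), collapse = ", "))
  n_univ <- length(universe)
  m <- length(module_genes)
  rows <- lapply(names(background), function(id) {
    pw <- background[[id]]$genes
    k <- length(intersect(module_genes, pw))
    K <- length(pw)
    data.frame(module_id = module_id, pathway_id = id, overlap = k,
               module_size = m, pathway_size = K, universe = n_univ,
               p = phyper(k - 1, K, n_univ - K, m, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = character(), pathway_id = character(),
               overlap = integer(), module_size = integer(),
               pathway_size = integer(), universe = integer(), p = numeric(),
               stringsAsFactors = FALSE)
  out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out$is_ego_pathway <- call_significant(out$p_adj, alpha)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}

#' Select ego pathways
#'
#' Filters enrichment results to the significantly over-represented
#' pathways (`p_adj < 0.05`, strict) and splits them by module.
#'
#' @param results Data frame from [fisher_enrichment()] (rows for one or
#'   several modules).
#' @param alpha Threshold on adjusted p; default 0.05.
#' @return Named list (by `module_id`) of data frames; modules with no ego
#'   pathway are absent.
#' @export
select_ego_pathways <- function(results, alpha = 0.05) {
  hits <- results[call_significant(results$p_adj, alpha), , drop = FALSE]
  split(hits, hits$module_id)
}
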