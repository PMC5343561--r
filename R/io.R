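#' Read an expression matrix and its sample labels
#'
#' Expects a tab-separated file with a header row of sample ids, gene ids in
#' the first column, and one row per gene, plus a two-column labels file
#' (`sample`, `label` with values `case`/`control`). Duplicate gene rows are
#' collapsed by keeping the row with the highest mean expression — a
#' deterministic stand-in for probe summarization, which is out of scope.
#'
#' @param path Expression TSV path.
#' @param labels_path Labels TSV path.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column and samples")
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric expression value at row %d, column '%s'",
                 bad[1, 1], colnames(raw)[-1][bad[1, 2]]))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at row %d (gene '%s'), column '%s'",
                 idx[1], genes[idx[1]], colnames(m)[idx[2]]))
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)
    message(length(genes) - length(keep),
            " duplicate gene row(s) collapsed by maximum mean expression")
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes

  lab <- read.delim(labels_path, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs columns sample and label")
  labels <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  expression_dataset(m, labels)
}

#' Read a STRING-style weighted edge list
#'
#' Two or three tab-separated columns: `gene_a`, `gene_b`, and optionally a
#' non-negative `weight` (missing column means weight 1). Duplicate pairs in
#' either orientation keep the maximum weight; self-loops are dropped with a
#' message.
#'
#' @param path Edge list TSV path (no header).
#' @return An [interaction_network()].
#' @export
read_edgelist <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("edge list needs at least two columns")
  if (ncol(raw) == 2) raw$V3 <- 1
  w <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(w))
    stop("unparseable edge weight at line ", which(is.na(w))[1])
  if (any(w < 0))
    stop("negative edge weight at line ", which(w < 0)[1])
  interaction_network(data.frame(a = raw[[1]], b = raw[[2]], weight = w,
                                 stringsAsFactors = FALSE))
}

#' Read a GMT pathway file
#'
#' Broad-dialect GMT: one pathway per line, tab-separated fields
#' `name`, `description`, then member genes. Genes repeated within a line
#' are deduplicated; duplicate pathway names are an error.
#'
#' @param path GMT file path.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f)
    list(description = f[2], genes = unique(f[-(1:2)])))
  names(sets) <- ids
  pathway_collection(sets)
}

#' Write pipeline results as tab-separated tables
#'
#' Emits `ego_genes.tsv`, `modules.tsv`, `enrichment.tsv`, a `modules.gmt`
#' gene-set file of module memberships, and `summary.json` with the stage
#' counts of the run. Tables with no rows are written header-only.
#'
#' @param fit An `egonet` fit object (see [egonet()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "egonet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(ego_genes = file.path(dir, "ego_genes.tsv"),
             modules = file.path(dir, "modules.tsv"),
             enrichment = file.path(dir, "enrichment.tsv"),
             modules_gmt = file.path(dir, "modules.gmt"),
             summary = file.path(dir, "summary.json"))

  write_tsv_num(score_table(fit$scores), paths["ego_genes"])
  write_tsv_num(module_table(fit$modules), paths["modules"])
  write_tsv_num(enrichment_table(fit$enrichment), paths["enrichment"])
  writeLines(module_gmt_lines(fit$modules), paths["modules_gmt"])

  jsonlite::write_json(fit$summary, paths["summary"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

# numeric columns serialized at full double precision so that staged and
# end-to-end runs produce byte-identical files
write_tsv_num <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

score_table <- function(scores) {
  if (is.null(scores))
    return(data.frame(gene = character(), d = numeric(), s = numeric(),
                      f = numeric(), z = numeric(), is_ego = logical()))
  scores
}

enrichment_table <- function(enr) {
  if (is.null(enr))
    return(data.frame(module_id = character(), pathway_id = character(),
                      overlap = integer(), module_size = integer(),
                      pathway_size = integer(), universe = integer(),
                      p = numeric(), p_adj = numeric(),
                      is_ego_pathway = logical()))
  enr
}

module_gmt_lines <- function(modules) {
  vapply(modules, function(m)
    paste(c(m$module_id, paste0("ego:", m$ego_gene), m$genes),
          collapse = "\t"), "")
}

# flatten a list of (possibly tested) candidate modules into the
# modules.tsv layout
module_table <- function(modules) {
  if (!length(modules)) {
    return(data.frame(module_id = character(), ego_gene = character(),
                      genes = character(), size = integer(), auc = numeric(),
                      p_perm = numeric(), p_adj = numeric(),
                      is_significant = logical()))
  }
  do.call(rbind, lapply(modules, function(m) {
    data.frame(module_id = m$module_id, ego_gene = m$ego_gene,
               genes = paste(m$genes, collapse = ";"),
               size = length(m$genes), auc = m$auc,
               p_perm = m$p_perm %||% NA_real_,
               p_adj = m$p_adj %||% NA_real_,
               is_significant = m$significant %||% NA,
               stringsAsFactors = FALSE)
  }))
}
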