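#' Configuration for the synthetic benchmark generator
#'
#' Describes a two-group expression study with a planted, hub-centred
#' co-expression module laid over a random interaction graph, together with
#' a pathway collection containing one set that overlaps the planted module.
#' Defaults mirror a small disease/control microarray design (19 cases vs 6
#' controls) at desk scale.
#'
#' @param n_cases,n_controls Samples per group (each at least 2).
#' @param n_genes Total number of genes.
#' @param graph_model Background graph: `"scale_free"` (preferential
#'   attachment, m = 2) or `"erdos_renyi"`.
#' @param planted_module_size Number of planted module genes including the
#'   hub; at least 4.
#' @param planted_hub Gene id given to the planted hub. Purely a readable
#'   label; no biological identity is claimed.
#' @param effect_size Standardized mean difference (case minus control) added
#'   to every planted gene.
#' @param within_module_correlation Target pairwise within-group Pearson
#'   correlation of planted genes, in `[0, 1)`; achieved by a shared
#'   per-sample latent factor.
#' @param noise_sd Residual standard deviation of expression values.
#' @param pathway_count Number of gene sets in the generated GMT collection.
#' @param planted_pathway_overlap Genes shared between the planted pathway
#'   and the planted module (at most `planted_module_size`).
#' @param seed Integer seed; equal seeds give bit-identical outputs.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 19,
                             n_controls = 6,
                             n_genes = 300,
                             graph_model = c("scale_free", "erdos_renyi"),
                             planted_module_size = 6,
                             planted_hub = "IL1B",
                             effect_size = 3,
                             within_module_correlation = 0.9,
                             noise_sd = 1,
                             pathway_count = 50,
                             planted_pathway_overlap = 5,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              graph_model = match.arg(graph_model),
              planted_module_size = as.integer(planted_module_size),
              planted_hub = as.character(planted_hub),
              effect_size = as.numeric(effect_size),
              within_module_correlation = as.numeric(within_module_correlation),
              noise_sd = as.numeric(noise_sd),
              pathway_count = as.integer(pathway_count),
              planted_pathway_overlap = as.integer(planted_pathway_overlap),
              seed = as.integer(seed))
  if (cfg$n_cases < 2) stop("invalid 'n_cases': need at least 2")
  if (cfg$n_controls < 2) stop("invalid 'n_controls': need at least 2")
  if (cfg$planted_module_size < 4)
    stop("invalid 'planted_module_size': need at least 4")
  if (cfg$planted_module_size >= cfg$n_genes)
    stop("invalid 'n_genes': must exceed 'planted_module_size'")
  if (cfg$within_module_correlation < 0 || cfg$within_module_correlation >= 1)
    stop("invalid 'within_module_correlation': must be in [0, 1)")
  if (cfg$noise_sd <= 0) stop("invalid 'noise_sd': must be positive")
  if (cfg$planted_pathway_overlap > cfg$planted_module_size)
    stop("invalid 'planted_pathway_overlap': exceeds 'planted_module_size'")
  if (cfg$planted_pathway_overlap < 1)
    stop("invalid 'planted_pathway_overlap': need at least 1")
  if (cfg$pathway_count < 1) stop("invalid 'pathway_count': need at least 1")
  class(cfg) <- "synthetic_config"
  cfg
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic benchmark dataset with planted ground truth
#'
#' Draws a random background interaction graph, plants a hub-centred module
#' (a star on the hub plus chords between consecutive satellites), and
#' simulates expression so that planted genes share a per-sample latent
#' factor (pairwise within-group correlation approximately
#' `within_module_correlation`) and are shifted between groups by
#' `effect_size` standard deviations. All remaining genes are independent
#' noise. A pathway collection is generated with one set overlapping the
#' planted module by `planted_pathway_overlap` genes.
#'
#' Planted expression follows
#' `x = noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * eps) + noise_sd * effect_size * 1(case)`
#' with `z` shared across the module within each sample, so the expected
#' within-group correlation of two planted genes is exactly `rho`.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list with elements `expression` ([expression_dataset()]),
#'   `network` ([interaction_network()]), `pathways`
#'   ([pathway_collection()]) and `truth` (list: `planted_genes`,
#'   `planted_hub`, `planted_pathway`).
#' @export
#' @examples
#' sim <- simulate_egonet_data(synthetic_config(n_genes = 100, seed = 7))
#' sim$truth$planted_hub
simulate_egonet_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    genes <- sprintf("G%04d", seq_len(n_genes))
    planted_idx <- sort(sample.int(n_genes, config$planted_module_size))
    hub_idx <- planted_idx[1]
    genes[hub_idx] <- config$planted_hub
    planted <- genes[planted_idx]
    satellites <- setdiff(planted, config$planted_hub)

    g <- switch(config$graph_model,
      scale_free = igraph::sample_pa(n_genes, m = 2, directed = FALSE),
      erdos_renyi = igraph::sample_gnp(n_genes, p = 4 / n_genes))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(a = genes[el[, 1]], b = genes[el[, 2]],
                        stringsAsFactors = FALSE)
    # planted module: star on the hub plus chords between consecutive
    # satellites, guaranteeing a connected, hub-centred subgraph
    star <- data.frame(a = config$planted_hub, b = satellites,
                       stringsAsFactors = FALSE)
    chords <- data.frame(a = satellites[-length(satellites)],
                         b = satellites[-1], stringsAsFactors = FALSE)
    edges <- rbind(edges, star, chords)
    edges <- edges[edges$a != edges$b, ]
    edges$weight <- round(runif(nrow(edges), 0.15, 0.999), 3)
    network <- interaction_network(edges, nodes = genes)

    n <- config$n_cases + config$n_controls
    samples <- sprintf("S%02d", seq_len(n))
    labels <- c(rep("case", config$n_cases), rep("control", config$n_controls))
    names(labels) <- samples

    values <- matrix(rnorm(n_genes * n, sd = config$noise_sd),
                     n_genes, n, dimnames = list(genes, samples))
    rho <- config$within_module_correlation
    latent <- rnorm(n)
    shift <- config$effect_size * config$noise_sd * (labels == "case")
    for (gname in planted) {
      eps <- rnorm(n)
      values[gname, ] <- config$noise_sd *
        (sqrt(rho) * latent + sqrt(1 - rho) * eps) + shift
    }

    pw_names <- sprintf("PW%04d", seq_len(config$pathway_count))
    sets <- vector("list", config$pathway_count)
    names(sets) <- pw_names
    non_planted <- setdiff(genes, planted)
    max_size <- min(100, length(non_planted))
    for (i in seq_len(config$pathway_count)) {
      size <- sample(min(5, max_size):max_size, 1)
      sets[[i]] <- list(description = sprintf("synthetic pathway %d", i),
                        genes = sample(non_planted, size))
    }
    # planted pathway: fixed size 10 (or as close as the overlap allows),
    # overlap genes always including the hub
    overlap_genes <- c(config$planted_hub,
                       sample(satellites, config$planted_pathway_overlap - 1))
    pad <- sample(non_planted, max(10 - config$planted_pathway_overlap, 0))
    planted_pw <- pw_names[1]
    sets[[planted_pw]] <- list(description = "synthetic planted pathway",
                               genes = c(overlap_genes, pad))

    list(expression = expression_dataset(values, labels),
         network = network,
         pathways = pathway_collection(sets),
         truth = list(planted_genes = planted,
                      planted_hub = config$planted_hub,
                      planted_pathway = planted_pw))
  })
}

#' Write a synthetic dataset to disk as plain-text fixture files
#'
#' Emits the expression matrix, sample labels, edge list, GMT pathway file
#' and a JSON manifest of the planted ground truth. Files round-trip
#' losslessly through [read_expression()], [read_edgelist()] and
#' [read_gmt()].
#'
#' @param sim A list as returned by [simulate_egonet_data()].
#' @param dir Output directory (created if missing).
#'
#' @return Invisibly, a named character vector of the written file paths
#'   (`expression`, `labels`, `edges`, `gmt`, `manifest`).
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             edges = file.path(dir, "edges.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             manifest = file.path(dir, "truth.json"))

  expr <- sim$expression
  vals <- matrix(sprintf("%.17g", expr$values), nrow(expr$values),
                 dimnames = dimnames(expr$values))
  df <- data.frame(gene = rownames(vals), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(expr$values),
                         label = as.character(expr$labels)),
              paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$network$edges, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gmt_lines <- vapply(names(sim$pathways), function(id) {
    s <- sim$pathways[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(gmt_lines, paths["gmt"])
  jsonlite::write_json(sim$truth, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
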