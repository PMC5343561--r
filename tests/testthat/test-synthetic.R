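test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genes = 80, seed = 7)
  a <- simulate_egonet_data(cfg)
  b <- simulate_egonet_data(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$pathways, b$pathways)
  expect_identical(a$truth, b$truth)
  c <- simulate_egonet_data(synthetic_config(n_genes = 80, seed = 8))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(synthetic_config(n_cases = 1), "n_cases")
  expect_error(synthetic_config(n_controls = 1), "n_controls")
  expect_error(synthetic_config(planted_module_size = 3),
               "planted_module_size")
  expect_error(synthetic_config(planted_pathway_overlap = 7,
                                planted_module_size = 6),
               "planted_pathway_overlap")
  expect_error(synthetic_config(within_module_correlation = 1),
               "within_module_correlation")
})

test_that("planted structure is present: hub-centred connected module, pathway overlap", {
  cfg <- synthetic_config(n_genes = 100, seed = 3)
  sim <- simulate_egonet_data(cfg)
  truth <- sim$truth
  expect_true(truth$planted_hub %in% truth$planted_genes)
  expect_length(truth$planted_genes, cfg$planted_module_size)
  # every satellite touches the hub (star) and the module is connected
  edges <- sim$network$edges
  sats <- setdiff(truth$planted_genes, truth$planted_hub)
  for (s in sats) {
    hit <- (edges$a == truth$planted_hub & edges$b == s) |
      (edges$b == truth$planted_hub & edges$a == s)
    expect_true(any(hit))
  }
  pw <- sim$pathways[[truth$planted_pathway]]$genes
  expect_identical(length(intersect(pw, truth$planted_genes)),
                   as.integer(cfg$planted_pathway_overlap))
  expect_length(sim$pathways, cfg$pathway_count)
})

test_that("planted gene pairs are strongly co-expressed (latent-factor construction)", {
  hits <- 0L; pairs <- 0L
  for (seed in 1:100) {
    sim <- simulate_egonet_data(
      synthetic_config(n_genes = 30, planted_module_size = 6,
                       effect_size = 3, within_module_correlation = 0.9,
                       noise_sd = 1, seed = seed))
    x <- sim$expression$values[sim$truth$planted_genes, ]
    r <- cor(t(x))
    vals <- abs(r[upper.tri(r)])
    hits <- hits + sum(vals > 0.8)
    pairs <- pairs + length(vals)
  }
  expect_gte(hits / pairs, 0.95)
})

test_that("null data give nominal edge-test size", {
  # effect 0, correlation 0: the one-sided edge test should reject at ~alpha
  total <- 0L; rejected <- 0L
  for (seed in 1:100) {
    sim <- simulate_egonet_data(
      synthetic_config(n_genes = 40, effect_size = 0,
                       within_module_correlation = 0, seed = seed))
    st <- edge_statistics(sim$expression, sim$network)
    rejected <- rejected + sum(st$p_value < 0.05)
    total <- total + nrow(st)
  }
  rate <- rejected / total
  # binomial tolerance around 0.05 (correlated edges inflate the variance a
  # little; allow 4 nominal standard errors)
  tol <- 4 * sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 0.015 + tol)
})

test_that("planted-module classifier AUC is monotone in effect size", {
  effects <- c(0, 1, 2, 3)
  mean_auc <- sapply(effects, function(es) {
    mean(sapply(1:20, function(seed) {
      sim <- simulate_egonet_data(
        synthetic_config(n_genes = 30, effect_size = es, seed = seed))
      as.numeric(module_auc(sim$truth$planted_genes, sim$expression))
    }))
  })
  expect_true(all(diff(mean_auc) >= 0))
  expect_lt(mean_auc[1], 0.7)
  expect_gt(mean_auc[4], 0.95)
})

test_that("fixtures round-trip losslessly through the readers", {
  sim <- simulate_egonet_data(synthetic_config(n_genes = 60, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  expect_true(all(file.exists(paths)))

  expr2 <- read_expression(paths["expression"], paths["labels"])
  expect_identical(expr2$values, sim$expression$values)
  expect_identical(expr2$labels, sim$expression$labels)

  net2 <- read_edgelist(paths["edges"])
  expect_identical(net2$edges, sim$network$edges)

  pw2 <- read_gmt(paths["gmt"])
  expect_identical(length(pw2), length(sim$pathways))
  expect_identical(pw2[[sim$truth$planted_pathway]]$genes,
                   sim$pathways[[sim$truth$planted_pathway]]$genes)
  expect_identical(length(readLines(paths["gmt"])), length(sim$pathways))

  manifest <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  expect_identical(manifest$planted_genes, sim$truth$planted_genes)
  expect_identical(manifest$planted_hub, sim$truth$planted_hub)
})

test_that("identical seeds write byte-identical fixture files", {
  cfg <- synthetic_config(n_genes = 40, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture(simulate_egonet_data(cfg), d1)
  p2 <- write_fixture(simulate_egonet_data(cfg), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})
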