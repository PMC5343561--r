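test_that("AUC equals brute-force pair counting on the held-out decision values", {
  # fixed decision values (0.9, 0.8, 0.4 | 0.6, 0.3, 0.1): 8 of 9
  # case-control pairs concordant
  dv <- c(0.9, 0.8, 0.4, 0.6, 0.3, 0.1)
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(egonetr:::rank_sum_auc(dv, pos), 8 / 9, tolerance = 1e-12)
  expect_equal(pair_count_auc(dv, pos), 8 / 9, tolerance = 1e-12)

  # ties count one half
  dv2 <- c(0.5, 0.7, 0.5, 0.2)
  pos2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(egonetr:::rank_sum_auc(dv2, pos2),
               pair_count_auc(dv2, pos2), tolerance = 1e-12)

  # and on real cross-validated decision values
  sim <- simulate_egonet_data(synthetic_config(n_genes = 40, seed = 12,
                                               effect_size = 1))
  auc <- module_auc(sim$truth$planted_genes[1:3], sim$expression)
  dv3 <- attr(auc, "decision_values")
  expect_equal(as.numeric(auc),
               pair_count_auc(dv3, sim$expression$labels == "case"),
               tolerance = 1e-12)
})

test_that("a perfectly separating gene reaches AUC 1", {
  expr <- separable_expr()
  expect_equal(as.numeric(module_auc("SEP", expr)), 1, tolerance = 1e-12)
})

test_that("AUC does not depend on which group is called 'case'", {
  # a class-symmetric classifier gives the same AUC after a label swap:
  # decision values negate and the positive class swaps simultaneously
  sim <- simulate_egonet_data(synthetic_config(n_genes = 40, seed = 13,
                                               effect_size = 1.5))
  genes <- sim$truth$planted_genes[1:4]
  auc <- module_auc(genes, sim$expression)
  flipped <- ifelse(sim$expression$labels == "case", "control", "case")
  auc_flip <- module_auc(genes, sim$expression, labels = flipped)
  expect_equal(as.numeric(auc_flip), as.numeric(auc), tolerance = 1e-9)
  expect_equal(unname(attr(auc_flip, "decision_values")),
               unname(-attr(auc, "decision_values")), tolerance = 1e-6)
})

test_that("AUC is approximately 0.5 on null data", {
  aucs <- sapply(1:100, function(seed) {
    sim <- simulate_egonet_data(
      synthetic_config(n_genes = 20, effect_size = 0,
                       within_module_correlation = 0, seed = seed))
    as.numeric(module_auc(sim$truth$planted_genes, sim$expression))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("module_auc validates its inputs", {
  expr <- separable_expr()
  expect_error(module_auc(character(), expr), "empty")
  expect_error(module_auc("NOPE", expr), "NOPE")
  expect_error(module_auc("SEP", expr, labels = rep("case", 9)), "class")
})

test_that("strict mode stops when no neighbour strictly improves", {
  # SEP alone is perfect; adding noise genes cannot strictly improve
  expr <- separable_expr()
  net <- toy_net(rbind(c("SEP", "N1"), c("SEP", "N2")))
  mod <- expand_ego("SEP", net, expr, allow_plateau = FALSE)
  expect_identical(mod$genes, "SEP")
  expect_equal(mod$auc, 1, tolerance = 1e-12)
  expect_identical(nrow(mod$trace), 1L)
  expect_true(all(diff(mod$trace$auc) > 0))
})

test_that("plateau mode absorbs AUC-neutral neighbours of a saturated module", {
  sim <- simulate_egonet_data(synthetic_config(n_genes = 60, seed = 16))
  bg <- build_background_ppin(sim$expression, sim$network)
  den <- suppressMessages(extract_den(edge_statistics(sim$expression, bg)))
  hub <- sim$truth$planted_hub
  mod <- expand_ego(hub, den, sim$expression)
  strictmod <- expand_ego(hub, den, sim$expression, allow_plateau = FALSE)
  expect_gte(length(mod$genes), length(strictmod$genes))
  expect_true(all(strictmod$genes %in% mod$genes) ||
                length(strictmod$genes) <= length(mod$genes))
  # a strongly planted module is recovered in majority in plateau mode
  expect_gte(length(intersect(mod$genes, sim$truth$planted_genes)), 3L)
})

test_that("equal AUC gains break ties toward the higher z-score", {
  # two identical candidate genes: expansion must pick the higher-z one
  set.seed(7)
  base <- c(rnorm(5, 2), rnorm(4, 0))
  m <- rbind(EGO = base + rnorm(9, 0, 1.5),
             ZLO = base, ZHI = base)
  colnames(m) <- sprintf("S%d", 1:9)
  expr <- expression_dataset(m, c(rep("case", 5), rep("control", 4)))
  net <- toy_net(rbind(c("EGO", "ZLO"), c("EGO", "ZHI")))
  mod <- expand_ego("EGO", net, expr, z = c(EGO = 3, ZLO = 0.1, ZHI = 2))
  if (length(mod$genes) > 1) expect_identical(mod$genes[2], "ZHI")
  mod2 <- expand_ego("EGO", net, expr,
                     z = c(EGO = 3, ZLO = 2.5, ZHI = 2))
  if (length(mod2$genes) > 1) expect_identical(mod2$genes[2], "ZLO")
  expect_identical(length(mod$genes), length(mod2$genes))
})

test_that("expansion traces never drop and the size cap is respected", {
  sim <- simulate_egonet_data(synthetic_config(n_genes = 60, seed = 14,
                                               effect_size = 1))
  bg <- build_background_ppin(sim$expression, sim$network)
  st <- edge_statistics(sim$expression, bg)
  den <- suppressMessages(extract_den(st, pcc_threshold = 0.3,
                                      p_threshold = 0.5))
  ego <- den$nodes[1]
  mod <- expand_ego(ego, den, sim$expression, size_cap = 5)
  expect_lte(length(mod$genes), 5L)
  expect_identical(mod$genes[1], mod$ego_gene)
  expect_true(all(diff(mod$trace$auc) >= -1e-9))  # never drops
  expect_equal(mod$auc,
               as.numeric(module_auc(mod$genes, sim$expression)),
               tolerance = 1e-12)
  expect_error(expand_ego("NOT_A_NODE", den, sim$expression), "NOT_A_NODE")
})

test_that("module filtering keeps AUC >= 0.8 and size >= 4, order preserved", {
  cand <- function(id, auc, size)
    structure(list(module_id = id, ego_gene = "E",
                   genes = sprintf("g%d", seq_len(size)), auc = auc,
                   trace = NULL), class = "candidate_module")
  candidates <- list(cand("M1", 0.75, 2), cand("M2", 1, 4),
                     cand("M3", 1, 6), cand("M4", 1, 5),
                     cand("M5", 1, 6), cand("M6", 1, 6),
                     cand("M7", 0.94, 3))
  kept <- filter_modules(candidates)
  expect_length(kept, 5L)
  expect_identical(vapply(kept, `[[`, "", "module_id"),
                   c("M2", "M3", "M4", "M5", "M6"))

  expect_length(filter_modules(list()), 0L)
  # inclusive boundaries
  expect_length(filter_modules(list(cand("MB", 0.8, 4))), 1L)
  expect_length(filter_modules(list(cand("MB", 0.7999, 4))), 0L)
})

test_that("one candidate module is grown per ego gene", {
  sim <- simulate_egonet_data(synthetic_config(n_genes = 150, seed = 15))
  fit <- egonet(sim$expression, sim$network,
                control = egonet_control(perm_B = 5), seed = 15)
  expect_identical(length(fit$candidates), length(fit$ego_genes))
  for (i in seq_along(fit$candidates))
    expect_identical(fit$candidates[[i]]$ego_gene, fit$ego_genes[i])
})
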