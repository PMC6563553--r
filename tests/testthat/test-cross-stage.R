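pres_fixture <- function(seed = 3) {
  cfg <- sim_config(
    n_samples_per_group = 12, n_modules = 3, module_sizes = c(40, 50, 60),
    n_background_genes = 50, trait_effect_sizes = rep(0, 3),
    preserved_fraction = 0, seed = seed
  )
  sim <- simulate_two_stage_counts(cfg)
  list(
    expr1 = suppressWarnings(vst_counts(sim$counts1)),
    expr2 = suppressWarnings(vst_counts(sim$counts2)),
    labels = stats::setNames(
      ifelse(sim$truth$gene_module_stage1 == "none", "grey",
        sim$truth$gene_module_stage1
      ),
      sim$truth$genes
    )
  )
}

test_that("self-copied modules score strong preservation, scrambled ones none", {
  fx <- pres_fixture()
  self <- module_preservation(fx$expr1, fx$labels, fx$expr1,
    n_perm = 100, beta = 6, seed = 1
  )
  expect_true(all(self$Z_summary > 10))
  expect_true(all(self$evidence == "strong"))
  # in the second stage every module's genes were re-drawn onto new scores
  noise <- module_preservation(fx$expr1, fx$labels, fx$expr2,
    n_perm = 100, beta = 6, seed = 1
  )
  expect_true(all(noise$Z_summary < 2))
  # ordering: preservation against self always exceeds against noise
  expect_true(all(self$Z_summary > noise$Z_summary))
})

test_that("preservation evidence classes follow the 2/10 thresholds", {
  expect_equal(preservation_class(c(-1, 0, 1.99)), rep("none", 3))
  expect_equal(preservation_class(c(2, 5, 10)), rep("weak-to-moderate", 3))
  expect_equal(preservation_class(c(10.01, 50)), rep("strong", 2))
})

test_that("module overlap cross-tabulation counts and tests match the margins", {
  genes <- paste0("g", 1:100)
  la <- stats::setNames(rep(c("turquoise", "blue", "grey"), c(40, 40, 20)), genes)
  # identical partitions: diagonal cells equal module sizes, minimal p
  ot <- module_overlap_table(la, la)
  expect_equal(sum(ot$counts), 100)
  expect_equal(unname(ot$counts["turquoise", "turquoise"]), 40)
  expect_equal(unname(ot$counts["blue", "blue"]), 40)
  min_p_tt <- oracle_fisher_p(matrix(c(40, 0, 0, 60), 2, byrow = TRUE))
  expect_equal(unname(ot$p["turquoise", "turquoise"]), min_p_tt, tolerance = 1e-9)
  # one partition lumping everything: rows reproduce B's sizes, all p = 1
  lb <- stats::setNames(rep("turquoise", 100), genes)
  ot2 <- module_overlap_table(lb, la)
  expect_equal(
    as.numeric(ot2$counts["turquoise", ]),
    as.numeric(table(la)[colnames(ot2$counts)])
  )
  expect_true(all(ot2$p == 1))
  # grand total conserved under relabeling
  la_rot <- stats::setNames(rep(c("blue", "turquoise", "grey"), c(40, 40, 20)), genes)
  expect_equal(sum(module_overlap_table(la_rot, la)$counts), 100)
  expect_error(
    module_overlap_table(
      stats::setNames("turquoise", "a"),
      stats::setNames("blue", "b")
    ),
    "disjoint"
  )
})

test_that("consensus over identical datasets equals single-dataset modules", {
  fx <- pres_fixture(seed = 6)
  det <- suppressWarnings(detect_modules(fx$expr1, network_config(beta = 6)))
  cons <- suppressWarnings(
    consensus_modules(list(a = fx$expr1, b = fx$expr1), network_config(beta = 6))
  )
  expect_equal(
    mclust::adjustedRandIndex(det$modules$labels, cons$modules$labels), 1
  )
  # invariant to dataset order up to label names
  cons_rev <- suppressWarnings(
    consensus_modules(list(b = fx$expr1, a = fx$expr1), network_config(beta = 6))
  )
  expect_equal(
    mclust::adjustedRandIndex(cons$modules$labels, cons_rev$modules$labels), 1
  )
})

test_that("a module planted in only one dataset is absent from the consensus", {
  fx <- pres_fixture(seed = 9)
  # dataset 2: same gene universe, no planted structure (one 1-gene module)
  noise_cfg <- sim_config(
    n_samples_per_group = 12, n_modules = 1, module_sizes = 1,
    n_background_genes = 199, trait_effect_sizes = 0, seed = 10
  )
  noise_sim <- simulate_two_stage_counts(noise_cfg)
  expr_noise <- suppressWarnings(vst_counts(noise_sim$counts1))
  cons <- suppressWarnings(
    consensus_modules(list(fx$expr1, expr_noise), network_config(beta = 6))
  )
  labels <- cons$modules$labels
  for (m in c("module1", "module2", "module3")) {
    members <- names(fx$labels)[fx$labels == m]
    in_mods <- labels[members] != "grey"
    # at most a stray few genes may land in some consensus module
    expect_lt(mean(in_mods), 0.5)
  }
})

test_that("a module planted in both datasets is recovered by the consensus", {
  cfg <- sim_config(
    n_samples_per_group = 12, n_modules = 3, module_sizes = c(40, 50, 60),
    n_background_genes = 50, trait_effect_sizes = rep(0, 3),
    preserved_fraction = 1, seed = 12
  )
  sim <- simulate_two_stage_counts(cfg)
  e1 <- suppressWarnings(vst_counts(sim$counts1))
  e2 <- suppressWarnings(vst_counts(sim$counts2))
  cons <- suppressWarnings(consensus_modules(list(e1, e2), network_config(beta = 6)))
  truth <- sim$truth$gene_module_stage1
  ari <- mclust::adjustedRandIndex(cons$modules$labels, truth)
  expect_gt(ari, 0.7)
  expect_length(cons$eigengenes, 2)
})
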