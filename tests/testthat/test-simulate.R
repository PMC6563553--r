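test_that("simulated counts respect the configured design", {
  cfg <- sim_config(seed = 42)
  sim <- simulate_two_stage_counts(cfg)
  for (m in list(sim$counts1, sim$counts2)) {
    expect_true(is.integer(m))
    expect_true(all(m >= 0))
    expect_equal(dim(m), c(400, 12))
    # library sizes near the configured range (negative-binomial wiggle)
    expect_true(all(colSums(m) > 0.8 * cfg$library_size_range[1]))
    expect_true(all(colSums(m) < 1.2 * cfg$library_size_range[2]))
  }
  expect_equal(sim$meta1$morph, rep(c("benthic", "limnetic"), each = 6))
  # every gene appears exactly once in the module map
  expect_setequal(names(sim$truth$gene_module_stage1), rownames(sim$counts1))
  # bit-identical reruns under the same seed
  sim2 <- simulate_two_stage_counts(cfg)
  expect_identical(sim$counts1, sim2$counts1)
  expect_identical(sim$counts2, sim2$counts2)
})

test_that("full preservation keeps the stage-2 module map identical", {
  cfg <- sim_config(preserved_fraction = 1, seed = 5)
  sim <- simulate_two_stage_counts(cfg)
  expect_identical(sim$truth$gene_module_stage1, sim$truth$gene_module_stage2)
  cfg0 <- sim_config(preserved_fraction = 0, seed = 5)
  sim0 <- simulate_two_stage_counts(cfg0)
  expect_true(all(sim0$truth$module_preserved == FALSE))
  moved <- sim0$truth$gene_module_stage1 != sim0$truth$gene_module_stage2
  expect_true(mean(moved[sim0$truth$gene_module_stage1 != "none"]) > 0.5)
})

test_that("planted modules are tight and mutually independent after transform", {
  cfg <- sim_config(
    n_samples_per_group = 12, trait_effect_sizes = rep(0, 6), seed = 7
  )
  sim <- simulate_two_stage_counts(cfg)
  expr <- suppressWarnings(vst_counts(sim$counts1))
  truth <- sim$truth$gene_module_stage1
  cm <- cor(expr)
  within <- c()
  between <- c()
  for (m in paste0("module", 1:6)) {
    g <- names(truth)[truth == m]
    sub <- cm[g, g]
    within <- c(within, mean(sub[upper.tri(sub)]))
    other <- names(truth)[!(truth %in% c(m, "none"))]
    between <- c(between, mean(cm[g, other]))
  }
  expect_true(all(within >= 0.3))
  expect_lt(max(abs(between)), 0.12)
})

test_that("eigengene-trait correlation grows monotonically with the planted effect", {
  deltas <- c(0, 0.5, 1, 2)
  avg_abs_cor <- sapply(deltas, function(d) {
    mean(sapply(1:20, function(s) {
      cfg <- sim_config(
        n_samples_per_group = 6, n_modules = 1, module_sizes = 40,
        n_background_genes = 0, trait_effect_sizes = d,
        seed = 900 + s
      )
      sim <- simulate_two_stage_counts(cfg)
      expr <- suppressWarnings(vst_counts(sim$counts1))
      eg <- compute_eigengenes(
        expr, stats::setNames(sim$truth$gene_module_stage1, sim$truth$genes)
      )
      abs(cor(eg$scores[, 1], trait_vector(sim$meta1$morph)))
    }))
  })
  expect_true(all(diff(avg_abs_cor) > 0))
})

test_that("simulated genomes place transcripts uniformly unless enrichment is planted", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_two_stage_counts(cfg)
  # uniform placement: mean overlap over 100 draws matches the closed form
  obs <- sapply(1:100, function(i) {
    gen <- simulate_genome(sim$truth,
      n_linkage_groups = 4, genome_length = 4e6,
      n_qtl = 6, qtl_length = 1e5, seed = 5000 + i
    )
    count_overlaps(gen$transcripts, gen$qtl)
  })
  # each QTL covers 1e5 of 4e6 with 1kb transcripts; QTL may overlap each other,
  # so the disjoint-union expectation is an upper bound and the mean must sit
  # within a few SE below it
  n_genes <- length(sim$truth$genes)
  upper <- n_genes * 6 * (1e5 + 999) / 1e6 / 4
  expect_lt(mean(obs), upper + 3 * sd(obs) / 10)
  expect_gt(mean(obs), upper * 0.75)
  # planted enrichment with probability 1: all module transcripts inside QTL
  gen1 <- simulate_genome(sim$truth,
    enriched_module = "module1",
    enrichment_prob = 1, seed = 77
  )
  m1 <- names(sim$truth$gene_module_stage1)[sim$truth$gene_module_stage1 == "module1"]
  m1_regions <- region_set(
    gen1$transcripts$intervals[gen1$transcripts$intervals$name %in% m1, ],
    gen1$transcripts$genome
  )
  expect_equal(count_overlaps(m1_regions, gen1$qtl), length(m1))
  # one linkage group fully covered by one QTL: every transcript overlaps
  gen_full <- simulate_genome(sim$truth,
    n_linkage_groups = 1, genome_length = 1e6,
    n_qtl = 1, qtl_length = 1e6, seed = 78
  )
  expect_equal(
    count_overlaps(gen_full$transcripts, gen_full$qtl),
    length(sim$truth$genes)
  )
  expect_error(
    simulate_genome(sim$truth, n_linkage_groups = 4, genome_length = 4e5, qtl_length = 2e5),
    "longer than"
  )
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(module_sizes = rep(10, 5)), "length n_modules")
  expect_error(sim_config(trait_effect_sizes = c(1, 2)), "length n_modules")
  expect_error(sim_config(loading_range = c(0, 1.5)), "within")
  expect_error(sim_config(nb_dispersion = -1), "positive")
  expect_error(sim_config(preserved_fraction = 1.5), "\\[0, 1\\]")
})
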