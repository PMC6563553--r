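make_eigengene_fixture <- function(scores) {
  structure(
    list(
      scores = scores,
      prop_var = stats::setNames(rep(0.5, ncol(scores)), colnames(scores)),
      kME = NULL
    ),
    class = "eigengene_matrix"
  )
}

test_that("trait coding is benthic 0 / limnetic 1 and rejects bad input", {
  tv <- trait_vector(c("benthic", "limnetic", "benthic"))
  expect_equal(unname(tv), c(0, 1, 0))
  expect_error(trait_vector(c("benthic", "pelagic")), "morph")
  expect_error(trait_vector(rep("benthic", 4)), "constant")
})

test_that("eigengene-trait association recovers exact and null relations", {
  trait <- rep(c(0, 1), each = 6)
  me_hit <- as.numeric(scale(trait))
  # orthogonal by construction: equal group means
  me_null <- rep(c(-1, 1), 6)
  scores <- cbind(hit = me_hit, null = me_null / sd(me_null))
  eg <- make_eigengene_fixture(scores)
  res <- eigengene_trait_association(eg, trait)
  expect_equal(res$table$r[res$table$module == "hit"], 1, tolerance = 1e-10)
  expect_lt(res$table$p[res$table$module == "hit"], 1e-10)
  expect_equal(res$table$r[res$table$module == "null"], 0, tolerance = 1e-10)
  expect_true(all(res$table$q >= res$table$p))
  expect_true(all(res$table$selected == (res$table$q <= 0.05)))
  expect_error(
    eigengene_trait_association(eg, rep(0, 12)),
    "non-constant"
  )
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(0.37), 0.37)
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- runif(20)^2
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
  p20 <- c(0.001, 0.02, 0.03, seq(0.05, 0.9, length.out = 17))
  expect_equal(bh_adjust(p20), oracle_bh(p20), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("candidate rule requires both |kME| and |GS| strictly above threshold", {
  genes <- paste0("g", 1:6)
  labels <- stats::setNames(rep("turquoise", 6), genes)
  kme <- matrix(c(0.71, -0.9, 0.8, 0.69, 0.75, NA), ncol = 1,
    dimnames = list(genes, "turquoise")
  )
  gs <- stats::setNames(c(0.69, -0.8, 0.71, 0.9, 0.7, 0.8), genes)
  stats <- structure(
    list(
      table = data.frame(
        module = "turquoise", r = 0.9, p = 1e-4, q = 1e-4, selected = TRUE
      ),
      GS = gs, kME = kme, fdr_level = 0.05
    ),
    class = "module_trait_stats"
  )
  cand <- select_candidates(stats, labels, threshold = 0.7)
  # g1: GS 0.69 fails; g2: both negative but |.| > 0.7 passes; g3 passes;
  # g4: kME 0.69 fails; g5: GS = 0.7 not strictly above; g6: NA kME excluded
  expect_setequal(cand$turquoise$gene, c("g2", "g3"))
  all_cand <- select_candidates(stats, labels, threshold = 0)
  expect_setequal(all_cand$turquoise$gene, paste0("g", 1:5))
  # monotone non-increasing in threshold
  sizes <- sapply(c(0, 0.3, 0.5, 0.7, 0.85), function(th) {
    nrow(select_candidates(stats, labels, threshold = th)$turquoise)
  })
  expect_true(all(diff(sizes) <= 0))
  expect_error(select_candidates(stats, labels, which_modules = "blue"), "selected")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  mod <- paste0("m", 1:10)
  bg <- paste0("b", 1:10)
  de <- stats::setNames(c(rep(TRUE, 10), rep(FALSE, 10)), c(mod, bg))
  res <- fisher_module_enrichment(mod, de, bg)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p, oracle_fisher_p(res$table), tolerance = 1e-12)
  # balanced table: no association
  de2 <- stats::setNames(rep(c(TRUE, FALSE), 10), c(mod, bg))
  res2 <- fisher_module_enrichment(mod, de2, bg)
  expect_equal(res2$p, 1)
  expect_equal(res2$odds_ratio, 1)
  # degenerate margin: everything DE
  de3 <- stats::setNames(rep(TRUE, 20), c(mod, bg))
  res3 <- fisher_module_enrichment(mod, de3, bg)
  expect_equal(res3$p, 1)
  expect_true(res3$degenerate)
  # random tables against the enumeration oracle
  withr::with_seed(31, {
    for (i in 1:10) {
      n_mod <- sample(5:15, 1)
      n_bg <- sample(5:15, 1)
      flags <- stats::setNames(
        sample(c(TRUE, FALSE), n_mod + n_bg, replace = TRUE),
        c(paste0("m", seq_len(n_mod)), paste0("b", seq_len(n_bg)))
      )
      mm <- paste0("m", seq_len(n_mod))
      bb <- paste0("b", seq_len(n_bg))
      r <- fisher_module_enrichment(mm, flags, bb)
      if (!r$degenerate) {
        expect_equal(r$p, oracle_fisher_p(r$table), tolerance = 1e-9)
      }
    }
  })
})

test_that("under the simulation null the module-trait test is calibrated", {
  # 500 null modules: 100 small two-stage draws x 5 modules, no trait effect
  ps <- unlist(lapply(1:100, function(s) {
    cfg <- sim_config(
      n_samples_per_group = 12, n_modules = 5, module_sizes = rep(30, 5),
      n_background_genes = 0, trait_effect_sizes = rep(0, 5), seed = 4000 + s
    )
    sim <- simulate_two_stage_counts(cfg)
    expr <- suppressWarnings(vst_counts(sim$counts1))
    labels <- sim$truth$gene_module_stage1
    eg <- compute_eigengenes(expr, stats::setNames(labels, names(labels)))
    trait <- trait_vector(sim$meta1$morph)
    eigengene_trait_association(eg, trait)$table$p
  }))
  n <- length(ps)
  expect_gte(n, 500)
  hits <- sum(ps <= 0.05)
  expect_gte(hits, qbinom(0.025, n, 0.05))
  expect_lte(hits, qbinom(0.975, n, 0.05))
})
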