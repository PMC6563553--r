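test_that("eigenvalue test statistic matches an eigendecomposition oracle", {
  withr::with_seed(17, {
    base <- rnorm(20)
    expr <- sapply(1:30, function(i) base + rnorm(20, sd = 0.05))
    colnames(expr) <- paste0("g", 1:30)
  })
  res <- eigenvalue_permutation_test(expr, n_perm = 200, cor_type = "pearson", seed = 1)
  ev <- eigen(cor(expr), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(res$observed_stat, ev[1] / sum(ev), tolerance = 1e-10)
  expect_gt(res$observed_stat, 0.95) # near rank-1 module
  expect_equal(res$p, 0)
  # statistic bounds: (1/p, 1]
  expect_gt(res$observed_stat, 1 / 30)
  expect_lte(res$observed_stat, 1)
})

test_that("bicor variant runs and the null is reproducible under a fixed seed", {
  withr::with_seed(2, {
    x <- matrix(rnorm(15 * 10), 15, 10)
  })
  r1 <- eigenvalue_permutation_test(x, n_perm = 50, cor_type = "bicor", seed = 99)
  r2 <- eigenvalue_permutation_test(x, n_perm = 50, cor_type = "bicor", seed = 99)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_equal(r1$p, sum(r1$null_stats >= r1$observed_stat) / 50)
})

test_that("joint row permutation cannot disturb the statistic", {
  withr::with_seed(4, {
    x <- matrix(rnorm(12 * 8), 12, 8)
  })
  res <- eigenvalue_permutation_test(x, n_perm = 30, seed = 5, permute_rows = TRUE)
  expect_equal(res$null_stats, rep(res$observed_stat, 30), tolerance = 1e-10)
})

test_that("RV coefficient matches the trace oracle and its invariances", {
  x <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  y <- x[, 1, drop = FALSE]
  expect_equal(rv_coefficient(x, y), oracle_rv(x, y), tolerance = 1e-12)
  # one-column RV is the squared Pearson correlation
  withr::with_seed(8, {
    a <- rnorm(10)
    b <- 0.3 * a + rnorm(10)
    expect_equal(rv_coefficient(a, b), cor(a, b)^2, tolerance = 1e-12)
    # self-congruence and rotation invariance
    m <- matrix(rnorm(12 * 4), 12, 4)
    expect_equal(rv_coefficient(m, m), 1, tolerance = 1e-12)
    q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    expect_equal(rv_coefficient(m, m %*% q), 1, tolerance = 1e-12)
    expect_equal(rv_coefficient(m, m * 3 + 5), 1, tolerance = 1e-12)
  })
  expect_error(rv_coefficient(matrix(0, 3, 2), x), "zero total variance")
})

test_that("RV permutation test pins perfect association and ignores trait recoding", {
  trait <- rep(c(0, 1), each = 5)
  expr <- cbind(trait, trait) + 0
  res <- rv_permutation_test(expr, trait, n_perm = 100, seed = 3)
  expect_equal(res$observed_stat, 1, tolerance = 1e-12)
  # only label permutations recreating the trait (or its mirror) can tie
  expect_equal(res$p, mean(res$null_stats >= res$observed_stat - 1e-12))
  expect_lte(res$p, 0.05)
  # reversing the 0/1 coding changes nothing
  withr::with_seed(6, {
    x <- matrix(rnorm(10 * 6), 10, 6)
  })
  r1 <- rv_permutation_test(x, trait, n_perm = 50, seed = 11)
  r2 <- rv_permutation_test(x, 1 - trait, n_perm = 50, seed = 11)
  expect_equal(r1$observed_stat, r2$observed_stat, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)
  expect_warning(rv_permutation_test(x, trait, n_perm = 10, seed = 1), "resolution")
})

test_that("RV test power increases with the planted trait effect", {
  power_at <- function(delta) {
    mean(sapply(1:50, function(s) {
      cfg <- sim_config(
        n_samples_per_group = 12, n_modules = 1, module_sizes = 30,
        n_background_genes = 0, trait_effect_sizes = delta, seed = 7000 + s
      )
      sim <- simulate_two_stage_counts(cfg)
      expr <- suppressWarnings(vst_counts(sim$counts1))
      rv_permutation_test(
        expr, trait_vector(sim$meta1$morph),
        n_perm = 100, seed = s
      )$p <= 0.05
    }))
  }
  powers <- sapply(c(0, 0.5, 1, 2), power_at)
  # non-decreasing up to binomial noise at 50 replicates (2 SE at p ~ 0.1)
  expect_true(all(diff(powers) >= -0.09))
  # null rejection rate within the exact binomial band around 0.05
  expect_lte(50 * powers[1], qbinom(0.975, 50, 0.05))
  # a strong planted effect is rejected well above the nominal rate
  expect_gt(50 * powers[4], qbinom(0.975, 50, 0.05))
  expect_gt(powers[4], powers[1])
})
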