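toy_genome <- c(LG1 = 1000, LG2 = 2000)

test_that("region sets enforce BED conventions", {
  rs <- region_set(data.frame(chrom = "LG1", start = 0, end = 100), toy_genome)
  expect_equal(rs$intervals$end - rs$intervals$start, 100)
  expect_error(
    region_set(data.frame(chrom = "LG1", start = 100, end = 100), toy_genome),
    "start >= end"
  )
  expect_error(
    region_set(data.frame(chrom = "LG3", start = 0, end = 10), toy_genome),
    "absent from genome"
  )
  expect_error(
    region_set(data.frame(chrom = "LG1", start = 900, end = 1100), toy_genome),
    "outside"
  )
})

test_that("BED files round-trip bit-identically", {
  rs <- region_set(
    data.frame(
      chrom = c("LG1", "LG2", "LG2"), start = c(0, 10, 500),
      end = c(100, 400, 1500), name = c("a", "b", "c")
    ),
    toy_genome
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions(rs, path)
  first <- readBin(path, "raw", file.size(path))
  rs2 <- read_regions(path, toy_genome)
  expect_equal(rs2$intervals, rs$intervals)
  write_regions(rs2, path)
  expect_identical(readBin(path, "raw", file.size(path)), first)
  # malformed input
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("LG1\t100\t100\tx", bad)
  expect_error(read_regions(bad, toy_genome), "start >= end")
})

test_that("overlap counting is half-open with >= 1 bp intersection", {
  q <- region_set(data.frame(chrom = "LG1", start = 0, end = 100), toy_genome)
  s_abut <- region_set(data.frame(chrom = "LG1", start = 100, end = 200), toy_genome)
  expect_equal(count_overlaps(q, s_abut), 0)
  q2 <- region_set(data.frame(chrom = "LG1", start = 50, end = 150), toy_genome)
  expect_equal(count_overlaps(q2, s_abut), 1)
  # whole-genome subject: everything overlaps
  whole <- region_set(
    data.frame(chrom = c("LG1", "LG2"), start = 0, end = c(1000, 2000)),
    toy_genome
  )
  withr::with_seed(20, {
    st <- floor(runif(100, 0, 900))
    q3 <- region_set(
      data.frame(
        chrom = sample(names(toy_genome), 100, replace = TRUE),
        start = st, end = st + 50
      ),
      toy_genome
    )
  })
  expect_equal(count_overlaps(q3, whole), 100)
})

test_that("region permutation test is deterministic and flags extremes", {
  genome <- c(LG1 = 1e5, LG2 = 1e5)
  withr::with_seed(21, {
    st <- floor(runif(40, 0, 9e4))
    subj <- region_set(
      data.frame(
        chrom = sample(names(genome), 40, replace = TRUE),
        start = st, end = st + 2000
      ),
      genome
    )
  })
  # query identical to a subject covering a small genome fraction
  res <- region_permutation_test(subj, subj, n_perm = 200, seed = 7)
  expect_equal(res$observed, 40)
  expect_equal(res$p, mean(res$null >= res$observed))
  expect_lte(res$p, 0.05)
  res2 <- region_permutation_test(subj, subj, n_perm = 200, seed = 7)
  expect_identical(res$null, res2$null)
  expect_true(all(res$null <= 40))
  # intervals longer than their linkage group are rejected
  too_long <- structure(
    list(
      intervals = data.frame(
        chrom = "LG1", start = 0, end = 1e5, name = "big"
      ),
      genome = c(LG1 = 1e5 - 1)
    ),
    class = "region_set"
  )
  expect_error(
    region_permutation_test(too_long, subj, n_perm = 10, seed = 1),
    "longer than its linkage group"
  )
})

test_that("mean null overlap matches the uniform-placement expectation", {
  # subject covering 20% of each linkage group
  genome <- c(LG1 = 1e5, LG2 = 1e5)
  subj <- region_set(
    data.frame(chrom = c("LG1", "LG2"), start = 0, end = 2e4),
    genome
  )
  withr::with_seed(22, {
    st <- floor(runif(100, 0, 1e5 - 100))
    q <- region_set(
      data.frame(
        chrom = sample(names(genome), 100, replace = TRUE),
        start = st, end = st + 100
      ),
      genome
    )
  })
  res <- region_permutation_test(q, subj, n_perm = 500, seed = 9)
  # P(100bp interval hits [0, 2e4)) = (2e4 + 99) / (1e5 - 99)
  expected <- 100 * (2e4 + 99) / (1e5 - 99)
  expect_lt(
    abs(mean(res$null) - expected),
    3 * sd(res$null) / sqrt(500) + 0.5
  )
})

test_that("overlap battery adjusts across pairs and handles empty sets", {
  genome <- c(LG1 = 1e5)
  subj <- list(
    qtlA = region_set(data.frame(chrom = "LG1", start = 0, end = 2e4), genome),
    qtlB = region_set(data.frame(chrom = "LG1", start = 5e4, end = 6e4), genome)
  )
  withr::with_seed(23, {
    st <- floor(runif(30, 0, 9e4))
    gs <- region_set(data.frame(chrom = "LG1", start = st, end = st + 500), genome)
  })
  empty <- region_set(data.frame(chrom = character(), start = numeric(), end = numeric()), genome)
  bat <- overlap_battery(
    list(genes = gs, none = empty), subj,
    combined = TRUE, n_perm = 100, seed = 2
  )
  expect_equal(nrow(bat), 6) # 2 gene sets x (2 qtl sets + combined)
  expect_true(all(bat$q >= bat$p))
  expect_true(all(bat$p[bat$gene_set == "none"] == 1))
  expect_true(all(bat$empty[bat$gene_set == "none"]))
  # single pair: q equals p
  bat1 <- overlap_battery(list(genes = gs), subj["qtlA"], combined = TRUE, n_perm = 100, seed = 2)
  expect_equal(bat1$q, bat1$p)
  # identical gene sets give identical p-values against the same subject
  bat2 <- overlap_battery(list(a = gs, b = gs), subj["qtlA"], combined = FALSE, n_perm = 100, seed = 5)
  expect_equal(bat2$observed[1], bat2$observed[2])
  expect_equal(bat2$p[1], bat2$p[2])
})
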