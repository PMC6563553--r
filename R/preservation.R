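# Cross-stage module preservation (Z_summary) and module overlap
# cross-tabulation.

# Density and connectivity statistics for the gene set `idx` (indices into the
# common universe). Density statistics describe the test data only; the
# connectivity statistics correlate reference and test network properties of
# the same genes.
.preservation_stats <- function(idx, zr, zt, cor_ref, cor_test, adj_ref, adj_test) {
  sub_cr <- cor_ref[idx, idx]
  sub_ct <- cor_test[idx, idx]
  sub_ar <- adj_ref[idx, idx]
  sub_at <- adj_test[idx, idx]
  # test-side eigengene and explained variance
  svt <- svd(zt[, idx, drop = FALSE], nu = 1, nv = 0)
  svr <- svd(zr[, idx, drop = FALSE], nu = 1, nv = 0)
  prop_var_test <- svt$d[1]^2 / sum(svt$d^2)
  kme_test <- as.numeric(crossprod(zt[, idx, drop = FALSE], svt$u[, 1])) /
    (nrow(zt) - 1)
  kme_ref <- as.numeric(crossprod(zr[, idx, drop = FALSE], svr$u[, 1])) /
    (nrow(zr) - 1)
  # kME sign is arbitrary per dataset; align by absolute correlation
  c_kme <- suppressWarnings(stats::cor(kme_ref, kme_test))
  c(
    mean_adj = mean(off_diag(sub_at)),
    mean_cor = mean(off_diag(sub_ct)),
    prop_var = prop_var_test,
    cor_kim = suppressWarnings(stats::cor(rowSums(sub_ar) - 1, rowSums(sub_at) - 1)),
    cor_kme = if (is.na(c_kme)) NA_real_ else abs(c_kme),
    cor_cor = suppressWarnings(stats::cor(upper_tri(sub_cr), upper_tri(sub_ct)))
  )
}

#' Module preservation Z_summary between a reference and a test dataset
#'
#' Quantifies how well reference modules are maintained in a test dataset by
#' comparing, for each module, observed density statistics (mean within-module
#' adjacency, mean within-module correlation, eigengene explained-variance
#' fraction, all in the test data) and connectivity statistics (reference-test
#' correlations of intramodular connectivity, of kME, and of within-module
#' gene-gene correlations) against their null distributions under random gene
#' sets of the same size. Each statistic is standardized to a Z-score;
#' `Z_density` and `Z_connectivity` are the medians of their three statistics
#' and `Z_summary` is their mean. Evidence classes follow the usual thresholds:
#' below 2 no evidence, 2-10 weak-to-moderate, above 10 strong preservation.
#'
#' @param ref_expr,test_expr samples x genes expression matrices; preservation
#'   is computed on the intersection of their gene universes.
#' @param ref_modules `module_set` (or gene->label vector) of the reference.
#' @param n_perm number of label permutations (default 1000).
#' @param beta soft-thresholding power used for both networks' adjacencies.
#' @param max_p_outliers bicor outlier cap.
#' @param seed integer seed for the permutations.
#' @return data.frame (module, size, Z_density, Z_connectivity, Z_summary,
#'   evidence) with per-statistic observed values attached as attribute
#'   `observed`.
#' @export
module_preservation <- function(ref_expr, ref_modules, test_expr,
                                n_perm = 1000L, beta = 6L,
                                max_p_outliers = 0.1, seed = 1L) {
  ref_expr <- as.matrix(ref_expr)
  test_expr <- as.matrix(test_expr)
  labels <- if (inherits(ref_modules, "module_set")) ref_modules$labels else ref_modules
  common <- intersect(colnames(ref_expr), colnames(test_expr))
  if (length(common) == 0) stopf("gene universes do not intersect")
  ref_expr <- ref_expr[, common, drop = FALSE]
  test_expr <- test_expr[, common, drop = FALSE]
  labels <- labels[common]
  cor_ref <- suppressWarnings(bicor_matrix(ref_expr, max_p_outliers = max_p_outliers))
  cor_test <- suppressWarnings(bicor_matrix(test_expr, max_p_outliers = max_p_outliers))
  adj_ref <- signed_adjacency(cor_ref, beta)
  adj_test <- signed_adjacency(cor_test, beta)
  zr <- scale(ref_expr)
  zt <- scale(test_expr)
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[!is.na(mods)]
  rows <- list()
  observed_list <- list()
  for (m in mods) {
    idx <- which(labels == m)
    if (length(idx) < 3) {
      warning(sprintf("module '%s' has < 3 common genes; skipped", m))
      next
    }
    obs <- .preservation_stats(idx, zr, zt, cor_ref, cor_test, adj_ref, adj_test)
    null <- with_local_seed(derive_seed(seed, match(m, mods)), {
      vapply(seq_len(n_perm), function(i) {
        ridx <- sample(length(common), length(idx))
        .preservation_stats(ridx, zr, zt, cor_ref, cor_test, adj_ref, adj_test)
      }, numeric(6))
    })
    mu <- apply(null, 1, mean, na.rm = TRUE)
    s <- apply(null, 1, stats::sd, na.rm = TRUE)
    # A degenerate null (zero spread, e.g. connectivity statistics when test
    # data equal the reference) carries no evidence and is excluded.
    z <- ifelse(s > 1e-8, (obs - mu) / s, NA_real_)
    z_density <- stats::median(z[c("mean_adj", "mean_cor", "prop_var")], na.rm = TRUE)
    z_conn <- stats::median(z[c("cor_kim", "cor_kme", "cor_cor")], na.rm = TRUE)
    z_summary <- mean(c(z_density, z_conn), na.rm = TRUE)
    if (is.nan(z_summary)) z_summary <- 0
    rows[[m]] <- data.frame(
      module = m, size = length(idx),
      Z_density = z_density, Z_connectivity = z_conn, Z_summary = z_summary,
      evidence = preservation_class(z_summary),
      stringsAsFactors = FALSE
    )
    observed_list[[m]] <- obs
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "observed") <- observed_list
  attr(out, "n_perm") <- as.integer(n_perm)
  out
}

#' Evidence class for a preservation Z_summary
#'
#' @param z_summary numeric Z_summary value(s).
#' @return `"none"` (< 2), `"weak-to-moderate"` (2-10) or `"strong"` (> 10).
#' @export
preservation_class <- function(z_summary) {
  ifelse(z_summary < 2, "none",
    ifelse(z_summary <= 10, "weak-to-moderate", "strong")
  )
}

#' Cross-tabulation of two module partitions with Fisher exact tests
#'
#' Counts, over the common gene universe, how the genes of each module in
#' partition A distribute over the modules of partition B, and tests each
#' (non-grey) cell's overlap with a two-sided Fisher exact test, BH-adjusted
#' across cells.
#'
#' @param modules_a,modules_b `module_set`s (or named gene->label vectors).
#' @return list of class `overlap_table`: `counts` (A modules x B modules,
#'   including grey), `p` and `q` matrices (non-grey cells only), `n_common`.
#' @export
module_overlap_table <- function(modules_a, modules_b) {
  la <- if (inherits(modules_a, "module_set")) modules_a$labels else modules_a
  lb <- if (inherits(modules_b, "module_set")) modules_b$labels else modules_b
  common <- intersect(names(la), names(lb))
  if (length(common) == 0) stopf("gene universes are disjoint")
  la <- la[common]
  lb <- lb[common]
  counts <- table(factor(la), factor(lb))
  mods_a <- setdiff(rownames(counts), "grey")
  mods_b <- setdiff(colnames(counts), "grey")
  p <- matrix(NA_real_, length(mods_a), length(mods_b),
    dimnames = list(mods_a, mods_b)
  )
  n <- length(common)
  for (i in mods_a) {
    for (j in mods_b) {
      a <- counts[i, j]
      tab <- matrix(c(
        a, sum(counts[i, ]) - a,
        sum(counts[, j]) - a, n - sum(counts[i, ]) - sum(counts[, j]) + a
      ), nrow = 2, byrow = TRUE)
      p[i, j] <- stats::fisher.test(tab)$p.value
    }
  }
  q <- p
  q[] <- bh_adjust(as.numeric(p))
  structure(
    list(counts = unclass(counts), p = p, q = q, n_common = n),
    class = "overlap_table"
  )
}
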