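# Count filtering, variance-stabilizing transform and connectivity-based
# sample outlier removal.

#' Filter low-count transcripts
#'
#' Retains a transcript only if its total count across all samples is at least
#' `total_min` AND its summed count within every stage is at least
#' `per_stage_min` (counts are summed over the samples of each stage).
#'
#' @param counts genes x samples integer matrix.
#' @param stage_labels per-sample stage factor/character, one entry per column.
#' @param total_min minimum total count (default 100).
#' @param per_stage_min minimum per-stage summed count (default 50).
#' @return list with `counts` (the retained submatrix) and `n_removed`.
#' @export
filter_low_counts <- function(counts, stage_labels, total_min = 100, per_stage_min = 50) {
  counts <- as.matrix(counts)
  if (length(stage_labels) != ncol(counts)) {
    stopf("stage_labels must have one entry per sample (column)")
  }
  if (anyNA(stage_labels)) stopf("unknown (missing) stage label")
  stage_labels <- as.character(stage_labels)
  total <- rowSums(counts)
  keep <- total >= total_min
  for (s in unique(stage_labels)) {
    stage_sum <- rowSums(counts[, stage_labels == s, drop = FALSE])
    keep <- keep & (stage_sum >= per_stage_min)
  }
  list(counts = counts[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Variance-stabilizing transform of raw counts
#'
#' Library-size normalization by median-of-ratios size factors (computed over
#' genes with all-positive counts) followed by `log2(count / size_factor + 1)`.
#' This keeps abundances comparable across samples and stages while compressing
#' the count-dependent variance; it is monotone in counts within a sample and
#' finite everywhere. An externally computed transformed matrix can be supplied
#' downstream instead wherever an `ExpressionMatrix` is accepted.
#'
#' Note the orientation change: counts are stored genes x samples (the on-disk
#' convention) while all network computation uses samples x genes; this
#' function is the single place where the transpose happens.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return samples x genes matrix of transformed abundances, with attribute
#'   `size_factors`.
#' @export
vst_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(colSums(counts) == 0)) stopf("sample(s) with all-zero counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stopf("no gene has positive counts in every sample; cannot size-factor normalize")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - logg))
  })
  # anchor the median size factor at 1 so a typical sample is unrescaled
  sf <- sf / stats::median(sf)
  expr <- t(log2(sweep(counts, 2, sf, "/") + 1))
  attr(expr, "size_factors") <- sf
  expr
}

#' Iterative removal of outlying samples by standardized connectivity
#'
#' Builds a sample-sample network with signed-square adjacency
#' `A_ij = ((1 + cor(i, j)) / 2)^2` (Pearson, over genes), computes each
#' sample's connectivity `k_i = sum_{j != i} A_ij` and its standardization
#' `Z.k_i = (k_i - mean(k)) / sd(k)`, removes every sample with
#' `Z.k < z_threshold`, and repeats until no sample is removed. When `sd(k)`
#' is zero (e.g. identical samples) all `Z.k` are defined as 0.
#'
#' @param expr samples x genes expression matrix (>= 4 samples).
#' @param z_threshold standardized-connectivity threshold (default -2).
#' @return list with `expr` (retained samples) and `report`, a data.frame with
#'   columns iteration, sample_id, z_k, removed; plus the threshold as an
#'   attribute.
#' @export
remove_outlier_samples <- function(expr, z_threshold = -2) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 4) stopf("need at least 4 samples for outlier screening")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("s", seq_len(nrow(expr)))
  report <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- stats::cor(t(expr))
    a <- ((1 + r) / 2)^2
    diag(a) <- 0
    k <- rowSums(a)
    s <- stats::sd(k)
    zk <- if (is.na(s) || s == 0) rep(0, length(k)) else (k - mean(k)) / s
    removed <- zk < z_threshold
    report[[iter]] <- data.frame(
      iteration = iter, sample_id = rownames(expr),
      z_k = zk, removed = removed, row.names = NULL
    )
    if (!any(removed)) break
    if (nrow(expr) - sum(removed) < 3) {
      stopf(
        "outlier removal would leave fewer than 3 samples (iteration %d)", iter
      )
    }
    expr <- expr[!removed, , drop = FALSE]
  }
  report <- do.call(rbind, report)
  attr(report, "threshold") <- z_threshold
  list(expr = expr, report = report)
}
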