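# Signed weighted network construction: adjacency, soft-threshold selection and
# topological overlap.

#' Network construction parameters
#'
#' Collects the parameters of signed-network construction and module detection.
#' Defaults follow common practice for signed coexpression networks: powers 1-30
#' are scanned for a scale-free fit R^2 of 0.9 and power 20 is used as fallback
#' when no scanned power reaches that target; modules need at least 30 genes and
#' modules whose eigengenes have correlation dissimilarity below 0.25 are
#' merged.
#'
#' @param beta soft-thresholding power; `NULL` selects it via
#'   [pick_soft_threshold()].
#' @param powers_scanned integer powers scanned for the scale-free criterion.
#' @param scale_free_r2_target signed R^2 target for the scale-free fit.
#' @param fallback_beta power used when no scanned power reaches the target.
#' @param max_p_outliers biweight midcorrelation outlier cap, see [bicor()].
#' @param min_module_size smallest allowed module.
#' @param merge_cut_height eigengene correlation dissimilarity (1 - cor) below
#'   which modules are merged.
#' @param coherence_factor module-validation multiplier: a candidate cluster is
#'   kept only if its eigengene explained-variance fraction exceeds
#'   `coherence_factor` times the random-matrix expectation
#'   `(1 + sqrt(q/n))^2 / q` for a module of q genes on n samples.
#' @param pam_kme unassigned genes are attached to the module whose eigengene
#'   they correlate with most, provided that (signed) correlation exceeds this
#'   threshold.
#' @param trim_frac module members whose signed kME falls below `trim_frac`
#'   times the module's median kME are released as unassigned.
#' @param min_mean_k a power is eligible for selection only while the network's
#'   mean connectivity is at least this value; below it the network is
#'   essentially empty and the scale-free fit is meaningless.
#' @param n_bins number of equal-width bins for the scale-free fit.
#' @return a list of class `network_config`.
#' @export
network_config <- function(beta = NULL,
                           powers_scanned = 1:30,
                           scale_free_r2_target = 0.9,
                           fallback_beta = 20L,
                           max_p_outliers = 0.1,
                           min_module_size = 30L,
                           merge_cut_height = 0.25,
                           coherence_factor = 1.25,
                           pam_kme = 0.5,
                           trim_frac = 0.5,
                           min_mean_k = 1,
                           n_bins = 10L) {
  stopifnot(
    is.null(beta) || (beta >= 1),
    all(powers_scanned >= 1),
    scale_free_r2_target > 0, scale_free_r2_target <= 1,
    fallback_beta >= 1,
    max_p_outliers > 0, max_p_outliers <= 0.5,
    min_module_size >= 2,
    merge_cut_height >= 0, merge_cut_height < 1,
    coherence_factor >= 1,
    pam_kme >= 0, pam_kme < 1,
    trim_frac >= 0, trim_frac < 1,
    min_mean_k >= 0,
    n_bins >= 2
  )
  structure(
    list(
      beta = beta, powers_scanned = as.integer(powers_scanned),
      scale_free_r2_target = scale_free_r2_target,
      fallback_beta = as.integer(fallback_beta),
      max_p_outliers = max_p_outliers,
      min_module_size = as.integer(min_module_size),
      merge_cut_height = merge_cut_height,
      coherence_factor = coherence_factor,
      pam_kme = pam_kme,
      trim_frac = trim_frac,
      min_mean_k = min_mean_k,
      n_bins = as.integer(n_bins)
    ),
    class = "network_config"
  )
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + c_ij) / 2)^beta`, the signed weighted adjacency: perfectly
#' anticorrelated genes get adjacency 0, perfectly correlated genes 1. The
#' diagonal is forced to 1.
#'
#' @param cor_matrix correlation matrix with entries in \[-1, 1\].
#' @param beta soft-thresholding power (>= 1).
#' @return adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(cor_matrix, beta) {
  if (beta < 1) stopf("beta must be >= 1")
  cm <- as.matrix(cor_matrix)
  if (any(cm > 1 + 1e-12 | cm < -1 - 1e-12, na.rm = TRUE)) {
    stopf("correlations must lie in [-1, 1]")
  }
  a <- ((1 + cm) / 2)^beta
  diag(a) <- 1
  a
}

#' Choose the soft-thresholding power by the scale-free topology criterion
#'
#' For each scanned power the whole-network connectivities `k_i` are binned
#' (equal-width bins) and log10 of the bin frequency is regressed on log10 of
#' the bin's mean connectivity. The signed fit index is `-sign(slope) * R^2`
#' (scale-free topology requires a decreasing frequency in k). The smallest
#' power reaching `scale_free_r2_target` while the mean connectivity stays at
#' least `min_mean_k` is returned; if none qualifies, `fallback_beta` is
#' returned with a warning.
#'
#' @param expr samples x genes expression matrix (>= 30 genes).
#' @param config a [network_config()].
#' @return list with `beta`, `reached_target` flag, and `fit_table`
#'   (power, signed R^2, mean/median/max connectivity).
#' @export
pick_soft_threshold <- function(expr, config = network_config()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 30) stopf("need at least 30 genes to assess scale-free fit")
  if (all(apply(expr, 2, stats::sd) == 0)) stopf("constant expression matrix")
  cors <- bicor_matrix(expr, max_p_outliers = config$max_p_outliers)
  base <- (1 + cors) / 2
  diag(base) <- NA
  fit <- data.frame(
    power = config$powers_scanned, signed_r2 = NA_real_,
    mean_k = NA_real_, median_k = NA_real_, max_k = NA_real_
  )
  for (i in seq_along(config$powers_scanned)) {
    p <- config$powers_scanned[i]
    k <- rowSums(base^p, na.rm = TRUE)
    fit$mean_k[i] <- mean(k)
    fit$median_k[i] <- stats::median(k)
    fit$max_k[i] <- max(k)
    fit$signed_r2[i] <- .scale_free_fit(k, config$n_bins)
  }
  ok <- which(fit$signed_r2 >= config$scale_free_r2_target &
    fit$mean_k >= config$min_mean_k)
  if (length(ok) > 0) {
    beta <- fit$power[min(ok)]
    reached <- TRUE
  } else {
    beta <- config$fallback_beta
    reached <- FALSE
    warning(sprintf(
      "no scanned power reached signed R^2 >= %.2f; using fallback power %d",
      config$scale_free_r2_target, beta
    ))
  }
  list(beta = as.integer(beta), reached_target = reached, fit_table = fit)
}

# Signed scale-free fit index: discretize k into equal-width bins and regress
# log10 of the bin frequency on log10 of the bin's mean connectivity. A
# scale-free (power-law) connectivity distribution is linear with negative
# slope on this plot; unimodal noise distributions fit poorly or slope upward.
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) return(NA_real_)
  bins <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(tapply(k, bins, length)) / length(k)
  mean_k <- as.numeric(tapply(k, bins, mean))
  keep <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3) return(NA_real_)
  fitlm <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fitlm)$r.squared
  slope <- stats::coef(fitlm)[2]
  -sign(slope) * r2
}

#' Topological overlap matrix (signed TOM)
#'
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the sum
#' over `u != i, j`, `k_i` the off-diagonal connectivity, and `t_ii = 1`. Genes
#' sharing many strong neighbours have high topological overlap even when their
#' direct adjacency is moderate; `1 - t` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\], unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stopf("adjacency must be symmetric")
  if (any(a < -1e-12 | a > 1 + 1e-12)) stopf("adjacency entries must lie in [0, 1]")
  diag(a) <- 1
  k <- rowSums(a) - 1
  aa <- a %*% a
  # (a %*% a)_ij counts u = i and u = j, contributing 2 a_ij when diag(a) = 1
  num <- aa - 2 * a + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}
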