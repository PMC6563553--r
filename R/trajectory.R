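# Global transcription-profile exploration: group centroid distances, PCoA of
# sample distances, and between-group PCA in principal-coordinate space.

#' Euclidean distances between group centroids
#'
#' Distances between unweighted group mean expression vectors, e.g. between the
#' four stage x morph combinations.
#'
#' @param expr samples x genes expression matrix.
#' @param groups per-sample grouping factor/character (>= 2 non-empty groups).
#' @return symmetric matrix of centroid-centroid Euclidean distances.
#' @export
group_euclidean_distances <- function(expr, groups) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != nrow(expr)) stopf("groups must have one entry per sample")
  if (length(unique(groups)) < 2) stopf("need at least 2 groups")
  centroids <- t(vapply(
    split(seq_len(nrow(expr)), groups),
    function(idx) colMeans(expr[idx, , drop = FALSE]),
    numeric(ncol(expr))
  ))
  as.matrix(stats::dist(centroids))
}

#' Principal coordinates analysis of a Euclidean distance matrix
#'
#' Gower double-centering of `-D^2 / 2` followed by eigendecomposition; scores
#' are eigenvectors scaled by the square root of their (positive) eigenvalues.
#' All eigenvalues are returned, including any negative ones (expected to be
#' zero for genuinely Euclidean input).
#'
#' @param d symmetric sample x sample distance matrix with zero diagonal (or a
#'   `dist` object).
#' @return list with `scores` (samples x axes) and `eigenvalues`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stopf("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stopf("distance matrix must have a zero diagonal")
  n <- nrow(dm)
  # cmdscale warns when fewer than k eigenvalues are positive; scores are
  # returned for the positive ones only, which is the intended behavior
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  scores <- fit$points
  if (is.null(scores) || ncol(scores) == 0) {
    scores <- matrix(0, n, 1, dimnames = list(rownames(dm), "PCo1"))
  } else {
    colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  }
  list(scores = scores, eigenvalues = fit$eig)
}

#' Between-group PCA in principal-coordinate space
#'
#' PCA of the unweighted group-centroid matrix, with every individual projected
#' onto the centroid axes. Axis variance is reported as a fraction of the total
#' among-individual variance in the input space, and axis signs are fixed by
#' making each axis's largest-magnitude loading positive.
#'
#' @param scores samples x coordinates matrix (e.g. PCoA scores).
#' @param groups per-sample grouping (>= 2 groups).
#' @return list of class `bgpca`: `groups` (levels), `centroids`, `axes`
#'   (loadings, coordinates x axes), `centroid_scores`, `scores` (individuals x
#'   axes), `var_fraction` (per-axis fraction of among-individual variance).
#' @export
between_group_pca <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  if (length(groups) != nrow(scores)) stopf("groups must have one entry per sample")
  lev <- sort(unique(groups))
  if (length(lev) < 2) stopf("need at least 2 groups")
  centroids <- t(vapply(
    lev,
    function(g) colMeans(scores[groups == g, , drop = FALSE]),
    numeric(ncol(scores))
  ))
  center <- colMeans(centroids)
  cc <- sweep(centroids, 2, center)
  sv <- svd(cc)
  nz <- sum(sv$d > max(sv$d) * 1e-10)
  nz <- max(nz, 1L)
  axes <- sv$v[, seq_len(nz), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(axes))) {
    i_max <- which.max(abs(axes[, j]))
    if (axes[i_max, j] < 0) axes[, j] <- -axes[, j]
  }
  dimnames(axes) <- list(colnames(scores), paste0("bgPC", seq_len(nz)))
  ind <- sweep(scores, 2, center) %*% axes
  cen_scores <- cc %*% axes
  total_var <- sum(apply(scores, 2, stats::var))
  var_fraction <- if (total_var > 0) {
    apply(ind, 2, stats::var) / total_var
  } else {
    stats::setNames(rep(0, nz), colnames(axes))
  }
  structure(
    list(
      groups = lev, centroids = centroids, axes = axes,
      centroid_scores = cen_scores, scores = ind,
      var_fraction = var_fraction
    ),
    class = "bgpca"
  )
}
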