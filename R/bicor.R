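# Biweight midcorrelation with a cap on the fraction of observations that can
# receive zero weight (maxPOutliers). This is the robust correlation underlying
# all signed-network computations in the package.

# Transform one vector into its normalized, weighted, median-centered form so
# that bicor(x, y) = sum(prep(x) * prep(y)). When robust = FALSE (binary
# traits) the vector is simply mean-centered and normalized, which is the
# appropriate hybrid for correlating expression with a 0/1 predictor.
.bicor_prep <- function(v, max_p_outliers = 0.1, robust = TRUE) {
  v <- as.numeric(v)
  fallback <- FALSE
  if (robust) {
    med <- stats::median(v)
    madv <- stats::mad(v)
    if (madv == 0) {
      fallback <- TRUE
    }
  }
  if (!robust || fallback) {
    centered <- v - mean(v)
    nrm <- sqrt(sum(centered^2))
    if (nrm == 0) {
      out <- rep(NA_real_, length(v))
    } else {
      out <- centered / nrm
    }
    attr(out, "pearson_fallback") <- fallback
    return(out)
  }
  u <- (v - med) / (9 * madv)
  # Side-wise rescaling: if more than max_p_outliers of a tail would fall
  # beyond |u| = 1 (zero weight), shrink that side so the bounding quantile
  # maps onto -1/+1. At most max_p_outliers of either tail is then discarded.
  ql <- stats::quantile(u, probs = max_p_outliers, names = FALSE)
  qh <- stats::quantile(u, probs = 1 - max_p_outliers, names = FALSE)
  if (ql > -1) ql <- -1
  if (qh < 1) qh <- 1
  u <- ifelse(u < 0, u / abs(ql), u / qh)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  centered <- (v - med) * w
  nrm <- sqrt(sum(centered^2))
  out <- if (nrm == 0) rep(NA_real_, length(v)) else centered / nrm
  attr(out, "pearson_fallback") <- FALSE
  out
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation based on Tukey biweights around the median and MAD, with
#' a cap (`max_p_outliers`) on the fraction of either tail that may receive
#' zero weight. Vectors with zero MAD fall back to Pearson centering for that
#' vector and the result carries a `"pearson_fallback"` attribute.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @param max_p_outliers maximum fraction of observations in either tail that
#'   may be assigned zero weight; default 0.1.
#' @param robust_x,robust_y use the robust biweight transform for the given
#'   side; set `robust_y = FALSE` when `y` is a binary trait (robust weighting
#'   is inappropriate for binary predictors).
#' @return correlation in \[-1, 1\], with attribute `pearson_fallback`, a
#'   length-2 logical marking which sides fell back to Pearson.
#' @export
#' @examples
#' bicor(c(1, 2, 3, 4, 100), c(1, 2, 3, 4, 5))
bicor <- function(x, y, max_p_outliers = 0.1, robust_x = TRUE, robust_y = TRUE) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("bicor needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("bicor is undefined for constant vectors")
  }
  px <- .bicor_prep(x, max_p_outliers, robust_x)
  py <- .bicor_prep(y, max_p_outliers, robust_y)
  r <- sum(px * py)
  r <- min(1, max(-1, r))
  attr(r, "pearson_fallback") <- c(
    x = isTRUE(attr(px, "pearson_fallback")),
    y = isTRUE(attr(py, "pearson_fallback"))
  )
  r
}

#' Biweight midcorrelation matrix
#'
#' Pairwise biweight midcorrelations between the columns of `x` (samples in
#' rows), or between columns of `x` and columns of `y`. Constant columns yield
#' `NA` correlations (off the diagonal) and a warning.
#'
#' @param x numeric matrix, samples x variables.
#' @param y optional second matrix with the same number of rows.
#' @param max_p_outliers see [bicor()].
#' @param robust_y logical; use the biweight transform on `y`'s columns
#'   (disable for binary traits).
#' @return correlation matrix (`ncol(x)` x `ncol(x)` or `ncol(x)` x `ncol(y)`).
#' @export
bicor_matrix <- function(x, y = NULL, max_p_outliers = 0.1, robust_y = TRUE) {
  x <- as.matrix(x)
  prep_all <- function(m, robust) {
    out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    const <- logical(ncol(m))
    for (j in seq_len(ncol(m))) {
      if (stats::sd(m[, j]) == 0) {
        const[j] <- TRUE
        next
      }
      out[, j] <- .bicor_prep(m[, j], max_p_outliers, robust)
    }
    if (any(const)) {
      warning(sprintf("%d constant column(s) produce NA correlations", sum(const)))
    }
    out
  }
  px <- prep_all(x, TRUE)
  if (is.null(y)) {
    r <- crossprod(px)
    diag(r) <- 1
  } else {
    y <- as.matrix(y)
    if (nrow(y) != nrow(x)) stopf("x and y must have the same number of rows")
    py <- prep_all(y, robust_y)
    r <- crossprod(px, py)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}
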