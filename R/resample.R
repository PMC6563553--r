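# Two permutation tests validating selected modules: a parallel-analysis-style
# test of the variance explained by the first eigenvalue, and a multivariate
# trait-association test based on the Escoufier RV coefficient.

.perm_result <- function(observed, null, n_perm, stat_name, seed, plus_one) {
  p <- if (plus_one) {
    (sum(null >= observed) + 1) / (n_perm + 1)
  } else {
    sum(null >= observed) / n_perm
  }
  structure(
    list(
      observed_stat = observed, null_stats = null, n_perm = as.integer(n_perm),
      p = p, stat_name = stat_name, seed = as.integer(seed)
    ),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "%s: observed = %.4f, p = %.4g (%d permutations)\n",
    x$stat_name, x$observed_stat, x$p, x$n_perm
  ))
  invisible(x)
}

# Fraction of variance carried by the leading eigenvalue of the module's
# gene-gene correlation matrix. The correlation matrix is crossprod(P) for a
# suitably normalized samples x genes matrix P (columns standardized for
# Pearson, biweight-prepped for bicor), so its eigenvalue spectrum equals the
# squared singular values of P — much cheaper than forming the p x p matrix.
.eigvar_stat <- function(expr, cor_type, max_p_outliers) {
  p <- switch(cor_type,
    pearson = scale(expr),
    bicor = apply(expr, 2, .bicor_prep, max_p_outliers = max_p_outliers),
    stopf("cor_type must be 'pearson' or 'bicor'")
  )
  d2 <- svd(p, nu = 0, nv = 0)$d^2
  d2[1] / sum(d2)
}

#' Permutation test of the variance explained by the first eigenvalue
#'
#' Tests whether a module's eigengene captures more covariation than expected
#' from noise, in the spirit of parallel analysis: the observed statistic is
#' the fraction of variance explained by the leading eigenvalue of the module's
#' correlation matrix; under the null each gene's values are independently
#' permuted across samples, which destroys inter-gene association while
#' preserving each gene's marginal distribution. The p-value is the proportion
#' of permuted statistics greater than or equal to the observed one.
#'
#' A `permute_rows` switch instead applies one shared permutation of whole rows
#' per replicate; this leaves any correlation matrix unchanged and is provided
#' only to demonstrate that sample relabeling alone cannot produce a null.
#'
#' @param module_expr samples x genes expression of one module (>= 3 samples,
#'   >= 2 genes). Constant genes are dropped with a warning.
#' @param n_perm number of permutations (default 1000).
#' @param cor_type `"pearson"` or `"bicor"`.
#' @param seed integer seed.
#' @param max_p_outliers outlier cap when `cor_type = "bicor"`.
#' @param plus_one use the (b+1)/(m+1) p-value estimator.
#' @param permute_rows permute whole rows jointly instead of per-gene (see
#'   above).
#' @return a `permutation_test`.
#' @export
eigenvalue_permutation_test <- function(module_expr, n_perm = 1000L,
                                        cor_type = c("pearson", "bicor"),
                                        seed = 1L, max_p_outliers = 0.1,
                                        plus_one = FALSE, permute_rows = FALSE) {
  cor_type <- match.arg(cor_type)
  x <- as.matrix(module_expr)
  if (nrow(x) < 3) stopf("need at least 3 samples")
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("%d constant gene(s) dropped", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stopf("need at least 2 non-constant genes")
  # The per-column normalization (standardization or biweight prep) depends
  # only on the multiset of values in the column, so it commutes with
  # permuting the column: prep once, permute the prepped columns.
  prep <- switch(cor_type,
    pearson = scale(x),
    bicor = apply(x, 2, .bicor_prep, max_p_outliers = max_p_outliers)
  )
  eigvar <- function(m) {
    d2 <- svd(m, nu = 0, nv = 0)$d^2
    d2[1] / sum(d2)
  }
  observed <- eigvar(prep)
  n <- nrow(x)
  p_genes <- ncol(x)
  gid <- rep(seq_len(p_genes), each = n)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      xp <- if (permute_rows) {
        prep[sample.int(n), , drop = FALSE]
      } else {
        # columnwise independent shuffle: order by (column, random key)
        matrix(prep[order(gid + stats::runif(n * p_genes) * 0.5)], n, p_genes)
      }
      eigvar(xp)
    }, numeric(1))
  })
  .perm_result(
    observed, null, n_perm,
    sprintf("first-eigenvalue explained variance (%s)", cor_type),
    seed, plus_one
  )
}

#' Escoufier RV coefficient
#'
#' Multivariate analog of the squared correlation between two matrices sharing
#' observations: with column-centered `X`, `Y` and (cross-)covariance blocks
#' `S`, `RV = trace(Sxy Syx) / sqrt(trace(Sxx^2) trace(Syy^2))`, in \[0, 1\].
#'
#' @param x,y numeric matrices (or vectors) with the same number of rows
#'   (>= 3 samples).
#' @return RV coefficient.
#' @export
rv_coefficient <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stopf("x and y must have the same number of rows")
  if (nrow(x) < 3) stopf("need at least 3 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sxx <- crossprod(xc)
  syy <- crossprod(yc)
  sxy <- crossprod(xc, yc)
  den <- sqrt(sum(sxx^2) * sum(syy^2))
  if (den == 0) stopf("zero total variance in x or y")
  sum(sxy^2) / den
}

#' RV permutation test of module-trait multivariate association
#'
#' Observed statistic: RV between the module's samples x genes expression and
#' the trait as a single column. The null permutes the benthic/limnetic labels
#' while keeping the expression matrix fixed; the p-value is the proportion of
#' permuted RV values greater than or equal to the observed one.
#'
#' @param module_expr samples x genes expression of one module.
#' @param trait 0/1 trait vector (non-constant).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param plus_one use the (b+1)/(m+1) p-value estimator.
#' @return a `permutation_test`.
#' @export
rv_permutation_test <- function(module_expr, trait, n_perm = 100L, seed = 1L,
                                plus_one = FALSE) {
  x <- as.matrix(module_expr)
  trait <- as.numeric(trait)
  if (length(trait) != nrow(x)) stopf("trait length must match the sample count")
  if (stats::sd(trait) == 0) stopf("trait must be non-constant")
  if (n_perm < 20) warning("fewer than 20 permutations: p-value resolution is coarse")
  observed <- rv_coefficient(x, trait)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rv_coefficient(x, sample(trait))
    }, numeric(1))
  })
  .perm_result(observed, null, n_perm, "Escoufier RV (trait association)", seed, plus_one)
}
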