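# Shared fixture builders: small planted-structure matrices built in code.

# Block-structured samples x genes matrix: each block driven by one latent
# score plus gene-level noise; extra pure-noise genes appended.
make_block_expr <- function(n_samples, block_sizes, noise_genes = 0,
                            block_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    cols <- list()
    for (b in seq_along(block_sizes)) {
      s <- rnorm(n_samples)
      for (i in seq_len(block_sizes[b])) {
        cols[[length(cols) + 1]] <- s + rnorm(n_samples, sd = block_sd)
      }
    }
    for (i in seq_len(noise_genes)) {
      cols[[length(cols) + 1]] <- rnorm(n_samples)
    }
    x <- do.call(cbind, cols)
    colnames(x) <- paste0("g", seq_len(ncol(x)))
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    x
  })
}

block_truth <- function(block_sizes, noise_genes = 0) {
  lab <- c(
    rep(paste0("block", seq_along(block_sizes)), times = block_sizes),
    rep("none", noise_genes)
  )
  stats::setNames(lab, paste0("g", seq_along(lab)))
}

# Straight-line independent biweight midcorrelation (the published formula,
# written without reference to the package internals) used as oracle.
oracle_bicor <- function(x, y, maxp = 0.1) {
  prep <- function(v) {
    med <- median(v)
    madv <- mad(v)
    if (madv == 0) {
      c <- v - mean(v)
      return(c / sqrt(sum(c^2)))
    }
    u <- (v - med) / (9 * madv)
    ql <- unname(quantile(u, maxp))
    qh <- unname(quantile(u, 1 - maxp))
    if (ql > -1) ql <- -1
    if (qh < 1) qh <- 1
    u <- ifelse(u < 0, u / abs(ql), u / qh)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    c <- (v - med) * w
    c / sqrt(sum(c^2))
  }
  sum(prep(x) * prep(y))
}

# Triple-loop topological overlap oracle.
oracle_tom <- function(a) {
  diag(a) <- 1
  p <- nrow(a)
  k <- rowSums(a) - 1
  out <- matrix(1, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(p)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Textbook BH step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Elementwise-trace RV oracle.
oracle_rv <- function(x, y) {
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  sxx <- t(x) %*% x
  syy <- t(y) %*% y
  sxy <- t(x) %*% y
  num <- sum(diag(sxy %*% t(sxy)))
  num / sqrt(sum(diag(sxx %*% sxx)) * sum(diag(syy %*% syy)))
}

# Exact two-sided Fisher p by hypergeometric enumeration of all tables with
# the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
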