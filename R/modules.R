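# Module detection on TOM dissimilarity: average-linkage clustering, an
# adaptive cut that maximizes the number of valid modules, a coherence filter
# against a random-matrix baseline, kME-based assignment of leftover genes, and
# eigengene-similarity merging.

.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue"
)

.module_colors <- function(n) {
  if (n <= length(.module_palette)) return(.module_palette[seq_len(n)])
  c(.module_palette, paste0("module", seq_len(n - length(.module_palette))))
}

# First principal component of a samples x genes submatrix: genes standardized,
# scores scaled to unit variance and oriented so the eigengene correlates
# positively with the module's average standardized expression. Constant genes
# are dropped (with a warning at the caller's discretion).
.module_pc <- function(sub) {
  sds <- apply(sub, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 1) stopf("module has no non-constant genes")
  z <- scale(sub[, keep, drop = FALSE])
  sv <- svd(z, nu = 1, nv = 0)
  score <- sv$u[, 1]
  s <- stats::sd(score)
  score <- if (s > 0) score / s else score
  avg <- rowMeans(z)
  if (stats::sd(avg) > 0 && stats::cor(score, avg) < 0) score <- -score
  d2 <- sv$d^2
  list(
    score = score,
    prop_var = d2[1] / sum(d2),
    prop_var2 = if (length(d2) > 1) d2[2] / sum(d2) else 0,
    n_dropped = sum(!keep)
  )
}

# A gene set is a coherent module when its leading eigenvalue fraction exceeds
# the random-matrix baseline by `factor` AND its second eigenvalue fraction
# stays below that bound (a mixture of two distinct modules fails the second
# condition and is split further down the tree).
.is_coherent <- function(sub, factor) {
  pc <- .module_pc(sub)
  bound <- factor * .propvar_baseline(ncol(sub), nrow(sub))
  pc$prop_var >= bound && pc$prop_var2 < bound
}

# Random-matrix baseline for the leading-eigenvalue fraction of a q-gene module
# on n samples under independence; used to reject incoherent clusters.
.propvar_baseline <- function(q, n) (1 + sqrt(q / n))^2 / q

#' Detect coexpression modules
#'
#' Builds a signed weighted network (biweight midcorrelation, signed adjacency
#' at the chosen soft-thresholding power, topological overlap), clusters genes
#' by average-linkage on TOM dissimilarity, and cuts the tree adaptively: the
#' cut height maximizing the number of clusters of at least
#' `min_module_size` genes is chosen (smallest such height on ties), clusters
#' whose eigengene explains no more variance than expected from uncorrelated
#' genes are discarded, unassigned genes are attached to the module whose
#' eigengene they correlate with above `pam_kme`, and modules with eigengene
#' correlation dissimilarity below `merge_cut_height` are merged iteratively.
#' Unassigned genes are labeled `"grey"`.
#'
#' @param expr samples x genes expression matrix.
#' @param config a [network_config()]; when `config$beta` is `NULL` the power
#'   is chosen by [pick_soft_threshold()].
#' @return list with `modules` (a `module_set`: gene->color labels, dendrogram,
#'   parameters, beta) and `eigengenes` (an `eigengene_matrix`, see
#'   [compute_eigengenes()]).
#' @export
detect_modules <- function(expr, config = network_config()) {
  expr <- as.matrix(expr)
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  colnames(expr) <- genes
  if (ncol(expr) < config$min_module_size) {
    warning("fewer genes than the minimum module size; all genes left unassigned")
    modules <- .as_module_set(setNames(rep("grey", ncol(expr)), genes),
      dendrogram = NULL, config = config, beta = NA_integer_
    )
    return(list(modules = modules, eigengenes = NULL))
  }
  beta <- config$beta
  if (is.null(beta)) beta <- pick_soft_threshold(expr, config)$beta
  cors <- bicor_matrix(expr, max_p_outliers = config$max_p_outliers)
  adj <- signed_adjacency(cors, beta)
  tom <- tom_similarity(adj)
  res <- .modules_from_tom(
    dissim = 1 - tom,
    config = config,
    coherent = function(idx) {
      .is_coherent(expr[, idx, drop = FALSE], config$coherence_factor)
    },
    kme_of = function(module_idx_list) {
      me <- vapply(module_idx_list, function(idx) {
        .module_pc(expr[, idx, drop = FALSE])$score
      }, numeric(nrow(expr)))
      bicor_matrix(expr, me, max_p_outliers = config$max_p_outliers)
    },
    me_dissim = function(module_idx_list) {
      me <- vapply(module_idx_list, function(idx) {
        .module_pc(expr[, idx, drop = FALSE])$score
      }, numeric(nrow(expr)))
      1 - stats::cor(me)
    }
  )
  labels <- .label_modules(res$assignment, genes)
  modules <- .as_module_set(labels, res$tree, config, beta)
  eig <- if (any(labels != "grey")) {
    compute_eigengenes(expr, modules, max_p_outliers = config$max_p_outliers)
  } else {
    NULL
  }
  list(modules = modules, eigengenes = eig)
}

# Core detect/validate/assign/merge routine shared by single-dataset and
# consensus detection. `coherent(idx)`, `kme_of(list_of_idx)` and
# `me_dissim(list_of_idx)` abstract over where expression comes from.
#
# Candidate modules are found by walking the dendrogram top-down: a node is
# accepted as a (maximal) module when it is large enough and coherent; an
# incoherent node is split into its children and the search continues. This is
# cut-height free: each module is recognized at the resolution where it is a
# single coherent block, regardless of where unrelated parts of the tree merge.
.modules_from_tom <- function(dissim, config, coherent, kme_of, me_dissim) {
  n <- nrow(dissim)
  tree <- stats::hclust(stats::as.dist(dissim), method = "average")
  merge <- tree$merge
  members <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    members[[k]] <- c(
      if (merge[k, 1] < 0) -merge[k, 1] else members[[merge[k, 1]]],
      if (merge[k, 2] < 0) -merge[k, 2] else members[[merge[k, 2]]]
    )
  }
  assignment <- integer(n) # 0 = unassigned
  next_id <- 1L
  stack <- nrow(merge) # root
  while (length(stack) > 0) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    idx <- members[[k]]
    if (length(idx) < config$min_module_size) next
    if (coherent(idx)) {
      assignment[idx] <- next_id
      next_id <- next_id + 1L
    } else {
      kids <- merge[k, ]
      stack <- c(stack, kids[kids > 0])
    }
  }
  if (all(assignment == 0L)) {
    return(list(assignment = assignment, tree = tree))
  }
  mods <- sort(unique(assignment[assignment > 0L]))
  idx_list <- lapply(mods, function(m) which(assignment == m))
  kme <- kme_of(idx_list)
  # Trim hangers-on: a member whose (signed) kME falls below half the module's
  # median kME does not follow the module's profile and is released.
  for (j in seq_along(mods)) {
    idx <- idx_list[[j]]
    med <- stats::median(kme[idx, j], na.rm = TRUE)
    drop <- idx[!is.na(kme[idx, j]) & kme[idx, j] < config$trim_frac * med]
    assignment[drop] <- 0L
  }
  # Attach leftover genes to the module whose eigengene they match best.
  grey <- which(assignment == 0L)
  if (length(grey) > 0) {
    best_mod <- max.col(replace(kme[grey, , drop = FALSE], is.na(kme[grey, , drop = FALSE]), -Inf),
      ties.method = "first"
    )
    best_val <- kme[cbind(grey, best_mod)]
    take <- !is.na(best_val) & best_val > config$pam_kme
    assignment[grey[take]] <- mods[best_mod[take]]
  }
  # Merge modules whose eigengenes are nearly identical.
  repeat {
    mods <- sort(unique(assignment[assignment > 0L]))
    if (length(mods) < 2) break
    idx_list <- lapply(mods, function(m) which(assignment == m))
    d <- me_dissim(idx_list)
    diag(d) <- Inf
    min_d <- min(d)
    if (min_d >= config$merge_cut_height) break
    pair <- which(d == min_d, arr.ind = TRUE)[1, ]
    keep_mod <- mods[min(pair)]
    drop_mod <- mods[max(pair)]
    assignment[assignment == drop_mod] <- keep_mod
  }
  # The minimum module size applies to the final membership: modules whose
  # trimmed (and merged) membership falls below it are dissolved.
  for (m in unique(assignment[assignment > 0L])) {
    if (sum(assignment == m) < config$min_module_size) {
      assignment[assignment == m] <- 0L
    }
  }
  list(assignment = assignment, tree = tree)
}

# Convert integer assignments to color labels by decreasing module size
# (largest module = "turquoise", ties broken by first gene index).
.label_modules <- function(assignment, genes) {
  labels <- rep("grey", length(assignment))
  mods <- unique(assignment[assignment > 0L])
  if (length(mods) > 0) {
    sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
    firsts <- vapply(mods, function(m) which(assignment == m)[1], integer(1))
    ord <- order(-sizes, firsts)
    colors <- .module_colors(length(mods))
    for (i in seq_along(ord)) {
      labels[assignment == mods[ord[i]]] <- colors[i]
    }
  }
  stats::setNames(labels, genes)
}

.as_module_set <- function(labels, dendrogram, config, beta) {
  structure(
    list(labels = labels, dendrogram = dendrogram, params = config, beta = beta),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf(
    "module_set: %d genes, %d modules (+%d grey)\n",
    length(x$labels), sum(names(tab) != "grey"),
    sum(x$labels == "grey")
  ))
  print(tab)
  invisible(x)
}

#' Module sizes (non-grey)
#'
#' @param modules a `module_set`.
#' @return named integer vector of module sizes, decreasing.
#' @export
module_sizes <- function(modules) {
  tab <- table(modules$labels[modules$labels != "grey"])
  sort(as.table(tab), decreasing = TRUE)
}

#' Compute module eigengenes, explained variance, and module membership
#'
#' The eigengene of a module is the first principal component of its
#' standardized samples x genes submatrix, scaled to unit variance and oriented
#' to correlate positively with the module's average standardized expression.
#' Module membership (kME) is the biweight midcorrelation of each gene's
#' expression with each module eigengene.
#'
#' @param expr samples x genes expression matrix.
#' @param modules a `module_set` or a named gene->label character vector;
#'   `"grey"` genes are skipped.
#' @param max_p_outliers outlier cap for the kME correlations.
#' @return an `eigengene_matrix`: list with `scores` (samples x modules),
#'   `prop_var` (per-module explained-variance fraction, in (0, 1\]) and `kME`
#'   (genes x modules).
#' @export
compute_eigengenes <- function(expr, modules, max_p_outliers = 0.1) {
  expr <- as.matrix(expr)
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  labels <- labels[colnames(expr)]
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[!is.na(mods)]
  if (length(mods) == 0) stopf("no non-grey modules to summarize")
  ord <- order(-vapply(mods, function(m) sum(labels == m, na.rm = TRUE), numeric(1)))
  mods <- mods[ord]
  scores <- matrix(NA_real_, nrow(expr), length(mods),
    dimnames = list(rownames(expr), mods)
  )
  prop_var <- stats::setNames(numeric(length(mods)), mods)
  dropped <- 0L
  for (m in mods) {
    idx <- which(labels == m)
    if (length(idx) < 2) stopf("module '%s' has fewer than 2 genes", m)
    pc <- .module_pc(expr[, idx, drop = FALSE])
    dropped <- dropped + pc$n_dropped
    scores[, m] <- pc$score
    prop_var[m] <- pc$prop_var
  }
  if (dropped > 0) {
    warning(sprintf("%d constant gene(s) dropped from eigengene PCAs", dropped))
  }
  kme <- suppressWarnings(
    bicor_matrix(expr, scores, max_p_outliers = max_p_outliers)
  )
  structure(
    list(scores = scores, prop_var = prop_var, kME = kme),
    class = "eigengene_matrix"
  )
}
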