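# Consensus modules across datasets: per-dataset TOMs calibrated to a common
# scale, combined by elementwise minimum, and clustered with the same module
# detection parameters used within stages.

#' Consensus module detection across datasets
#'
#' Computes one signed TOM per dataset (on the shared gene universe, with the
#' same parameters as within-stage detection), calibrates TOMs to a common
#' scale by power-transforming each so its 95th percentile matches the first
#' dataset's, and takes the elementwise minimum as the consensus TOM, so that
#' only coexpression present in every dataset survives. Module detection then
#' proceeds as in [detect_modules()], with module coherence required in every
#' dataset, unassigned genes attached only when their kME passes the threshold
#' in every dataset, and merging driven by the consensus eigengene
#' dissimilarity (the maximum across datasets). Eigengenes are finally computed
#' separately per dataset, so trait association can be assessed per stage.
#'
#' @param expr_list list of >= 2 samples x genes matrices sharing gene names.
#' @param config a [network_config()]; `config$beta` (or the power picked on
#'   the first dataset) is used for every dataset.
#' @param calibration_quantile TOM quantile matched across datasets
#'   (default 0.95).
#' @return list with `modules` (consensus `module_set`) and `eigengenes`
#'   (per-dataset list of `eigengene_matrix` or NULL when no module is found).
#' @export
consensus_modules <- function(expr_list, config = network_config(),
                              calibration_quantile = 0.95) {
  stopifnot(is.list(expr_list), length(expr_list) >= 2)
  expr_list <- lapply(expr_list, as.matrix)
  common <- Reduce(intersect, lapply(expr_list, colnames))
  if (length(common) < 30) stopf("fewer than 30 shared genes across datasets")
  expr_list <- lapply(expr_list, function(e) e[, common, drop = FALSE])
  beta <- config$beta
  if (is.null(beta)) beta <- pick_soft_threshold(expr_list[[1]], config)$beta
  toms <- lapply(expr_list, function(e) {
    cors <- suppressWarnings(bicor_matrix(e, max_p_outliers = config$max_p_outliers))
    tom_similarity(signed_adjacency(cors, beta))
  })
  # Calibrate: power-transform each TOM so its calibration quantile equals the
  # first dataset's; a power (rather than linear) map keeps values in [0, 1].
  q_ref <- stats::quantile(upper_tri(toms[[1]]), calibration_quantile, names = FALSE)
  toms <- lapply(toms, function(tm) {
    q_d <- stats::quantile(upper_tri(tm), calibration_quantile, names = FALSE)
    if (q_d > 0 && q_d < 1 && q_ref > 0 && q_ref < 1) {
      tm <- tm^(log(q_ref) / log(q_d))
    }
    tm
  })
  cons <- Reduce(pmin, toms)
  diag(cons) <- 1
  n_per <- vapply(expr_list, nrow, integer(1))
  res <- .modules_from_tom(
    dissim = 1 - cons,
    config = config,
    coherent = function(idx) {
      all(vapply(seq_along(expr_list), function(d) {
        .is_coherent(expr_list[[d]][, idx, drop = FALSE], config$coherence_factor)
      }, logical(1)))
    },
    kme_of = function(module_idx_list) {
      per_ds <- lapply(expr_list, function(e) {
        me <- vapply(module_idx_list, function(idx) {
          .module_pc(e[, idx, drop = FALSE])$score
        }, numeric(nrow(e)))
        suppressWarnings(bicor_matrix(e, me, max_p_outliers = config$max_p_outliers))
      })
      Reduce(pmin, per_ds)
    },
    me_dissim = function(module_idx_list) {
      per_ds <- lapply(expr_list, function(e) {
        me <- vapply(module_idx_list, function(idx) {
          .module_pc(e[, idx, drop = FALSE])$score
        }, numeric(nrow(e)))
        1 - stats::cor(me)
      })
      Reduce(pmax, per_ds)
    }
  )
  labels <- .label_modules(res$assignment, common)
  modules <- .as_module_set(labels, res$tree, config, beta)
  eig <- NULL
  if (any(labels != "grey")) {
    eig <- lapply(expr_list, function(e) {
      compute_eigengenes(e, labels, max_p_outliers = config$max_p_outliers)
    })
    names(eig) <- names(expr_list) %||% paste0("dataset", seq_along(expr_list))
  }
  list(modules = modules, eigengenes = eig)
}
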