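# Stage-by-stage orchestrator: preprocess -> network -> module-trait ->
# permutation tests, plus cross-stage, trajectory and genomic-overlap analyses
# when the corresponding inputs are supplied.

#' Pipeline configuration
#'
#' Every stage parameter with its default: count filters 100 (total) and 50
#' (per stage), outlier Z threshold -2, powers 1-30 with fallback 20 and
#' scale-free target 0.9, bicor outlier cap 0.1, minimum module size 30, merge
#' cut height 0.25, 1,000 permutations for the eigenvalue test, 100 for the RV
#' test, 1,000 for module preservation, candidate threshold 0.7, FDR level
#' 0.05, and 1,000 region permutations. All values are validated against their
#' admissible ranges.
#'
#' @param total_min,per_stage_min count filter thresholds, see
#'   [filter_low_counts()].
#' @param z_threshold sample outlier threshold, see [remove_outlier_samples()].
#' @param network a [network_config()].
#' @param eig_perms,rv_perms,preservation_perms,region_perms permutation counts.
#' @param candidate_threshold joint |kME|, |GS| candidate rule.
#' @param fdr_level BH FDR level for module selection.
#' @param consensus_quantile TOM calibration quantile for consensus modules.
#' @param seed global seed; every randomized stage uses a substream derived
#'   deterministically from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(total_min = 100, per_stage_min = 50,
                            z_threshold = -2, network = network_config(),
                            eig_perms = 1000L, rv_perms = 100L,
                            preservation_perms = 1000L, region_perms = 1000L,
                            candidate_threshold = 0.7, fdr_level = 0.05,
                            consensus_quantile = 0.95, seed = 1L) {
  stopifnot(
    total_min >= 0, per_stage_min >= 0,
    z_threshold < 0,
    inherits(network, "network_config"),
    eig_perms >= 1, rv_perms >= 1, preservation_perms >= 1, region_perms >= 1,
    candidate_threshold >= 0, candidate_threshold <= 1,
    fdr_level > 0, fdr_level < 1,
    consensus_quantile > 0, consensus_quantile < 1
  )
  structure(
    list(
      total_min = total_min, per_stage_min = per_stage_min,
      z_threshold = z_threshold, network = network,
      eig_perms = as.integer(eig_perms), rv_perms = as.integer(rv_perms),
      preservation_perms = as.integer(preservation_perms),
      region_perms = as.integer(region_perms),
      candidate_threshold = candidate_threshold, fdr_level = fdr_level,
      consensus_quantile = consensus_quantile, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Within-stage analysis: VST, outlier removal, network, modules, trait
# association, candidates, permutation tests.
.run_stage <- function(counts, meta, config, stage_name, seed) {
  expr <- vst_counts(counts)
  rownames(expr) <- meta$sample_id
  outl <- remove_outlier_samples(expr, config$z_threshold)
  expr <- outl$expr
  meta <- meta[match(rownames(expr), meta$sample_id), , drop = FALSE]
  power <- pick_soft_threshold(expr, config$network)
  net_cfg <- config$network
  net_cfg$beta <- power$beta
  det <- detect_modules(expr, net_cfg)
  stage <- list(
    name = stage_name, expr = expr, meta = meta, outliers = outl$report,
    beta = power$beta, reached_target = power$reached_target,
    fit_table = power$fit_table, modules = det$modules,
    eigengenes = det$eigengenes
  )
  if (is.null(det$eigengenes)) {
    return(stage)
  }
  if (!"morph" %in% names(meta) || anyNA(meta$morph)) {
    stopf("stage %s: morph metadata is required for trait analyses", stage_name)
  }
  trait <- trait_vector(meta$morph)
  assoc <- eigengene_trait_association(
    det$eigengenes, trait,
    fdr_level = config$fdr_level, expr = expr,
    max_p_outliers = config$network$max_p_outliers
  )
  stage$trait <- trait
  stage$association <- assoc
  stage$candidates <- select_candidates(
    assoc, det$modules,
    threshold = config$candidate_threshold
  )
  selected <- assoc$table$module[assoc$table$selected]
  perm <- list()
  for (i in seq_along(selected)) {
    m <- selected[i]
    sub <- expr[, det$modules$labels == m, drop = FALSE]
    perm[[m]] <- list(
      eigenvalue_pearson = eigenvalue_permutation_test(
        sub,
        n_perm = config$eig_perms, cor_type = "pearson",
        seed = derive_seed(seed, 100 + i)
      ),
      eigenvalue_bicor = eigenvalue_permutation_test(
        sub,
        n_perm = config$eig_perms, cor_type = "bicor",
        max_p_outliers = config$network$max_p_outliers,
        seed = derive_seed(seed, 200 + i)
      ),
      rv = rv_permutation_test(
        sub, trait,
        n_perm = config$rv_perms,
        seed = derive_seed(seed, 300 + i)
      )
    )
  }
  stage$permutation_tests <- perm
  stage
}

.stage_artifacts <- function(stage, out_dir) {
  tag <- stage$name
  write_tsv_atomic(
    stage$fit_table, file.path(out_dir, sprintf("%s_soft_threshold.tsv", tag))
  )
  write_json_atomic(
    list(
      threshold = attr(stage$outliers, "threshold"),
      iterations = stage$outliers
    ),
    file.path(out_dir, sprintf("%s_outliers.json", tag))
  )
  labels <- stage$modules$labels
  mod_df <- data.frame(gene = names(labels), module = unname(labels))
  if (!is.null(stage$eigengenes)) {
    own_kme <- rep(NA_real_, length(labels))
    in_mod <- labels != "grey"
    own_kme[in_mod] <- stage$eigengenes$kME[cbind(
      which(in_mod), match(labels[in_mod], colnames(stage$eigengenes$kME))
    )]
    mod_df$kME <- own_kme
    if (!is.null(stage$association)) mod_df$GS <- unname(stage$association$GS[names(labels)])
    me_df <- data.frame(
      sample = rownames(stage$eigengenes$scores), stage$eigengenes$scores,
      check.names = FALSE
    )
    write_tsv_atomic(me_df, file.path(out_dir, sprintf("%s_eigengenes.tsv", tag)))
  }
  write_tsv_atomic(mod_df, file.path(out_dir, sprintf("%s_modules.tsv", tag)))
  if (!is.null(stage$association)) {
    write_tsv_atomic(
      stage$association$table,
      file.path(out_dir, sprintf("%s_module_trait.tsv", tag))
    )
    cand <- do.call(rbind, lapply(names(stage$candidates), function(m) {
      df <- stage$candidates[[m]]
      if (nrow(df) == 0) return(NULL)
      cbind(module = m, df)
    }))
    if (!is.null(cand)) {
      write_tsv_atomic(cand, file.path(out_dir, sprintf("%s_candidates.tsv", tag)))
    }
  }
}

#' Run the full coexpression-divergence pipeline
#'
#' Executes, per stage: variance-stabilizing transform, iterative sample
#' outlier removal, soft-threshold selection, module detection, eigengene-trait
#' association with candidate selection, and both permutation tests on the
#' selected modules. The low-count filter is applied jointly across stages
#' before the per-stage analyses. When two stages are supplied it adds module
#' preservation (reference = stage 2, the older stage; test = stage 1), the
#' module overlap cross-tabulation, consensus modules with per-stage trait
#' association, and the trajectory analysis (pooled transform of the original
#' unfiltered counts, centroid distances, PCoA, between-group PCA). When
#' transcript positions and QTL intervals are supplied it runs the
#' linkage-group-restricted overlap battery on the selected modules' genes (and
#' on DE genes when flags are given).
#'
#' @param counts1,counts2 genes x samples count matrices (or TSV paths);
#'   `counts2` optional.
#' @param meta1,meta2 metadata data.frames (or TSV paths) with sample_id,
#'   stage, morph.
#' @param transcripts optional [region_set()] of transcript positions (names
#'   must be gene ids).
#' @param qtl optional [region_set()] or named list of region sets.
#' @param de_flags optional named logical vector of DE calls per gene.
#' @param config a [pipeline_config()].
#' @param out_dir run directory; all artifacts and `report.json` are written
#'   there (atomically).
#' @return invisibly, a list with the per-stage results, cross-stage results,
#'   trajectory, overlap battery and the report.
#' @export
run_pipeline <- function(counts1, meta1, counts2 = NULL, meta2 = NULL,
                         transcripts = NULL, qtl = NULL, de_flags = NULL,
                         config = pipeline_config(), out_dir) {
  if (is.character(counts1)) counts1 <- read_counts(counts1)
  if (is.character(meta1)) meta1 <- read_metadata(meta1)
  if (is.character(counts2)) counts2 <- read_counts(counts2)
  if (is.character(meta2)) meta2 <- read_metadata(meta2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  two_stage <- !is.null(counts2)
  if (two_stage && is.null(meta2)) stopf("counts2 supplied without meta2")
  # joint low-count filter across stages
  if (two_stage) {
    common <- intersect(rownames(counts1), rownames(counts2))
    joint <- cbind(counts1[common, , drop = FALSE], counts2[common, , drop = FALSE])
    stages <- c(rep("s1", ncol(counts1)), rep("s2", ncol(counts2)))
  } else {
    joint <- counts1
    stages <- rep("s1", ncol(counts1))
  }
  flt <- filter_low_counts(joint, stages, config$total_min, config$per_stage_min)
  kept <- rownames(flt$counts)
  c1 <- counts1[kept, , drop = FALSE]
  res <- list(config = config, n_genes_filtered = flt$n_removed)
  res$stage1 <- .run_stage(c1, meta1, config, "stage1", derive_seed(config$seed, 1))
  .stage_artifacts(res$stage1, out_dir)
  if (two_stage) {
    c2 <- counts2[kept, , drop = FALSE]
    res$stage2 <- .run_stage(c2, meta2, config, "stage2", derive_seed(config$seed, 2))
    .stage_artifacts(res$stage2, out_dir)
    # preservation: older stage (stage 2) as reference, stage 1 as test
    res$preservation <- module_preservation(
      res$stage2$expr, res$stage2$modules, res$stage1$expr,
      n_perm = config$preservation_perms, beta = res$stage2$beta,
      max_p_outliers = config$network$max_p_outliers,
      seed = derive_seed(config$seed, 3)
    )
    write_tsv_atomic(res$preservation, file.path(out_dir, "preservation.tsv"))
    res$overlap_table <- module_overlap_table(res$stage1$modules, res$stage2$modules)
    write_json_atomic(
      list(
        counts = as.data.frame.matrix(res$overlap_table$counts),
        q = as.data.frame.matrix(res$overlap_table$q)
      ),
      file.path(out_dir, "module_overlap.json")
    )
    net_cfg <- config$network
    net_cfg$beta <- res$stage2$beta
    res$consensus <- consensus_modules(
      list(stage1 = res$stage1$expr, stage2 = res$stage2$expr),
      config = net_cfg, calibration_quantile = config$consensus_quantile
    )
    if (!is.null(res$consensus$eigengenes)) {
      res$consensus$association <- lapply(
        names(res$consensus$eigengenes),
        function(nm) {
          st <- res[[nm]]
          eigengene_trait_association(
            res$consensus$eigengenes[[nm]], st$trait,
            fdr_level = config$fdr_level, expr = st$expr,
            max_p_outliers = config$network$max_p_outliers
          )
        }
      )
      names(res$consensus$association) <- names(res$consensus$eigengenes)
    }
    # trajectory from the original (unfiltered) counts with a pooled transform
    pooled <- vst_counts(cbind(counts1[common, , drop = FALSE], counts2[common, , drop = FALSE]))
    groups <- c(
      paste(meta1$stage, meta1$morph, sep = "_"),
      paste(meta2$stage, meta2$morph, sep = "_")
    )
    res$trajectory <- list(
      group_distances = group_euclidean_distances(pooled, groups),
      groups = groups
    )
    pc <- pcoa(stats::dist(pooled))
    res$trajectory$bgpca <- between_group_pca(pc$scores, groups)
    write_tsv_atomic(
      data.frame(
        sample = rownames(pooled), group = groups,
        res$trajectory$bgpca$scores, check.names = FALSE
      ),
      file.path(out_dir, "trajectory_scores.tsv")
    )
    write_tsv_atomic(
      as.data.frame(res$trajectory$group_distances),
      file.path(out_dir, "group_distances.tsv")
    )
  }
  if (!is.null(transcripts) && !is.null(qtl)) {
    gene_sets <- list()
    for (st in c("stage1", if (two_stage) "stage2")) {
      assoc <- res[[st]]$association
      if (is.null(assoc)) next
      for (m in assoc$table$module[assoc$table$selected]) {
        genes <- names(res[[st]]$modules$labels)[res[[st]]$modules$labels == m]
        idx <- transcripts$intervals$name %in% genes
        gene_sets[[paste(st, m, sep = ".")]] <-
          region_set(transcripts$intervals[idx, , drop = FALSE], transcripts$genome)
      }
    }
    if (!is.null(de_flags)) {
      de_genes <- names(de_flags)[as.logical(de_flags)]
      idx <- transcripts$intervals$name %in% de_genes
      if (any(idx)) {
        gene_sets$de_genes <- region_set(
          transcripts$intervals[idx, , drop = FALSE], transcripts$genome
        )
      }
    }
    qtl_sets <- if (inherits(qtl, "region_set")) list(qtl = qtl) else qtl
    if (length(gene_sets) > 0) {
      res$overlap_battery <- overlap_battery(
        gene_sets, qtl_sets,
        combined = TRUE, n_perm = config$region_perms,
        seed = derive_seed(config$seed, 4)
      )
      write_tsv_atomic(res$overlap_battery, file.path(out_dir, "qtl_overlap.tsv"))
    }
  }
  if (!is.null(de_flags)) {
    for (st in c("stage1", if (two_stage) "stage2")) {
      assoc <- res[[st]]$association
      if (is.null(assoc)) next
      selected <- assoc$table$module[assoc$table$selected]
      labels <- res[[st]]$modules$labels
      outside <- names(labels)[!(labels %in% selected)]
      enr <- lapply(selected, function(m) {
        genes <- names(labels)[labels == m]
        covered <- intersect(c(genes, outside), names(de_flags))
        fisher_module_enrichment(
          intersect(genes, covered), de_flags, intersect(outside, covered)
        )[c("odds_ratio", "p")]
      })
      names(enr) <- selected
      res[[st]]$de_enrichment <- enr
    }
  }
  res$report <- .pipeline_report(res, two_stage)
  write_json_atomic(res$report, file.path(out_dir, "report.json"))
  .write_log(res, config, out_dir)
  invisible(res)
}

.pipeline_report <- function(res, two_stage) {
  stage_report <- function(st) {
    out <- list(
      n_samples = nrow(st$expr),
      n_outliers_removed = sum(st$outliers$removed),
      beta = st$beta,
      scale_free_target_reached = st$reached_target,
      n_modules = if (is.null(st$eigengenes)) 0L else ncol(st$eigengenes$scores),
      module_sizes = as.list(module_sizes(st$modules))
    )
    if (!is.null(st$association)) {
      out$module_trait <- st$association$table
      out$n_selected <- sum(st$association$table$selected)
      out$n_candidates <- lapply(st$candidates, nrow)
      out$permutation_tests <- lapply(st$permutation_tests, function(pt) {
        lapply(pt, function(t) list(observed = t$observed_stat, p = t$p))
      })
    }
    if (!is.null(st$de_enrichment)) out$de_enrichment <- st$de_enrichment
    out
  }
  report <- list(
    seed = res$config$seed,
    n_genes_filtered = res$n_genes_filtered,
    stage1 = stage_report(res$stage1)
  )
  if (two_stage) {
    report$stage2 <- stage_report(res$stage2)
    report$preservation <- res$preservation
    report$consensus <- list(
      n_modules = sum(unique(res$consensus$modules$labels) != "grey"),
      module_sizes = as.list(module_sizes(res$consensus$modules))
    )
    if (!is.null(res$consensus$association)) {
      report$consensus$association <- lapply(
        res$consensus$association, function(a) a$table
      )
    }
    gd <- res$trajectory$group_distances
    report$trajectory <- list(
      group_distances = as.data.frame(gd),
      bgpca_var_fraction = as.list(res$trajectory$bgpca$var_fraction)
    )
  }
  if (!is.null(res$overlap_battery)) {
    report$qtl_overlap <- res$overlap_battery
  }
  report
}

.write_log <- function(res, config, out_dir) {
  cfg_lines <- c(
    sprintf("seed=%d", config$seed),
    sprintf("total_min=%g", config$total_min),
    sprintf("per_stage_min=%g", config$per_stage_min),
    sprintf("z_threshold=%g", config$z_threshold),
    sprintf("powers_scanned=%s", paste(range(config$network$powers_scanned), collapse = "..")),
    sprintf("scale_free_r2_target=%g", config$network$scale_free_r2_target),
    sprintf("fallback_beta=%d", config$network$fallback_beta),
    sprintf("max_p_outliers=%g", config$network$max_p_outliers),
    sprintf("min_module_size=%d", config$network$min_module_size),
    sprintf("merge_cut_height=%g", config$network$merge_cut_height),
    sprintf("eig_perms=%d", config$eig_perms),
    sprintf("rv_perms=%d", config$rv_perms),
    sprintf("preservation_perms=%d", config$preservation_perms),
    sprintf("region_perms=%d", config$region_perms),
    sprintf("candidate_threshold=%g", config$candidate_threshold),
    sprintf("fdr_level=%g", config$fdr_level),
    sprintf("stage1_beta=%d", res$stage1$beta),
    if (!is.null(res$stage2)) sprintf("stage2_beta=%d", res$stage2$beta)
  )
  atomic_write(file.path(out_dir, "run.log"), function(tmp) {
    writeLines(cfg_lines, tmp)
  })
}
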