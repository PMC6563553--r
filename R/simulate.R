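# Synthetic two-stage RNA-seq generator with planted coexpression modules,
# trait effects, partial cross-stage preservation, and a toy genome with QTL
# intervals. The generator defines the study conditions every downstream stage
# is tested against.

#' Simulation configuration
#'
#' Defaults emulate a small two-stage benthic/limnetic design: 6 benthic and 6
#' limnetic samples per stage, six 50-gene modules (two of them
#' trait-associated with a latent shift of 2 between morphs), 100 background
#' genes, gene loadings in (0.6, 0.9), negative-binomial counts with dispersion
#' 0.1 and library sizes of 0.5-1 million reads, and half of the modules
#' preserved intact in the second stage.
#'
#' @param n_samples_per_group samples per morph per stage.
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of module sizes (length `n_modules`).
#' @param n_background_genes unstructured genes added to the matrix.
#' @param trait_effect_sizes per-module shift added to the latent module score
#'   of limnetic samples; either one vector (used at both stages) or a list
#'   with elements `stage1` and `stage2`.
#' @param loading_range range in (0, 1\] for per-gene module loadings.
#' @param nb_dispersion negative-binomial dispersion d (Var = mu + mu^2 d).
#' @param library_size_range range of per-sample library sizes.
#' @param preserved_fraction fraction of modules kept intact in stage 2; genes
#'   of the remaining modules are reshuffled onto new independent latent scores.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_group = 6L,
                       n_modules = 6L,
                       module_sizes = rep(50L, 6L),
                       n_background_genes = 100L,
                       trait_effect_sizes = c(2, 2, 0, 0, 0, 0),
                       loading_range = c(0.6, 0.9),
                       nb_dispersion = 0.1,
                       library_size_range = c(5e5, 1e6),
                       preserved_fraction = 0.5,
                       seed = 1L) {
  if (is.list(trait_effect_sizes)) {
    stopifnot(all(c("stage1", "stage2") %in% names(trait_effect_sizes)))
    delta1 <- trait_effect_sizes$stage1
    delta2 <- trait_effect_sizes$stage2
  } else {
    delta1 <- delta2 <- trait_effect_sizes
  }
  if (n_samples_per_group < 2) stopf("need at least 2 samples per group")
  if (length(module_sizes) != n_modules) {
    stopf("module_sizes must have length n_modules (%d)", n_modules)
  }
  if (any(module_sizes < 1)) stopf("all module sizes must be >= 1")
  if (length(delta1) != n_modules || length(delta2) != n_modules) {
    stopf("trait_effect_sizes must have length n_modules (%d)", n_modules)
  }
  if (loading_range[1] <= 0 || loading_range[2] > 1 ||
    loading_range[1] > loading_range[2]) {
    stopf("loading_range must be an interval within (0, 1]")
  }
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (library_size_range[1] < 1 || library_size_range[1] > library_size_range[2]) {
    stopf("library_size_range must be a positive increasing interval")
  }
  if (preserved_fraction < 0 || preserved_fraction > 1) {
    stopf("preserved_fraction must lie in [0, 1]")
  }
  structure(
    list(
      n_samples_per_group = as.integer(n_samples_per_group),
      n_modules = as.integer(n_modules),
      module_sizes = as.integer(module_sizes),
      n_background_genes = as.integer(n_background_genes),
      delta_stage1 = as.numeric(delta1),
      delta_stage2 = as.numeric(delta2),
      loading_range = as.numeric(loading_range),
      nb_dispersion = as.numeric(nb_dispersion),
      library_size_range = as.numeric(library_size_range),
      preserved_fraction = as.numeric(preserved_fraction),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# One stage of counts from the latent module model: log-mean
# mu_g = b_g + a_g * s_{m(g)} + eps, counts NB with per-sample library size.
.simulate_stage_counts <- function(module_of, loadings, baseline, delta, meta, config) {
  n_samples <- nrow(meta)
  n_genes <- length(module_of)
  n_modules <- config$n_modules
  scores <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
  scores <- scores + outer(as.numeric(meta$morph == "limnetic"), delta)
  noise_sd <- sqrt(pmax(0, 1 - loadings^2))
  logmu <- matrix(0, n_genes, n_samples)
  for (g in seq_len(n_genes)) {
    signal <- if (module_of[g] > 0) loadings[g] * scores[, module_of[g]] else 0
    logmu[g, ] <- baseline[g] + signal + stats::rnorm(n_samples, sd = noise_sd[g])
  }
  w <- exp(logmu)
  rel <- sweep(w, 2, colSums(w), "/")
  libsize <- round(stats::runif(
    n_samples, config$library_size_range[1], config$library_size_range[2]
  ))
  mu <- sweep(rel, 2, libsize, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    n_genes, n_samples
  )
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(names(module_of), meta$sample_id)
  counts
}

.stage_metadata <- function(stage, config) {
  n <- config$n_samples_per_group
  morph <- rep(c("benthic", "limnetic"), each = n)
  data.frame(
    sample_id = sprintf("%s_%s_%02d", stage, morph, c(seq_len(n), seq_len(n))),
    stage = stage,
    morph = morph,
    species = rep(c("spA", "spB", "spC", "spD"), length.out = 2 * n),
    lake = rep(c("lake1", "lake2"), length.out = 2 * n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-stage count dataset with planted structure
#'
#' Generates one count matrix per developmental stage from a latent module
#' model: each module has a per-sample standard-normal score, shifted by the
#' module's trait effect for limnetic samples; each member gene loads on its
#' module's score on the log scale with unit total latent variance; counts are
#' negative-binomial around library-size-scaled expected abundances. Stage 2
#' keeps the gene-module map of preserved modules and reshuffles the genes of
#' non-preserved modules onto new, independent latent scores.
#'
#' @param config a [sim_config()].
#' @return list with `counts1`, `counts2` (genes x samples integer matrices),
#'   `meta1`, `meta2` (sample metadata data.frames) and `truth`, a
#'   `sim_truth` recording the gene->module maps of both stages, per-stage
#'   trait effects, preservation flags, DE flags, and (after
#'   [simulate_genome()]) genomic positions and QTL intervals.
#' @export
simulate_two_stage_counts <- function(config = sim_config()) {
  with_local_seed(config$seed, {
    n_mod_genes <- sum(config$module_sizes)
    n_genes <- n_mod_genes + config$n_background_genes
    genes <- sprintf("g%04d", seq_len(n_genes))
    module_of1 <- c(
      rep(seq_len(config$n_modules), times = config$module_sizes),
      rep(0L, config$n_background_genes)
    )
    names(module_of1) <- genes
    loadings <- ifelse(
      module_of1 > 0,
      stats::runif(n_genes, config$loading_range[1], config$loading_range[2]),
      0
    )
    baseline <- stats::runif(n_genes, log(100), log(1000))
    meta1 <- .stage_metadata("1dph", config)
    meta2 <- .stage_metadata("1mph", config)
    counts1 <- .simulate_stage_counts(
      module_of1, loadings, baseline, config$delta_stage1, meta1, config
    )
    # Stage 2: keep preserved modules, reshuffle the rest onto new scores.
    n_preserved <- round(config$preserved_fraction * config$n_modules)
    preserved <- seq_len(config$n_modules) <= n_preserved
    module_of2 <- module_of1
    loadings2 <- loadings
    reassign <- which(module_of1 > 0 & !preserved[pmax(module_of1, 1L)])
    if (length(reassign) > 0) {
      shuffled <- sample(reassign)
      module_of2[reassign] <- module_of1[shuffled]
      loadings2[reassign] <- stats::runif(
        length(reassign), config$loading_range[1], config$loading_range[2]
      )
    }
    counts2 <- .simulate_stage_counts(
      module_of2, loadings2, baseline, config$delta_stage2, meta2, config
    )
    module_names <- function(mo, stage_tag, new = logical(length(mo))) {
      ifelse(mo == 0, "none",
        ifelse(new, sprintf("module%d_%s", mo, stage_tag), sprintf("module%d", mo))
      )
    }
    trait_assoc <- config$delta_stage1 != 0 | config$delta_stage2 != 0
    gene_de <- module_of1 > 0 & trait_assoc[pmax(module_of1, 1L)]
    truth <- structure(
      list(
        genes = genes,
        gene_module_stage1 = stats::setNames(module_names(module_of1, "s1"), genes),
        gene_module_stage2 = stats::setNames(
          module_names(module_of2, "s2", new = !preserved[pmax(module_of2, 1L)] & module_of2 > 0),
          genes
        ),
        module_trait_stage1 = stats::setNames(
          config$delta_stage1, sprintf("module%d", seq_len(config$n_modules))
        ),
        module_trait_stage2 = stats::setNames(
          config$delta_stage2, sprintf("module%d", seq_len(config$n_modules))
        ),
        module_preserved = stats::setNames(
          preserved, sprintf("module%d", seq_len(config$n_modules))
        ),
        gene_de = stats::setNames(gene_de, genes),
        gene_positions = NULL,
        qtl = NULL,
        planted_overlap_module = NULL,
        config = config
      ),
      class = "sim_truth"
    )
    list(
      counts1 = counts1, counts2 = counts2,
      meta1 = meta1, meta2 = meta2, truth = truth
    )
  })
}

#' Write a simulated dataset to a run directory
#'
#' Writes counts and metadata as TSV, the planted truth as JSON and, when a
#' genome has been simulated, transcript positions and QTL intervals as BED
#' plus a linkage-group length table.
#'
#' @param sim result of [simulate_two_stage_counts()] (optionally with `truth`
#'   updated by [simulate_genome()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts1, file.path(dir, "counts_stage1.tsv"))
  write_counts(sim$counts2, file.path(dir, "counts_stage2.tsv"))
  write_metadata(sim$meta1, file.path(dir, "meta_stage1.tsv"))
  write_metadata(sim$meta2, file.path(dir, "meta_stage2.tsv"))
  truth <- sim$truth
  truth_json <- list(
    gene_module_stage1 = as.list(truth$gene_module_stage1),
    gene_module_stage2 = as.list(truth$gene_module_stage2),
    module_trait_stage1 = as.list(truth$module_trait_stage1),
    module_trait_stage2 = as.list(truth$module_trait_stage2),
    module_preserved = as.list(truth$module_preserved),
    gene_de = as.list(truth$gene_de),
    planted_overlap_module = truth$planted_overlap_module
  )
  write_json_atomic(truth_json, file.path(dir, "truth.json"))
  if (!is.null(truth$gene_positions)) {
    write_regions(truth$gene_positions, file.path(dir, "transcripts.bed"))
    write_regions(truth$qtl, file.path(dir, "qtl.bed"))
    write_tsv_atomic(
      data.frame(
        chrom = names(truth$gene_positions$genome),
        length = unname(truth$gene_positions$genome)
      ),
      file.path(dir, "genome.tsv")
    )
  }
  invisible(dir)
}

#' Simulate a toy genome with transcript positions and QTL intervals
#'
#' Linkage groups of equal length partition the genome; QTL intervals of fixed
#' length are placed uniformly; transcripts are placed uniformly at random on
#' linkage groups, except that genes of `enriched_module` are placed inside a
#' random QTL interval with probability `enrichment_prob` (planted overlap
#' enrichment). All intervals are 0-based, half-open.
#'
#' @param truth a `sim_truth` from [simulate_two_stage_counts()].
#' @param n_linkage_groups number of linkage groups (>= 1).
#' @param genome_length total genome length in bp.
#' @param n_qtl number of QTL intervals.
#' @param qtl_length length of each QTL interval in bp.
#' @param transcript_length genomic span of each transcript in bp.
#' @param enriched_module module name (e.g. `"module1"`, stage-1 map) whose
#'   genes are preferentially placed inside QTL, or `NULL`.
#' @param enrichment_prob probability that an enriched-module gene is placed
#'   inside a QTL interval.
#' @param seed integer seed (defaults to the simulation's seed + 1).
#' @return list with `transcripts` and `qtl` (both [region_set()]) and the
#'   updated `truth`.
#' @export
simulate_genome <- function(truth, n_linkage_groups = 4L, genome_length = 4e6,
                            n_qtl = 6L, qtl_length = 1e5,
                            transcript_length = 1000L,
                            enriched_module = NULL, enrichment_prob = 0.9,
                            seed = NULL) {
  if (n_linkage_groups < 1) stopf("need at least one linkage group")
  lg_len <- floor(genome_length / n_linkage_groups)
  if (qtl_length > lg_len) stopf("QTL longer than its linkage group")
  if (transcript_length > lg_len) stopf("transcript longer than its linkage group")
  if (!is.null(enriched_module) && transcript_length > qtl_length) {
    stopf("cannot plant enrichment: transcripts longer than QTL intervals")
  }
  seed <- seed %||% derive_seed(truth$config$seed, 17L)
  genome <- stats::setNames(
    rep(lg_len, n_linkage_groups), paste0("LG", seq_len(n_linkage_groups))
  )
  with_local_seed(seed, {
    qtl_lg <- sample(names(genome), n_qtl, replace = TRUE)
    qtl_start <- floor(stats::runif(n_qtl, 0, lg_len - qtl_length + 1))
    qtl <- region_set(
      data.frame(
        chrom = qtl_lg, start = qtl_start, end = qtl_start + qtl_length,
        name = sprintf("qtl%d", seq_len(n_qtl)), stringsAsFactors = FALSE
      ),
      genome = genome
    )
    genes <- truth$genes
    in_enriched <- if (is.null(enriched_module)) {
      rep(FALSE, length(genes))
    } else {
      truth$gene_module_stage1 == enriched_module &
        stats::runif(length(genes)) < enrichment_prob
    }
    chrom <- sample(names(genome), length(genes), replace = TRUE)
    start <- floor(stats::runif(length(genes), 0, lg_len - transcript_length + 1))
    for (i in which(in_enriched)) {
      q <- sample.int(n_qtl, 1)
      chrom[i] <- qtl_lg[q]
      start[i] <- qtl_start[q] +
        floor(stats::runif(1, 0, qtl_length - transcript_length + 1))
    }
    transcripts <- region_set(
      data.frame(
        chrom = chrom, start = start, end = start + transcript_length,
        name = genes, stringsAsFactors = FALSE
      ),
      genome = genome
    )
    truth$gene_positions <- transcripts
    truth$qtl <- qtl
    truth$planted_overlap_module <- enriched_module
    list(transcripts = transcripts, qtl = qtl, truth = truth)
  })
}
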