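# Eigengene-trait association, gene significance, candidate selection and DE
# enrichment of selected modules.

#' Encode the benthic/limnetic trait
#'
#' Benthic samples are coded 0 and limnetic samples 1, so a positive
#' eigengene-trait correlation means the module is overexpressed in limnetic
#' samples.
#'
#' @param morph character/factor vector with values "benthic"/"limnetic".
#' @param levels the two morph labels, in the order (0, 1).
#' @return named numeric 0/1 vector.
#' @export
trait_vector <- function(morph, levels = c("benthic", "limnetic")) {
  morph <- as.character(morph)
  if (anyNA(morph) || !all(morph %in% levels)) {
    stopf("morph must be one of: %s (no missing values)", paste(levels, collapse = ", "))
  }
  x <- as.numeric(morph == levels[2])
  if (length(unique(x)) < 2) stopf("trait is constant: both morphs must be present")
  stats::setNames(x, names(morph))
}

# Two-sided Student-t p-value for a correlation on n observations.
.cor_pvalue <- function(r, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Eigengene-trait association with FDR control
#'
#' Correlates each module eigengene with the binary benthic/limnetic trait
#' using a hybrid biweight midcorrelation: robust weighting on the eigengene
#' side only, none on the binary side (robust estimation is inappropriate for
#' binary predictors). Two-sided p-values use the Student-t approximation with
#' n - 2 degrees of freedom; Benjamini-Hochberg adjustment is applied across
#' modules and modules with `q <= fdr_level` are flagged as selected. When
#' `expr` is supplied, per-gene gene significance (GS: hybrid bicor of
#' expression with the trait) is also computed.
#'
#' @param eigengenes an `eigengene_matrix` from [compute_eigengenes()].
#' @param trait 0/1 trait vector (see [trait_vector()]), one value per sample.
#' @param fdr_level FDR threshold for module selection (default 0.05).
#' @param expr optional samples x genes expression matrix for GS.
#' @param max_p_outliers outlier cap for the robust side.
#' @return list of class `module_trait_stats`: `table` (module, r, p, q,
#'   selected), `GS` (per-gene trait correlation or NULL), `kME` (from the
#'   eigengene matrix), `fdr_level`.
#' @export
eigengene_trait_association <- function(eigengenes, trait, fdr_level = 0.05,
                                        expr = NULL, max_p_outliers = 0.1) {
  stopifnot(inherits(eigengenes, "eigengene_matrix"))
  me <- eigengenes$scores
  if (length(trait) != nrow(me)) stopf("trait length must match the sample count")
  if (stats::sd(trait) == 0) stopf("trait must be non-constant")
  if (any(apply(me, 2, stats::sd) == 0)) stopf("constant eigengene")
  n <- nrow(me)
  r <- as.numeric(bicor_matrix(me, matrix(trait, ncol = 1),
    max_p_outliers = max_p_outliers, robust_y = FALSE
  ))
  p <- .cor_pvalue(r, n)
  q <- bh_adjust(p)
  tab <- data.frame(
    module = colnames(me), r = r, p = p, q = q,
    selected = q <= fdr_level, stringsAsFactors = FALSE
  )
  gs <- NULL
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    if (nrow(expr) != n) stopf("expr and trait sample counts differ")
    gs <- as.numeric(suppressWarnings(bicor_matrix(
      expr, matrix(trait, ncol = 1),
      max_p_outliers = max_p_outliers, robust_y = FALSE
    )))
    names(gs) <- colnames(expr)
  }
  structure(
    list(table = tab, GS = gs, kME = eigengenes$kME, fdr_level = fdr_level),
    class = "module_trait_stats"
  )
}

#' Select candidate genes in trait-associated modules
#'
#' Within each selected module, a gene is a candidate when the absolute values
#' of BOTH its module membership (kME, correlation of expression with the
#' module eigengene) and its gene significance (GS, correlation of expression
#' with the trait) exceed `threshold` (strict inequality).
#'
#' @param stats a `module_trait_stats` with `GS` computed.
#' @param modules a `module_set` (or named gene->label vector).
#' @param threshold joint |kME|, |GS| threshold (default 0.7).
#' @param which_modules modules to extract candidates from; defaults to all
#'   selected modules. Requesting a non-selected module is an error.
#' @return named list (per module) of data.frames (gene, kME, GS).
#' @export
select_candidates <- function(stats, modules, threshold = 0.7,
                              which_modules = NULL) {
  stopifnot(inherits(stats, "module_trait_stats"))
  if (is.null(stats$GS)) stopf("gene significance not computed; pass expr to eigengene_trait_association")
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  selected <- stats$table$module[stats$table$selected]
  which_modules <- which_modules %||% selected
  bad <- setdiff(which_modules, selected)
  if (length(bad) > 0) {
    stopf("module(s) not in the selected set: %s", paste(bad, collapse = ", "))
  }
  out <- list()
  for (m in which_modules) {
    genes <- names(labels)[labels == m]
    kme <- stats$kME[genes, m]
    gs <- stats$GS[genes]
    take <- !is.na(kme) & !is.na(gs) & abs(kme) > threshold & abs(gs) > threshold
    out[[m]] <- data.frame(
      gene = genes[take], kME = unname(kme[take]), GS = unname(gs[take]),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Fisher exact enrichment of DE genes in a selected module
#'
#' Contrasts the frequency of differentially expressed genes inside the tested
#' module against their frequency among genes outside any selected module
#' (2 x 2 Fisher exact test, two-sided). The sample odds ratio `(a d) / (b c)`
#' is reported (not the conditional MLE).
#'
#' @param module_genes character vector: genes of the tested module.
#' @param de_flags named logical vector of differential-expression calls
#'   covering every gene in the contrast.
#' @param background character vector: genes outside any selected module.
#' @return list with `odds_ratio`, `p`, and the 2 x 2 `table`.
#' @export
fisher_module_enrichment <- function(module_genes, de_flags, background) {
  universe <- c(module_genes, setdiff(background, module_genes))
  missing <- setdiff(universe, names(de_flags))
  if (length(missing) > 0) {
    stopf("de_flags missing for %d gene(s), e.g. %s", length(missing), missing[1])
  }
  in_mod <- universe %in% module_genes
  de <- as.logical(de_flags[universe])
  tab <- matrix(
    c(
      sum(in_mod & de), sum(in_mod & !de),
      sum(!in_mod & de), sum(!in_mod & !de)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_module", "outside"), c("DE", "not_DE"))
  )
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab, degenerate = TRUE))
  }
  or <- (a * d) / (b * cc)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p, table = tab, degenerate = FALSE)
}
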