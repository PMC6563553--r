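# Linkage-group-restricted permutation test of genomic overlap between gene
# sets (as intervals) and QTL regions.

#' Permutation test of region overlap, restricted to linkage groups
#'
#' Each permutation re-places every query interval uniformly at random within
#' its own linkage group (length preserved), so the null respects both genome
#' size and linkage-group structure. The one-sided enrichment p-value is the
#' proportion of null overlap counts greater than or equal to the observed
#' count (with an optional `(b + 1) / (m + 1)` estimator).
#'
#' @param query,subject [region_set()] objects on the same genome.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the randomization.
#' @param plus_one use the (b+1)/(m+1) p-value estimator.
#' @return list of class `overlap_test`: observed count, `null` vector, `p`,
#'   `z` score, `n_perm`, `seed`.
#' @export
region_permutation_test <- function(query, subject, n_perm = 1000L, seed = 1L,
                                    plus_one = FALSE) {
  stopifnot(inherits(query, "region_set"), inherits(subject, "region_set"))
  widths <- query$intervals$end - query$intervals$start
  lg <- query$intervals$chrom
  lg_len <- query$genome[lg]
  if (any(widths > lg_len)) stopf("query interval longer than its linkage group")
  observed <- count_overlaps(query, subject)
  # Pre-reduce the subject per linkage group; a permuted query interval
  # [s, e) then overlaps iff the rightmost subject start <= s has end > s, or
  # the next subject start lies before e (binary search, vectorized).
  subj_by_lg <- lapply(split(
    subject$intervals[, c("start", "end")], subject$intervals$chrom
  ), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
    list(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  lg_groups <- split(seq_along(lg), lg)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ns <- floor(stats::runif(length(widths), 0, lg_len - widths + 1))
      total <- 0L
      for (g in names(lg_groups)) {
        idx <- lg_groups[[g]]
        sb <- subj_by_lg[[g]]
        if (is.null(sb)) next
        s <- ns[idx]
        e <- s + widths[idx]
        j <- findInterval(s, sb$start)
        hit <- (j >= 1 & sb$end[pmax(j, 1)] > s) |
          (j < length(sb$start) & sb$start[pmin(j + 1, length(sb$start))] < e)
        total <- total + sum(hit)
      }
      total
    }, numeric(1))
  })
  p <- if (plus_one) {
    (sum(null >= observed) + 1) / (n_perm + 1)
  } else {
    sum(null >= observed) / n_perm
  }
  s <- stats::sd(null)
  structure(
    list(
      observed = observed, null = null, p = p,
      z = if (s > 0) (observed - mean(null)) / s else NA_real_,
      n_perm = as.integer(n_perm), seed = as.integer(seed)
    ),
    class = "overlap_test"
  )
}

#' Battery of overlap tests with FDR control
#'
#' Runs [region_permutation_test()] for every (gene set, QTL set) pair —
#' optionally adding the union of all QTL sets as a combined subject — and
#' adjusts the resulting p-values with the Benjamini-Hochberg procedure.
#'
#' @param gene_sets named list of [region_set()] queries (e.g. per-module
#'   transcript positions).
#' @param qtl_sets named list of [region_set()] subjects.
#' @param combined also test each gene set against the union of all QTL sets.
#' @param n_perm permutations per test.
#' @param seed integer seed; each test uses a derived substream.
#' @param plus_one see [region_permutation_test()].
#' @return data.frame with gene_set, qtl_set, observed, expected (null mean),
#'   z, p, q (BH), empty-set flag; the individual `overlap_test` objects are
#'   attached as the `tests` attribute.
#' @export
overlap_battery <- function(gene_sets, qtl_sets, combined = TRUE,
                            n_perm = 1000L, seed = 1L, plus_one = FALSE) {
  stopifnot(length(gene_sets) >= 1, length(qtl_sets) >= 1)
  if (combined && length(qtl_sets) > 1) {
    all_int <- do.call(rbind, lapply(qtl_sets, function(x) x$intervals))
    qtl_sets <- c(qtl_sets, list(
      combined = region_set(all_int, qtl_sets[[1]]$genome)
    ))
  }
  rows <- list()
  tests <- list()
  i <- 0L
  for (gn in names(gene_sets)) {
    for (qn in names(qtl_sets)) {
      i <- i + 1L
      gs <- gene_sets[[gn]]
      if (nrow(gs$intervals) == 0) {
        rows[[i]] <- data.frame(
          gene_set = gn, qtl_set = qn, observed = 0, expected = NA_real_,
          z = NA_real_, p = 1, empty = TRUE, stringsAsFactors = FALSE
        )
        next
      }
      # Substream keyed to the query's content: identical gene sets always see
      # identical randomized placements (and therefore identical p-values
      # against the same subject), regardless of their position in the battery.
      key <- (nrow(gs$intervals) + sum(gs$intervals$start)) %% 99991
      tst <- region_permutation_test(
        gs, qtl_sets[[qn]],
        n_perm = n_perm, seed = derive_seed(seed, key), plus_one = plus_one
      )
      tests[[paste(gn, qn, sep = ".")]] <- tst
      rows[[i]] <- data.frame(
        gene_set = gn, qtl_set = qn, observed = tst$observed,
        expected = mean(tst$null), z = tst$z, p = tst$p, empty = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  attr(out, "tests") <- tests
  out
}
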