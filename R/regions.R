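# Genomic interval sets on named linkage groups, 0-based half-open, with an
# attached linkage-group length map.

#' Create a region set
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (0-based half-open coordinates).
#' @param genome named numeric vector mapping linkage-group name -> length.
#' @return object of class `region_set`.
#' @export
region_set <- function(intervals, genome) {
  stopifnot(is.data.frame(intervals), all(c("chrom", "start", "end") %in% names(intervals)))
  if (is.null(intervals$name)) {
    intervals$name <- sprintf("region%d", seq_len(nrow(intervals)))
  }
  intervals <- intervals[, c("chrom", "start", "end", "name")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (is.null(names(genome)) || anyNA(names(genome))) {
    stopf("genome must be a named vector of linkage-group lengths")
  }
  bad <- which(intervals$start >= intervals$end)
  if (length(bad) > 0) {
    stopf(
      "interval start >= end at row %d (%s:%s-%s)", bad[1],
      intervals$chrom[bad[1]], intervals$start[bad[1]], intervals$end[bad[1]]
    )
  }
  missing_lg <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_lg) > 0) {
    stopf("interval(s) on linkage group(s) absent from genome: %s",
      paste(missing_lg, collapse = ", "))
  }
  over <- which(intervals$start < 0 |
    intervals$end > genome[intervals$chrom])
  if (length(over) > 0) {
    stopf("interval at row %d extends outside its linkage group", over[1])
  }
  structure(list(intervals = intervals, genome = genome), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf(
    "region_set: %d intervals on %d linkage group(s)\n",
    nrow(x$intervals), length(x$genome)
  ))
  print(utils::head(x$intervals))
  invisible(x)
}

# 0-based half-open -> 1-based closed GRanges.
.as_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$intervals$chrom,
    ranges = IRanges::IRanges(
      start = rs$intervals$start + 1, end = rs$intervals$end
    )
  )
}

#' Read a BED3+ file into a region set
#'
#' Reads chrom/start/end (and optional name) columns; coordinates stay 0-based
#' half-open as in the BED convention. `start >= end` rows are rejected.
#'
#' @param path BED file path.
#' @param genome named numeric vector of linkage-group lengths, or the path of
#'   a two-column (chrom, length) TSV.
#' @return a [region_set()].
#' @export
read_regions <- function(path, genome) {
  if (is.character(genome) && length(genome) == 1) {
    g <- utils::read.table(genome, header = FALSE, sep = "\t",
      col.names = c("chrom", "length"), stringsAsFactors = FALSE)
    # tolerate an optional header row
    if (is.na(suppressWarnings(as.numeric(g$length[1])))) g <- g[-1, , drop = FALSE]
    genome <- stats::setNames(as.numeric(g$length), g$chrom)
  }
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stopf("cannot parse BED file '%s': %s", path, conditionMessage(e))
  )
  if (ncol(raw) < 3) stopf("BED file '%s' needs at least 3 columns", path)
  intervals <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    stringsAsFactors = FALSE
  )
  if (ncol(raw) >= 4) intervals$name <- as.character(raw[[4]])
  region_set(intervals, genome)
}

#' Write a region set as BED4
#'
#' @param rs a [region_set()].
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_regions <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  atomic_write(path, function(tmp) {
    df <- rs$intervals
    df$start <- format(df$start, scientific = FALSE, trim = TRUE)
    df$end <- format(df$end, scientific = FALSE, trim = TRUE)
    utils::write.table(df, tmp,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  })
}

#' Count query intervals overlapping a subject set
#'
#' A query interval counts if it shares at least 1 bp with any subject interval
#' (half-open semantics: `[0, 100)` and `[100, 200)` do not overlap).
#'
#' @param query,subject [region_set()] objects on the same genome.
#' @return integer count of overlapping query intervals.
#' @export
count_overlaps <- function(query, subject) {
  stopifnot(inherits(query, "region_set"), inherits(subject, "region_set"))
  # the two sets may legitimately occupy different subsets of linkage groups
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(query), .as_granges(subject))
  )
  sum(hits > 0)
}
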