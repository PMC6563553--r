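# Readers/writers for the on-disk formats: counts and metadata TSV, JSON
# reports. Genes are rows on disk (the RNA-seq convention); the in-memory
# samples x genes orientation used by network code is produced by vst_counts().

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column; entries
#' must be non-negative integers and gene ids unique.
#'
#' @param path TSV file path.
#' @return genes x samples integer matrix.
#' @export
read_counts <- function(path) {
  raw <- utils::read.table(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stopf("'%s' is not a gene x sample count table (empty or too few columns)", path)
  }
  genes <- as.character(raw[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stopf("duplicated gene id(s): %s", paste(unique(dup), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf(
      "non-integer or negative count at gene '%s', sample '%s'",
      genes[bad[1, 1]], colnames(m)[bad[1, 2]]
    )
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path) {
  atomic_write(path, function(tmp) {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read sample metadata from TSV
#'
#' Requires columns sample_id (unique) and stage; morph must be present (and
#' non-missing) when trait analyses are run.
#'
#' @param path TSV file path.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  if (!all(c("sample_id", "stage") %in% names(meta))) {
    stopf("metadata needs at least sample_id and stage columns")
  }
  if (anyDuplicated(meta$sample_id)) stopf("sample ids must be unique")
  meta
}

#' Write sample metadata as TSV
#'
#' @param meta metadata data.frame.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_metadata <- function(meta, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(meta, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

# Deterministic JSON writer used for reports and truth objects.
write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

write_tsv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
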