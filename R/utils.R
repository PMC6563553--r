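#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
#' afterwards, so that library code never perturbs user-level randomness.
#'
#' @param seed integer seed (`NULL` leaves the RNG untouched).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage substream seeds derived from one global seed; kept
# below 2^31 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Atomic file write
#'
#' Writes via a temporary file in the same directory followed by a rename, so a
#' crash never leaves a half-written artifact.
#'
#' @param path destination path.
#' @param writer function of one argument (a path) performing the actual write.
#' @keywords internal
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

off_diag <- function(m) m[row(m) != col(m)]

upper_tri <- function(m) m[upper.tri(m)]
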