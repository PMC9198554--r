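#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All coordinates are 0-based
# half-open internally; conversion to 1-based happens only in VCF and
# marker-map writers.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a stage tag
#'
#' One explicit seed flows through the whole pipeline; every module draws its
#' randomness from a deterministic child seed so stages can be re-run in
#' isolation. Result is kept below 2^31 - 1.
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return an integer seed.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 69621) %% (2^31 - 1))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Union length of possibly-overlapping numeric intervals
#'
#' Half-open [start, end) intervals on the real line; plain sweep so that
#' fractional (per-chromosome normalised) coordinates are supported.
#' @noRd
interval_union_length <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] > cur_e) {
        total <- total + (cur_e - cur_s)
        cur_s <- start[i]; cur_e <- end[i]
      } else {
        cur_e <- max(cur_e, end[i])
      }
    }
  }
  total + (cur_e - cur_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_user <- function(msg) stop(msg, call. = FALSE)
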