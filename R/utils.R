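# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' IUPAC-aware wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode a Sanger-encoded quality string to Phred scores
#'
#' @param qual character vector of Phred+33 encoded quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (!nzchar(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

# Arithmetic mean of the Phred values of each quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# Validate a reads data.frame (read_id, sample_id, seq, qual).
assert_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sample_id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("sequence/quality length mismatch for read(s): ",
         paste(reads$read_id[bad], collapse = ", "))
  invisible(reads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
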