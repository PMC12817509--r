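# Representative-sequence construction: subsample each shared cluster,
# build a consensus, then polish it by aligning reads back to the draft
# and applying column-wise majority edits.
#
# The consensus engine is a pileup-majority scheme over banded
# overlap alignments of the reads onto a backbone (the read whose length
# is closest to the cluster's median read length), iterated until it
# stabilises. Polishing reuses the same primitive with the current draft
# as backbone. Ties are broken toward the draft base, so error-free
# reads leave a correct draft unchanged. An external aligner+polisher
# can be plugged in via `backend`.

#' Consensus/polishing parameters
#'
#' @param subsample_cap reads used per cluster (default 200): larger
#'   clusters are uniformly subsampled to this size.
#' @param polish_rounds rounds of pileup-majority polishing applied after
#'   consensus construction (default 2, the conventional plateau).
#' @param band half-width of the alignment band (bases).
#' @param seed RNG seed for subsampling.
#' @return object of class `polish_params`.
#' @export
polish_params <- function(subsample_cap = 200L, polish_rounds = 2L,
                          band = 80L, seed = 42L) {
  stopifnot(subsample_cap >= 1, polish_rounds >= 0, band >= 8)
  structure(list(subsample_cap = as.integer(subsample_cap),
                 polish_rounds = as.integer(polish_rounds),
                 band = as.integer(band), seed = as.integer(seed)),
            class = "polish_params")
}

#' Subsample a cluster to at most `cap` reads
#'
#' All reads are kept when the cluster size is at or below `cap`
#' (equality is not subsampled); otherwise a uniform seed-reproducible
#' sample of exactly `cap`.
#'
#' @param reads reads data.frame.
#' @param cap subsample threshold (default 200).
#' @param seed RNG seed.
#' @return subset of `reads`.
#' @export
subsample_cluster <- function(reads, cap = 200L, seed = 42L) {
  n <- nrow(reads)
  if (n == 0) stop("reads must be non-empty")
  if (n <= cap) return(reads)
  idx <- with_local_seed(seed, sample.int(n, cap))
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One pileup-majority rewrite of `draft` given read sequences.
polish_round <- function(draft, seqs, band = 80L) {
  .polish_round_cpp(draft, seqs, band = band)
}

#' Consensus sequence of a read cluster
#'
#' Backbone = the read whose length is closest to the median read length
#' (ties to the earliest read); all reads are then aligned onto the
#' backbone and majority edits applied, iterating up to `max_rounds`
#' times or until the sequence stabilises. A single read is returned
#' unchanged. Deterministic for a fixed input order.
#'
#' @param seqs character vector of read sequences (>= 1).
#' @param max_rounds maximum majority-edit iterations (default 3).
#' @param band alignment band half-width.
#' @return consensus DNA string.
#' @export
consensus_sequence <- function(seqs, max_rounds = 3L, band = 80L) {
  if (!length(seqs)) stop("consensus of an empty read set")
  if (length(seqs) == 1L) return(seqs[[1]])
  lens <- nchar(seqs)
  backbone <- seqs[[which.min(abs(lens - median(lens)))]]
  draft <- backbone
  for (i in seq_len(max_rounds)) {
    res <- polish_round(draft, seqs, band)
    if (identical(res$seq, draft)) break
    draft <- res$seq
  }
  draft
}

#' Polish a draft sequence against a cluster's reads
#'
#' Per round: align all reads to the draft (banded overlap alignment),
#' build a column-wise pileup including insertions and deletions, and
#' replace each draft position by the weighted majority operation. Reads
#' identical to the draft leave it unchanged. If no read aligns, the
#' draft is returned unchanged with a warning.
#'
#' @param draft draft DNA string (non-empty).
#' @param reads reads data.frame (or character vector of sequences).
#' @param params a [polish_params()].
#' @param backend optional external polisher: a
#'   `function(draft, seqs)` returning the polished sequence, applied
#'   once per round under the same contract (e.g. a minimap2+racon
#'   wrapper).
#' @return polished DNA string.
#' @export
polish <- function(draft, reads, params = polish_params(),
                   backend = NULL) {
  stopifnot(nzchar(draft))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  out <- draft
  for (i in seq_len(params$polish_rounds)) {
    if (!is.null(backend)) {
      out <- backend(out, seqs)
      next
    }
    res <- polish_round(out, seqs, params$band)
    if (res$n_aligned == 0) {
      warning("no reads aligned to the draft; returning it unchanged")
      return(out)
    }
    if (identical(res$seq, out)) break
    out <- res$seq
  }
  out
}

#' Build the polished representative sequence of one cluster
#'
#' Subsample (cap `subsample_cap`), consensus, then `polish_rounds` of
#' polishing against the subsampled reads.
#'
#' @param reads reads data.frame of one shared cluster.
#' @param params a [polish_params()].
#' @param backend optional external polisher (see [polish()]).
#' @return representative DNA string.
#' @export
cluster_representative <- function(reads, params = polish_params(),
                                   backend = NULL) {
  sub <- subsample_cluster(reads, params$subsample_cap, params$seed)
  cons <- consensus_sequence(sub$seq, band = params$band)
  polish(cons, sub, params, backend = backend)
}
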