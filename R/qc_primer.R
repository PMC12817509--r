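# Quality/length filtering and primer-anchored amplicon extraction.
#
# Reads are kept when their mean Phred score and length fall inside the
# configured windows, then re-oriented and trimmed to the region between
# the forward primer and the reverse complement of the reverse primer.
# Primer placement uses semi-global alignment (primer end-to-end, free
# ends on the read) so that indel-rich long-read errors inside the primer
# region do not defeat the anchor; IUPAC degeneracy codes match their
# full sets (M matches A or C).

#' Default amplification primers
#'
#' 27F (`AGAGTTTGATCMTGGCTCAG`) and 1492R (`CGGTTACCTTGTTACGACTT`), the
#' primer pair used for full-length 16S rRNA gene amplification on
#' Nanopore barcoding kits. Both are written 5'->3' on their own strands.
#'
#' @param fwd forward primer (IUPAC DNA).
#' @param rev reverse primer (IUPAC DNA).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(fwd = "AGAGTTTGATCMTGGCTCAG",
                        rev = "CGGTTACCTTGTTACGACTT") {
  for (p in c(fwd = fwd, rev = rev)) {
    if (!nzchar(p)) stop("primers must be non-empty")
    if (grepl("[^ACGTURYSWKMBDHVN]", toupper(p)))
      stop("primer contains non-IUPAC characters: ", p)
  }
  structure(list(fwd = toupper(fwd), rev = toupper(rev)),
            class = "primer_pair")
}

#' Quality-control parameters
#'
#' @param min_quality minimum mean Phred score (arithmetic mean of the
#'   per-base Phred values). Default 10.
#' @param min_len,max_len read length window in bases; the defaults
#'   (1200-1800) bracket full-length 16S amplicons.
#' @param primer_min_identity minimum fraction of primer positions that
#'   must match at the best placement (default 0.95).
#' @return object of class `qc_params`.
#' @export
qc_params <- function(min_quality = 10, min_len = 1200L, max_len = 1800L,
                      primer_min_identity = 0.95) {
  stopifnot(min_len > 0, min_len <= max_len,
            primer_min_identity > 0, primer_min_identity <= 1)
  structure(list(min_quality = min_quality, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 primer_min_identity = primer_min_identity),
            class = "qc_params")
}

#' Filter reads on mean quality and length
#'
#' Keeps exactly the reads with mean Phred >= `min_quality` and length in
#' `[min_len, max_len]`; order is preserved and sequences are never
#' modified. Idempotent.
#'
#' @param reads reads data.frame (see [parse_fastq()]).
#' @param qc a [qc_params()] object.
#' @return the retained subset of `reads`.
#' @export
filter_reads <- function(reads, qc = qc_params()) {
  assert_reads(reads)
  if (!nrow(reads)) return(reads)
  len <- nchar(reads$seq)
  keep <- mean_phred(reads$qual) >= qc$min_quality &
    len >= qc$min_len & len <= qc$max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best semi-global placement of `primer` on `seq` (forward strand only).
# Returns list(start, end, identity) with 0-based half-open coordinates,
# or NULL when the primer is longer than seq.
match_primer_stranded <- function(seq, primer) {
  if (nchar(primer) > nchar(seq)) return(NULL)
  hit <- .primer_align_cpp(seq, primer)
  if (hit$start < 0) return(NULL)
  list(start = hit$start, end = hit$end,
       identity = hit$matches / nchar(primer))
}

#' Locate the best primer placement on a read or its reverse complement
#'
#' Semi-global alignment: the primer aligns end to end, the read has free
#' ends; identity is matched primer positions divided by primer length.
#' Both the read and its reverse complement are searched.
#'
#' @param seq DNA string to search.
#' @param primer IUPAC primer sequence.
#' @param min_identity identity threshold below which `NULL` is returned.
#' @return `NULL`, or a list with `start`, `end` (0-based half-open),
#'   `strand` (`"+"` or `"-"`) and `identity`. For `strand == "-"` the
#'   coordinates refer to the reverse complement of `seq`.
#' @export
match_primer <- function(seq, primer, min_identity = 0.95) {
  fwd <- match_primer_stranded(seq, primer)
  rev <- match_primer_stranded(revcomp(seq), primer)
  best <- NULL
  if (!is.null(fwd)) best <- c(fwd, strand = "+")
  if (!is.null(rev) && (is.null(best) || rev$identity > best$identity))
    best <- c(rev, strand = "-")
  if (is.null(best) || best$identity < min_identity) return(NULL)
  best[c("start", "end", "strand", "identity")]
}

#' Extract the amplicon between the two primers
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the same strand, with the forward primer upstream. The read
#' is re-oriented to the forward strand and trimmed to the region
#' *between* the primers (primers excluded); qualities are sliced
#' consistently. Returns `NULL` when either primer is missing at
#' `primer_min_identity` or the order test fails.
#'
#' @param read a single read as a list or one-row data.frame with `seq`
#'   and `qual` (and optionally `read_id`, `sample_id`).
#' @param primers a [primer_pair()].
#' @param qc a [qc_params()]; only `primer_min_identity` is used.
#' @return the trimmed, forward-oriented read (same shape as input), or
#'   `NULL`.
#' @export
extract_amplicon <- function(read, primers = primer_pair(),
                             qc = qc_params()) {
  if (is.data.frame(read)) read <- as.list(read[1, ])
  rc_rev <- revcomp(primers$rev)
  best <- NULL
  for (orient in c("+", "-")) {
    s <- if (orient == "+") read$seq else revcomp(read$seq)
    f <- match_primer_stranded(s, primers$fwd)
    r <- match_primer_stranded(s, rc_rev)
    if (is.null(f) || is.null(r)) next
    if (f$identity < qc$primer_min_identity ||
        r$identity < qc$primer_min_identity) next
    if (f$end > r$start) next
    score <- f$identity + r$identity
    if (is.null(best) || score > best$score)
      best <- list(orient = orient, from = f$end + 1L, to = r$start,
                   score = score)
  }
  if (is.null(best)) return(NULL)
  s <- if (best$orient == "+") read$seq else revcomp(read$seq)
  q <- read$qual
  if (best$orient == "-")
    q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
  if (best$from > best$to) return(NULL) # zero-length insert
  read$seq <- substr(s, best$from, best$to)
  read$qual <- substr(q, best$from, best$to)
  read
}

# Vectorised extract_amplicon over a reads data.frame; drops reads where
# extraction fails.
extract_amplicons <- function(reads, primers = primer_pair(),
                              qc = qc_params()) {
  assert_reads(reads)
  if (!nrow(reads)) return(reads)
  out <- lapply(seq_len(nrow(reads)), function(i)
    extract_amplicon(as.list(reads[i, ]), primers, qc))
  ok <- !vapply(out, is.null, logical(1))
  if (!any(ok)) return(reads[0, , drop = FALSE])
  res <- do.call(rbind, lapply(out[ok], as.data.frame))
  rownames(res) <- NULL
  res
}

#' Fraction of sequences from which the amplicon can be extracted
#'
#' Primer-efficiency audit: each sequence is treated as a perfect-quality
#' read and the fraction for which [extract_amplicon()] succeeds is
#' returned. Used to quantify primer bias against particular species.
#'
#' @param seqs character vector of DNA sequences (e.g. all 16S copies of
#'   a species).
#' @param primers a [primer_pair()].
#' @param min_identity primer identity threshold (default 0.95).
#' @return fraction in `[0, 1]`.
#' @export
primer_extraction_ratio <- function(seqs, primers = primer_pair(),
                                    min_identity = 0.95) {
  if (!length(seqs)) stop("seqs must be non-empty")
  qc <- qc_params(primer_min_identity = min_identity)
  ok <- vapply(seqs, function(s) {
    rd <- list(seq = s, qual = strrep("I", nchar(s)))
    !is.null(extract_amplicon(rd, primers, qc))
  }, logical(1), USE.NAMES = FALSE)
  mean(ok)
}
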