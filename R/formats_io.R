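# Readers and writers for the external formats the pipeline touches:
# FASTQ (Phred+33, optionally gzipped), reference FASTA with 7-rank
# taxonomy, BLAST outfmt-6 tabular hits, and the TSV tables of the final
# output directory. No science lives here; the contracts are bit-exact.

#' Parse a single FASTQ file
#'
#' Gzip compression is handled transparently. Each record is validated:
#' the header must start with `@`, the separator with `+`, and the quality
#' string must be exactly as long as the sequence. Violations raise an
#' error naming the file and the 1-based record index.
#'
#' @param path path to a `.fastq`/`.fq` file, optionally `.gz`.
#' @param sample_id sample identifier attached to every read; defaults to
#'   the file name stem.
#' @return data.frame with columns `read_id`, `sample_id`, `seq`, `qual`
#'   in file order.
#' @export
parse_fastq <- function(path, sample_id = fastq_stem(path)) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop(path, ": truncated FASTQ (", length(lines),
         " lines, not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(0), sample_id = character(0),
                      seq = character(0), qual = character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(path, ": record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop(path, ": record ", bad[1], ": separator does not start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(path, ": record ", bad[1],
         ": quality string length (", nchar(qual[bad[1]]),
         ") != sequence length (", nchar(seq[bad[1]]), ")")
  read_id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[`, "", 1L))
  data.frame(read_id = read_id, sample_id = sample_id,
             seq = seq, qual = qual)
}

fastq_stem <- function(path) {
  sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
}

#' Read a directory of per-sample FASTQ files
#'
#' One sample per file; the sample id is the file name stem (demultiplexing
#' is upstream of this tool).
#'
#' @param dir_path directory containing `.fastq`/`.fq(.gz)` files.
#' @return named list mapping sample id to a reads data.frame
#'   (see [parse_fastq()]).
#' @export
read_fastq_dir <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("input directory not found: ", dir_path)
  files <- list.files(dir_path, pattern = "\\.(fastq|fq)(\\.gz)?$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("no FASTQ files found in ", dir_path)
  files <- sort(files)
  out <- lapply(files, parse_fastq)
  names(out) <- vapply(files, fastq_stem, "", USE.NAMES = FALSE)
  out
}

#' Parse a 7-rank taxonomy string
#'
#' Accepts GTDB/Qiime2-style strings (`d__Bacteria;p__...;s__...`) with or
#' without rank prefixes. Empty labels (e.g. a bare `s__`) become
#' `"unclassified"`.
#'
#' @param x taxonomy string with exactly 7 semicolon-separated fields.
#' @param context label used in error messages (e.g. an accession).
#' @return named character vector of length 7 (see [TAX_RANKS]).
#' @export
parse_lineage <- function(x, context = NULL) {
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  if (length(parts) != 7L)
    stop("taxonomy string", if (!is.null(context)) paste0(" for '", context, "'"),
         " has ", length(parts), " fields, expected 7: ", x)
  labs <- sub("^[dpcofgs]__", "", parts)
  labs[!nzchar(labs)] <- "unclassified"
  setNames(labs, TAX_RANKS)
}

#' Serialize a 7-rank lineage to a Qiime2-compatible string
#'
#' @param lineage named character vector of length 7 (domain..species).
#' @param upto last rank to include (name or index); defaults to species.
#' @return single string such as `"d__Bacteria;p__...;s__..."`.
#' @export
format_lineage <- function(lineage, upto = 7L) {
  if (is.character(upto)) upto <- match(upto, TAX_RANKS)
  stopifnot(length(lineage) == 7L, upto >= 1L, upto <= 7L)
  paste0(TAX_PREFIXES[seq_len(upto)], lineage[seq_len(upto)],
         collapse = ";")
}

#' Parse a reference FASTA with 7-rank taxonomy
#'
#' Taxonomy may be embedded in the FASTA headers
#' (`accession d__...;p__...;...;s__...`) or supplied as a two-column
#' TSV mapping accession to taxonomy string.
#'
#' @param fasta path to the reference FASTA.
#' @param tax_map optional path to an accession-to-taxonomy TSV.
#' @return data.frame with `ref_id`, `seq` and one column per rank.
#' @export
parse_reference_fasta <- function(fasta, tax_map = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (!length(ss)) stop("reference FASTA is empty: ", fasta)
  headers <- names(ss)
  acc <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (is.null(tax_map)) {
    tax <- trimws(sub("^\\S+", "", headers))
    if (any(!nzchar(tax)))
      stop("no taxonomy in FASTA header for: ",
           paste(acc[!nzchar(tax)], collapse = ", "),
           " (supply tax_map instead)")
  } else {
    tm <- read.delim(tax_map, header = FALSE, colClasses = "character")
    if (ncol(tm) < 2L) stop("taxonomy map must have two columns: ", tax_map)
    if (tolower(tm[1, 1]) %in% c("feature id", "accession", "id"))
      tm <- tm[-1, , drop = FALSE]
    tax <- tm[[2]][match(acc, tm[[1]])]
    if (anyNA(tax))
      stop("no taxonomy map entry for: ", paste(acc[is.na(tax)], collapse = ", "))
  }
  lin <- t(vapply(seq_along(acc),
                  function(i) parse_lineage(tax[i], context = acc[i]),
                  character(7)))
  colnames(lin) <- TAX_RANKS
  out <- cbind(data.frame(ref_id = acc, seq = unname(as.character(ss))),
               as.data.frame(lin))
  rownames(out) <- NULL
  out
}

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse BLAST tabular (outfmt 6) hits
#'
#' Hits are grouped per query in input order; at most `max_hits` hits are
#' retained per query.
#'
#' @param path path to a 12-column BLAST tabular file.
#' @param max_hits per-query retention cap (default 50, the search depth
#'   used for taxonomy assignment).
#' @return named list mapping query id to a hits data.frame with the
#'   standard outfmt-6 columns.
#' @export
parse_blast_tabular <- function(path, max_hits = 50L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop(path, ": line ", which(nf < 12L)[1],
         ": expected >= 12 tab-separated fields, got ", nf[nf < 12L][1])
  mat <- t(vapply(parts, function(p) p[1:12], character(12)))
  df <- as.data.frame(mat)
  names(df) <- BLAST6_COLS
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart",
                "qend", "sstart", "send", "evalue", "bitscore")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop(path, ": line ", which(is.na(v))[1],
           ": non-numeric value '", df[[cc]][which(is.na(v))[1]],
           "' in column ", cc)
    df[[cc]] <- v
  }
  out <- split(df, factor(df$qseqid, levels = unique(df$qseqid)))
  lapply(out, function(h) {
    rownames(h) <- NULL
    head(h, max_hits)
  })
}

#' Write a feature table as TSV
#'
#' First column `Feature ID`, one column per sample, integer counts.
#' @param table integer matrix (rows features, columns samples).
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(`Feature ID` = rownames(table), table,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return integer matrix with feature row names.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write the final output directory
#'
#' Produces (a) a representative-sequence FASTA wrapped at 80 columns,
#' (b) the cluster count table, (c) a wide taxonomy TSV with one column
#' per rank, (d) a Qiime2-compatible two-column taxonomy TSV
#' (`Feature ID<TAB>Taxon`), and (e) one collapsed count table per rank.
#'
#' @param table integer feature table (rows = cluster ids, cols = samples).
#' @param taxonomy named list mapping cluster id to a 7-rank lineage.
#' @param rep_seqs named character vector mapping cluster id to its
#'   representative sequence.
#' @param out_dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(table, taxonomy, rep_seqs, out_dir) {
  clusters <- rownames(table)
  missing_tax <- setdiff(clusters, names(taxonomy))
  if (length(missing_tax))
    stop("clusters missing from taxonomy: ",
         paste(missing_tax, collapse = ", "))
  missing_seq <- setdiff(clusters, names(rep_seqs))
  if (length(missing_seq))
    stop("clusters missing from rep_seqs: ",
         paste(missing_seq, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(out_dir, "rep_seqs.fasta"),
    counts = file.path(out_dir, "cluster_counts.tsv"),
    tax_wide = file.path(out_dir, "taxonomy_wide.tsv"),
    tax_q2 = file.path(out_dir, "taxonomy.tsv")
  )
  ss <- Biostrings::DNAStringSet(rep_seqs[clusters])
  Biostrings::writeXStringSet(ss, paths[["fasta"]], width = 80L)
  write_feature_table(table, paths[["counts"]])
  lin <- t(vapply(taxonomy[clusters], identity, character(7)))
  wide <- data.frame(`Feature ID` = clusters, lin, check.names = FALSE)
  names(wide)[-1] <- tools::toTitleCase(TAX_RANKS)
  write.table(wide, paths[["tax_wide"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  q2 <- data.frame(
    `Feature ID` = clusters,
    Taxon = vapply(taxonomy[clusters], format_lineage, ""),
    check.names = FALSE)
  write.table(q2, paths[["tax_q2"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (r in seq_along(TAX_RANKS)) {
    collapsed <- collapse_by_rank(table, taxonomy, TAX_RANKS[r])
    p <- file.path(out_dir, paste0("counts_", TAX_RANKS[r], ".tsv"))
    write_feature_table(collapsed, p)
    paths[[paste0("counts_", TAX_RANKS[r])]] <- p
  }
  invisible(paths)
}
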