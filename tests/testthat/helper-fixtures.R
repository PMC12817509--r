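# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# Self-cleaning temporary directory tied to the calling test.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("acl")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw()
  else {
    set.seed(seed)
    draw()
  }
}

# A perfect-quality read list around a sequence.
clean_read <- function(seq, id = "r1", sample = "s1", q = 30L) {
  list(read_id = id, sample_id = sample, seq = seq,
       qual = strrep(intToUtf8(q + 33L), nchar(seq)))
}

reads_df <- function(seqs, sample = "s1", q = 30L) {
  data.frame(read_id = sprintf("%s_r%03d", sample, seq_along(seqs)),
             sample_id = sample, seq = seqs,
             qual = strrep(intToUtf8(q + 33L), nchar(seqs)))
}

write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", reads$qual)), path)
  path
}

# Full synthetic lineage string for quick reference tables.
lineage_string <- function(genus = "Testigenus", species = paste(genus, "sp1"),
                           family = "Testaceae") {
  sprintf("d__Bacteria;p__Testiota;c__Testia;o__Testales;f__%s;g__%s;s__%s",
          family, genus, species)
}

# Small reference data.frame with distinct or shared genera.
tiny_reference <- function(seqs, genus = paste0("G", seq_along(seqs)),
                           species = paste0(genus, " sp", seq_along(seqs))) {
  lin <- t(vapply(seq_along(seqs), function(i)
    parse_lineage(lineage_string(genus[i], species[i])), character(7)))
  colnames(lin) <- TAX_RANKS
  cbind(data.frame(ref_id = paste0("R", seq_along(seqs)), seq = seqs),
        as.data.frame(lin))
}

# Brute-force enumerator for the full taxonomy decision (gap retention,
# per-hit masking, rank-prefix consensus), written as plain loops so it
# can arbitrate the vectorised implementation.
oracle_taxonomy <- function(hits, gap, min_fraction) {
  ord <- order(-hits$bitscore, -hits$pident)
  h <- hits[ord, , drop = FALSE]
  keep <- h$bitscore > h$bitscore[1] - gap
  keep[h$bitscore == h$bitscore[1]] <- TRUE
  h <- h[keep, , drop = FALSE]
  thr <- c(65, 75, 78.5, 82, 86.5, 94.5, 97)
  for (i in seq_len(nrow(h)))
    for (r in 1:7)
      if (h$pident[i] < thr[r]) h[i, TAX_RANKS[r]] <- "unclassified"
  n <- nrow(h)
  for (r in 7:1) {
    pref <- apply(h[, TAX_RANKS[1:r], drop = FALSE], 1, paste,
                  collapse = ";")
    cnt <- table(pref)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1) {
      mp <- vapply(top, function(x) mean(h$pident[pref == x]), numeric(1))
      top <- top[order(-mp, top)]
    }
    if (max(cnt) / n >= min_fraction) {
      parts <- strsplit(top[1], ";", fixed = TRUE)[[1]]
      if (parts[r] != "unclassified")
        return(setNames(c(parts, rep("unclassified", 7 - r)), TAX_RANKS))
    }
  }
  setNames(rep("unclassified", 7), TAX_RANKS)
}

# The implementation's route to the same decision.
pipeline_taxonomy_decision <- function(hits, gap, min_fraction) {
  params <- tax_params(gap = gap, min_fraction = min_fraction)
  ret <- retain_hits(hits, gap)
  for (j in seq_len(nrow(ret)))
    ret[j, TAX_RANKS] <- mask_lineage(unlist(ret[j, TAX_RANKS]),
                                      ret$pident[j], params)
  select_taxonomy(ret, params)
}

# Random hit set for taxonomy oracle tests: up to max_hits hits drawn from
# a pool of n_lineages distinct lineages.
random_hits <- function(n_hits, n_lineages = 5) {
  genera <- paste0("Genus", seq_len(max(1, ceiling(n_lineages / 2))))
  lins <- t(sapply(seq_len(n_lineages), function(i) {
    g <- sample(genera, 1)
    parse_lineage(lineage_string(g, paste(g, "sp", i)))
  }))
  idx <- sample(n_lineages, n_hits, replace = TRUE)
  df <- as.data.frame(lins[idx, , drop = FALSE])
  names(df) <- TAX_RANKS
  df$pident <- round(runif(n_hits, 60, 100), 1)
  df$bitscore <- round(runif(n_hits, 400, 500), 1)
  df$ref_id <- paste0("H", seq_len(n_hits))
  df
}
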