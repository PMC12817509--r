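# Deterministic synthetic-data generation: a small multi-species
# 16S-like reference set with known lineages, mock communities of known
# composition, and long reads with an iid substitution/insertion/
# deletion error process, primers attached and strand randomized. Every
# stage of the pipeline is testable against the resulting ground truth
# without downloading anything.

DNA_BASES <- c("A", "C", "G", "T")

#' Error model for simulated long reads
#'
#' Independent per-base substitution, insertion and deletion
#' probabilities (no homopolymer weighting).
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in
#'   `[0, 0.2]` with a total below 0.5.
#' @param seed RNG seed used by [simulate_run()].
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sub_rate = 0.01, ins_rate = 0.01,
                        del_rate = 0.01, seed = 42L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(all(rates >= 0), all(rates <= 0.2), sum(rates) < 0.5)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a divergent reference set with known lineages
#'
#' One random ancestor sequence; each species is derived by substituting
#' bases at the divergence rate. Lineages share domain..family; genera
#' are spread over `n_genera` groups (set `n_genera < n_species` to test
#' genus-level fallback behaviour).
#'
#' @param n_species number of species.
#' @param length reference length in bases (default 1400, a full-length
#'   16S amplicon).
#' @param divergence per-base substitution rate from the ancestor, in
#'   `(0, 0.3]`.
#' @param seed RNG seed.
#' @param n_genera number of distinct genera (default `n_species`).
#' @return reference data.frame as from [parse_reference_fasta()].
#' @export
make_reference_set <- function(n_species, length = 1400L,
                               divergence = 0.1, seed = 1L,
                               n_genera = n_species) {
  stopifnot(n_species >= 1, divergence > 0, divergence <= 0.3,
            n_genera >= 1, n_genera <= n_species)
  with_local_seed(seed, {
    ancestor <- sample(DNA_BASES, length, replace = TRUE)
    seqs <- vapply(seq_len(n_species), function(i) {
      s <- ancestor
      if (i > 1 || n_species == 1) {
        mut <- runif(length) < divergence
        if (any(mut))
          s[mut] <- vapply(s[mut], function(b)
            sample(setdiff(DNA_BASES, b), 1L), "")
      }
      paste(s, collapse = "")
    }, "")
    genus_of <- rep(seq_len(n_genera), length.out = n_species)
    lin <- data.frame(
      domain = rep("Bacteria", n_species),
      phylum = rep("Simulibacterota", n_species),
      class = rep("Simulibacteria", n_species),
      order = rep("Simulales", n_species),
      family = rep("Simulaceae", n_species),
      genus = paste0("Simulivibrio_", LETTERS[genus_of]),
      species = paste0("Simulivibrio_", LETTERS[genus_of],
                       " species", seq_len(n_species)))
    cbind(data.frame(ref_id = paste0("REF", seq_len(n_species)),
                     seq = seqs), lin)
  })
}

# Apply the iid error process to one template; caller controls the RNG.
mutate_seq <- function(template, noise) {
  bases <- strsplit(template, "")[[1]]
  n <- length(bases)
  u_del <- runif(n) < noise$del_rate
  u_sub <- runif(n) < noise$sub_rate
  u_ins <- runif(n) < noise$ins_rate
  out <- character(0)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    b <- if (u_del[i]) character(0)
    else if (u_sub[i]) sample(setdiff(DNA_BASES, bases[i]), 1L)
    else bases[i]
    if (u_ins[i]) b <- c(b, sample(DNA_BASES, 1L))
    pieces[[i]] <- b
  }
  paste(unlist(pieces), collapse = "")
}

#' Simulate one noisy read from a template
#'
#' Per-base iid substitution/insertion/deletion; qualities are a
#' constant Phred score consistent with the total error rate.
#'
#' @param template DNA string.
#' @param noise a [noise_model()].
#' @param seed optional seed; when `NULL` the current RNG stream is
#'   used (so callers can drive many reads from one seed).
#' @return list with `seq` and `qual`.
#' @export
noisy_read <- function(template, noise, seed = NULL) {
  stopifnot(nzchar(template))
  make <- function() {
    s <- mutate_seq(template, noise)
    total <- noise$sub_rate + noise$ins_rate + noise$del_rate
    q <- if (total <= 0) 40L
    else as.integer(round(-10 * log10(max(total, 1e-4))))
    q <- max(2L, min(q, 93L))
    list(seq = s, qual = strrep(intToUtf8(q + 33L), nchar(s)))
  }
  if (is.null(seed)) make() else with_local_seed(seed, make())
}

#' Mock-community design
#'
#' @param reference reference data.frame (see [make_reference_set()]).
#' @param abundances relative abundances, one per reference row; must
#'   sum to 1.
#' @param n_reads_per_sample reads drawn per sample.
#' @param n_samples number of replicate samples.
#' @param primers [primer_pair()] attached to every template.
#' @return object of class `mock_design`.
#' @export
mock_design <- function(reference, abundances,
                        n_reads_per_sample = 300L, n_samples = 2L,
                        primers = primer_pair()) {
  stopifnot(nrow(reference) == length(abundances),
            abs(sum(abundances) - 1) < 1e-6, n_reads_per_sample >= 1,
            n_samples >= 1)
  structure(list(reference = reference, abundances = abundances,
                 n_reads_per_sample = as.integer(n_reads_per_sample),
                 n_samples = as.integer(n_samples), primers = primers),
            class = "mock_design")
}

#' Simulate a sequencing run of a mock community
#'
#' Per sample, reads are drawn from the species multinomially, the
#' template is `fwd_primer + reference + revcomp(rev_primer)`, the
#' strand is randomized 50/50, and the error process applied. FASTQ
#' files (one per sample), a read-level truth table and the expected
#' community profile are written to `out_dir`.
#'
#' @param design a [mock_design()].
#' @param noise a [noise_model()].
#' @param out_dir output directory (created).
#' @return list with `fastq_dir`, `truth` (data.frame `read_id`,
#'   `sample_id`, `species`, `strand`), `expected`
#'   (a [community_profile()]) and `design`.
#' @export
simulate_run <- function(design, noise, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- design$reference
  templates <- paste0(design$primers$fwd, ref$seq,
                      revcomp(design$primers$rev))
  truth <- with_local_seed(noise$seed, {
    rows <- list()
    for (s in seq_len(design$n_samples)) {
      sample_id <- sprintf("sample_%d", s)
      counts <- as.vector(rmultinom(1, design$n_reads_per_sample,
                                    design$abundances))
      origin <- rep(seq_len(nrow(ref)), counts)
      origin <- sample(origin) # shuffle read order within the sample
      recs <- lapply(seq_along(origin), function(j) {
        rd <- noisy_read(templates[origin[j]], noise)
        minus <- runif(1) < 0.5
        if (minus) rd$seq <- revcomp(rd$seq)
        data.frame(read_id = sprintf("%s_read%04d", sample_id, j),
                   sample_id = sample_id, seq = rd$seq, qual = rd$qual,
                   species = ref$species[origin[j]],
                   strand = if (minus) "-" else "+")
      })
      df <- do.call(rbind, recs)
      fq <- file.path(out_dir, paste0(sample_id, ".fastq"))
      writeLines(as.vector(rbind(paste0("@", df$read_id), df$seq,
                                 "+", df$qual)), fq)
      rows[[s]] <- df[, c("read_id", "sample_id", "species", "strand")]
    }
    do.call(rbind, rows)
  })
  rownames(truth) <- NULL
  expected <- community_profile(
    setNames(design$abundances, ref$species), "expected")
  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(taxon = names(expected),
               relative_abundance = as.numeric(expected)),
    file.path(out_dir, "expected_profile.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  list(fastq_dir = out_dir, truth = truth, expected = expected,
       design = design)
}
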