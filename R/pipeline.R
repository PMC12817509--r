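# Pipeline orchestration: QC -> primer extraction -> within-sample
# clustering -> between-sample merge -> consensus/polish -> taxonomy ->
# final output directory, with per-stage read accounting and a
# machine-readable run log. Rerunning with identical configuration and
# seed reproduces identical outputs.

#' Pipeline configuration
#'
#' @param input_dir directory of per-sample FASTQ files.
#' @param reference reference data.frame, or path to a reference FASTA
#'   with 7-rank taxonomy.
#' @param out_dir output directory.
#' @param qc a [qc_params()].
#' @param primers a [primer_pair()].
#' @param cluster a [cluster_params()].
#' @param polish a [polish_params()].
#' @param tax a [tax_params()].
#' @param hits_path optional precomputed BLAST outfmt-6 hits for the
#'   cluster representatives.
#' @param skip_qc skip the quality/length filter (primer extraction
#'   still runs).
#' @param seed master seed; propagated to clustering, subsampling and
#'   representative construction.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, reference, out_dir,
                            qc = qc_params(), primers = primer_pair(),
                            cluster = cluster_params(),
                            polish = polish_params(),
                            tax = tax_params(), hits_path = NULL,
                            skip_qc = FALSE, seed = 42L) {
  seed <- as.integer(seed)
  cluster$seed <- seed
  polish$seed <- seed
  structure(list(input_dir = input_dir, reference = reference,
                 out_dir = out_dir, qc = qc, primers = primers,
                 cluster = cluster, polish = polish, tax = tax,
                 hits_path = hits_path, skip_qc = isTRUE(skip_qc),
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes all stages in order and writes the final output directory
#' (`final_output/` under `out_dir`: representative FASTA, cluster count
#' table, wide and Qiime2-style taxonomy tables, one collapsed count
#' table per rank) plus a tab-separated run log with per-stage read
#' counters and wall times.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a summary list: `table`, `taxonomy`, `rep_seqs`,
#'   `assignment`, `log`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_rows <- list()
  tick <- function(stage, key, value) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(stage = stage, key = key, value = as.character(value))
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    tick(stage, "seconds", sprintf("%.2f", proc.time()[["elapsed"]] - t0))
    res
  }

  reads_by_sample <- timed("input", read_fastq_dir(config$input_dir))
  n_in <- vapply(reads_by_sample, nrow, integer(1))
  tick("input", "reads", sum(n_in))
  tick("input", "samples", length(reads_by_sample))

  filtered <- timed("qc", {
    if (config$skip_qc) reads_by_sample
    else lapply(reads_by_sample, filter_reads, qc = config$qc)
  })
  n_qc <- vapply(filtered, nrow, integer(1))
  tick("qc", "reads_pass", sum(n_qc))
  tick("qc", "reads_fail", sum(n_in) - sum(n_qc))
  if (sum(n_qc) == 0)
    stop("no reads survived the quality filter")

  extracted <- timed("primer_extraction",
    lapply(filtered, extract_amplicons, primers = config$primers,
           qc = config$qc))
  n_ex <- vapply(extracted, nrow, integer(1))
  tick("primer_extraction", "reads_pass", sum(n_ex))
  tick("primer_extraction", "reads_fail", sum(n_qc) - sum(n_ex))
  if (sum(n_ex) == 0)
    stop("no reads survived primer extraction")

  within <- timed("cluster_within",
    cluster_within_samples(extracted, config$cluster))
  all_reads <- do.call(rbind, c(extracted, make.row.names = FALSE))
  labels <- unlist(unname(within))
  all_reads$unique_cluster <- unname(labels[all_reads$read_id])
  unique_clusters <- split(
    all_reads[!is.na(all_reads$unique_cluster), , drop = FALSE],
    all_reads$unique_cluster[!is.na(all_reads$unique_cluster)])
  tick("cluster_within", "unique_clusters", length(unique_clusters))
  tick("cluster_within", "noise_reads", sum(is.na(all_reads$unique_cluster)))
  if (!length(unique_clusters))
    stop("no clusters found within samples (all reads noise)")

  merged <- timed("cluster_between",
    merge_between_samples(unique_clusters, config$cluster))
  assignment <- merged$assignment
  noise <- all_reads[is.na(all_reads$unique_cluster),
                     c("read_id", "sample_id"), drop = FALSE]
  if (nrow(noise)) {
    noise$unique_cluster <- NA_character_
    noise$shared_cluster <- NA_character_
    assignment <- rbind(assignment, noise)
  }
  rownames(assignment) <- NULL
  tick("cluster_between", "shared_clusters",
       length(unique(stats::na.omit(assignment$shared_cluster))))

  table <- build_cluster_table(assignment,
                               samples = names(reads_by_sample))

  shared_reads <- split(
    assignment[!is.na(assignment$shared_cluster), , drop = FALSE],
    assignment$shared_cluster[!is.na(assignment$shared_cluster)])
  seq_of <- setNames(all_reads$seq, all_reads$read_id)
  rep_seqs <- timed("consensus_polish", {
    out <- vapply(seq_along(shared_reads), function(i) {
      rd <- shared_reads[[i]]
      rd$seq <- unname(seq_of[rd$read_id])
      pp <- config$polish
      pp$seed <- config$polish$seed + i
      cluster_representative(rd, pp)
    }, "")
    setNames(out, names(shared_reads))
  })

  reference <- config$reference
  if (is.character(reference) && length(reference) == 1)
    reference <- parse_reference_fasta(reference)
  taxonomy <- timed("taxonomy",
    classify_clusters(rep_seqs, reference, config$tax,
                      hits_path = config$hits_path))

  final_dir <- file.path(config$out_dir, "final_output")
  paths <- write_outputs(table, taxonomy, rep_seqs, final_dir)
  log <- do.call(rbind, log_rows)
  log_path <- file.path(config$out_dir, "run_log.tsv")
  write.table(log, log_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(table = table, taxonomy = taxonomy,
                 rep_seqs = rep_seqs, assignment = assignment,
                 log = log,
                 paths = c(paths, run_log = log_path)))
}

#' Derive per-sample community profiles from pipeline results
#'
#' Collapses the cluster table at a rank and converts counts to
#' per-sample relative abundances, labelled by the rank's terminal
#' label (e.g. the species name), ready for [evaluate_profiles()].
#'
#' @param table cluster count table.
#' @param taxonomy named list of lineages.
#' @param rank rank name (default `"species"`).
#' @return list of [community_profile()]s, one per sample.
#' @export
profiles_from_table <- function(table, taxonomy, rank = "species") {
  r <- match(rank, TAX_RANKS)
  stopifnot(!is.na(r))
  collapsed <- collapse_by_rank(table, taxonomy, rank)
  label <- vapply(strsplit(rownames(collapsed), ";", fixed = TRUE),
                  function(p) sub("^[dpcofgs]__", "", p[r]), "")
  out <- lapply(colnames(collapsed), function(s) {
    v <- collapsed[, s]
    v <- tapply(v, label, sum)
    v <- v[v > 0]
    community_profile(v, sample_id = s)
  })
  names(out) <- colnames(collapsed)
  out
}
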