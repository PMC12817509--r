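# K-mer profiling, embedding, and the two-stage clustering scheme:
# reads are clustered within each sample ("within samples" mode), then
# up to 100 representatives per unique cluster are pooled and clustered
# again ("between samples" mode). A unique cluster's full read set is
# inherited by the shared cluster that captured at least half of its
# representatives; otherwise the unique cluster becomes a new shared
# cluster. Final shared clusters are renumbered Cluster_0.. by
# descending total read count.

#' Clustering parameters
#'
#' @param k k-mer size for read profiles (default 5; 4^5 = 1024
#'   dimensions, the established choice for long-read 16S profiles).
#' @param select_epsilon cluster-selection distance passed to
#'   [density_cluster()]; higher values merge or grow clusters.
#' @param min_cluster_size minimum reads per cluster (default 10).
#' @param embed_dim embedding dimensionality (default 2).
#' @param embed_neighbors retained for configuration compatibility; the
#'   spectral embedding used here has no neighbourhood-size parameter.
#' @param between_epsilon optional override of `select_epsilon` for the
#'   between-samples mode; defaults to the shared value.
#' @param seed RNG seed for representative subsampling.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(k = 5L, select_epsilon = 0.5,
                           min_cluster_size = 10L, embed_dim = 2L,
                           embed_neighbors = 15L,
                           between_epsilon = NULL, seed = 42L) {
  stopifnot(k >= 1, min_cluster_size >= 2, embed_dim >= 1,
            select_epsilon >= 0)
  structure(list(k = as.integer(k), select_epsilon = select_epsilon,
                 min_cluster_size = as.integer(min_cluster_size),
                 embed_dim = as.integer(embed_dim),
                 embed_neighbors = as.integer(embed_neighbors),
                 between_epsilon = between_epsilon %||% select_epsilon,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' K-mer frequency profile of one sequence
#'
#' Counts all `4^k` k-mers in fixed lexicographic order and normalizes by
#' the total counted k-mers. K-mers containing non-ACGT characters are
#' skipped. No strand collapsing is applied: reads are expected to be
#' oriented upstream by the primer-extraction step.
#'
#' @param seq DNA string with `nchar(seq) >= k`.
#' @param k k-mer size.
#' @return numeric vector of length `4^k` summing to 1.
#' @export
kmer_profile <- function(seq, k = 5L) {
  if (nchar(seq) < k)
    stop("sequence shorter than k (", nchar(seq), " < ", k, ")")
  kmer_profiles(seq, k)[1, ]
}

#' K-mer frequency profiles of many sequences
#'
#' @param seqs character vector of DNA sequences.
#' @param k k-mer size.
#' @return matrix (rows = sequences) of normalized k-mer frequencies.
#' @export
kmer_profiles <- function(seqs, k = 5L) {
  if (any(nchar(seqs) < k))
    stop("all sequences must be at least k bases long")
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("sequence with no countable k-mers (all ambiguous?)")
  m / tot
}

# Cosine distance matrix between profile rows.
cosine_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  x <- x / pmax(nrm, 1e-300)
  d <- 1 - tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Embed k-mer profiles into a low-dimensional space
#'
#' Classical multidimensional scaling (principal coordinates) of the
#' cosine distances between profiles, rescaled so that the root-mean-
#' square point norm is 1. The rescaling makes density-clustering
#' distance parameters comparable across datasets of different
#' divergence.
#'
#' @param profiles profile matrix from [kmer_profiles()].
#' @param embed_dim target dimensionality.
#' @return numeric matrix (rows = sequences, cols = `embed_dim`).
#' @export
embed_profiles <- function(profiles, embed_dim = 2L) {
  n <- nrow(profiles)
  d <- cosine_dist(profiles)
  kdim <- min(embed_dim, n - 1L)
  coords <- suppressWarnings(cmdscale(as.dist(d), k = kdim))
  if (is.null(dim(coords)) || ncol(coords) < embed_dim) {
    pad <- matrix(0, n, embed_dim - NCOL(coords))
    coords <- cbind(coords, pad)
  }
  rms <- sqrt(mean(rowSums(coords^2)))
  if (rms > 1e-12) coords <- coords / rms
  rownames(coords) <- rownames(profiles)
  coords
}

#' Embed and density-cluster a set of k-mer profiles
#'
#' The pipeline contract: (1) embed the profiles into `embed_dim`
#' dimensions preserving neighbourhood structure, (2) hierarchical
#' density-based clustering with cluster-selection distance
#' `select_epsilon` and minimum cluster size `min_cluster_size`. Fewer
#' than `min_cluster_size` profiles yield all-noise. Deterministic.
#'
#' @param profiles profile matrix (rows named by read id).
#' @param params a [cluster_params()].
#' @return named integer vector of labels (`NA` = noise).
#' @export
embed_and_cluster <- function(profiles, params = cluster_params()) {
  n <- nrow(profiles)
  ids <- rownames(profiles)
  if (n < params$min_cluster_size)
    return(setNames(rep(NA_integer_, n), ids))
  coords <- embed_profiles(profiles, params$embed_dim)
  labels <- density_cluster(coords, params$min_cluster_size,
                            params$select_epsilon)
  setNames(labels, ids)
}

#' Randomly pick representative reads for a cluster
#'
#' All reads are returned when the cluster holds fewer than `cap` reads;
#' otherwise a uniform sample of exactly `cap` reads without replacement,
#' reproducible by `seed`.
#'
#' @param cluster_reads reads data.frame.
#' @param cap maximum representatives (default 100).
#' @param seed RNG seed.
#' @return subset of `cluster_reads`.
#' @export
pick_representatives <- function(cluster_reads, cap = 100L, seed = 42L) {
  n <- nrow(cluster_reads)
  if (n == 0) stop("cluster_reads must be non-empty")
  if (n < cap) return(cluster_reads)
  idx <- with_local_seed(seed, sample.int(n, cap))
  out <- cluster_reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster reads independently within each sample
#'
#' @param reads_by_sample named list of reads data.frames (one per
#'   sample), already oriented and trimmed.
#' @param params a [cluster_params()].
#' @return named list mapping sample id to a named vector of unique
#'   cluster ids (`"<sample>::<label>"`) or `NA` for noise.
#' @export
cluster_within_samples <- function(reads_by_sample,
                                   params = cluster_params()) {
  out <- lapply(names(reads_by_sample), function(s) {
    reads <- reads_by_sample[[s]]
    if (!nrow(reads))
      return(setNames(character(0), character(0)))
    profiles <- kmer_profiles(reads$seq, params$k)
    rownames(profiles) <- reads$read_id
    labels <- embed_and_cluster(profiles, params)
    setNames(ifelse(is.na(labels), NA_character_,
                    paste0(s, "::", labels)), names(labels))
  })
  names(out) <- names(reads_by_sample)
  out
}

#' Inheritance decisions for unique clusters
#'
#' Given, for every unique cluster, the shared-mode labels of its
#' representatives (`NA` for representatives labelled noise), decide which
#' shared cluster inherits it: the modal shared label if it holds at
#' least half of the representatives (noise counts in the denominator),
#' otherwise `NA`, meaning the unique cluster becomes a new shared
#' cluster. Ties at exactly one half are broken toward the lower shared
#' label id.
#'
#' @param rep_labels named list mapping unique cluster id to an integer
#'   vector of shared labels (with `NA`s).
#' @return named integer vector: inherited shared label or `NA`.
#' @export
inheritance_decisions <- function(rep_labels) {
  vapply(rep_labels, function(lab) {
    n <- length(lab)
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NA_integer_)
    tab <- table(lab)
    frac <- as.numeric(tab) / n
    best <- max(frac)
    if (best < 0.5) return(NA_integer_)
    cand <- as.integer(names(tab)[frac == best])
    min(cand)
  }, integer(1))
}

#' Merge unique clusters into shared clusters across samples
#'
#' Pools up to 100 representatives per unique cluster, clusters the pool
#' in between-samples mode, and applies the at-least-half inheritance
#' rule (see [inheritance_decisions()]). Unique clusters not inherited by
#' any shared cluster are added as new shared clusters. Shared clusters
#' are renumbered `Cluster_0..Cluster_{n-1}` by descending total reads.
#'
#' @param unique_clusters named list mapping unique cluster id to its
#'   reads data.frame (noise reads excluded upstream).
#' @param params a [cluster_params()].
#' @param rep_cap representatives pooled per unique cluster (default 100).
#' @return list with `assignment` (data.frame `read_id`, `sample_id`,
#'   `unique_cluster`, `shared_cluster`), `decisions`, and `rep_labels`.
#' @export
merge_between_samples <- function(unique_clusters,
                                  params = cluster_params(),
                                  rep_cap = 100L) {
  stopifnot(length(unique_clusters) > 0)
  uids <- names(unique_clusters)
  reps <- lapply(seq_along(uids), function(i)
    pick_representatives(unique_clusters[[i]], rep_cap,
                         seed = params$seed + i))
  pool_seqs <- unlist(lapply(reps, function(r) r$seq), use.names = FALSE)
  pool_uid <- rep(uids, vapply(reps, nrow, integer(1)))
  profiles <- kmer_profiles(pool_seqs, params$k)
  rownames(profiles) <- sprintf("rep_%06d", seq_along(pool_seqs))
  between <- cluster_params(
    k = params$k, select_epsilon = params$between_epsilon,
    min_cluster_size = params$min_cluster_size,
    embed_dim = params$embed_dim,
    embed_neighbors = params$embed_neighbors, seed = params$seed)
  labels <- embed_and_cluster(profiles, between)
  rep_labels <- split(unname(labels), factor(pool_uid, levels = uids))
  decisions <- inheritance_decisions(rep_labels)
  # map every unique cluster to a shared group: inherited ones share the
  # shared-mode label; the rest get singleton groups
  group <- ifelse(is.na(decisions),
                  paste0("new::", uids),
                  paste0("shared::", decisions))
  names(group) <- uids
  sizes <- vapply(unique_clusters, nrow, integer(1))
  group_tot <- tapply(sizes, group, sum)
  ord <- order(-group_tot, names(group_tot))
  shared_name <- setNames(sprintf("Cluster_%d", seq_along(ord) - 1L),
                          names(group_tot)[ord])
  assignment <- do.call(rbind, lapply(uids, function(u) {
    r <- unique_clusters[[u]]
    data.frame(read_id = r$read_id, sample_id = r$sample_id,
               unique_cluster = u,
               shared_cluster = unname(shared_name[group[u]]))
  }))
  rownames(assignment) <- NULL
  list(assignment = assignment, decisions = decisions,
       rep_labels = rep_labels)
}

#' Build the cluster count table from an assignment
#'
#' @param assign assignment data.frame with `read_id`, `sample_id`,
#'   `shared_cluster` (`NA` = noise).
#' @param samples optional vector of sample ids fixing column order.
#' @return integer matrix: rows shared clusters, columns samples; the
#'   total equals the number of non-noise reads.
#' @export
build_cluster_table <- function(assign, samples = NULL) {
  samples <- samples %||% sort(unique(assign$sample_id))
  keep <- !is.na(assign$shared_cluster)
  a <- assign[keep, , drop = FALSE]
  clusters <- unique(a$shared_cluster)
  # order Cluster_0, Cluster_1, ... numerically when possible
  num <- suppressWarnings(as.integer(sub("^Cluster_", "", clusters)))
  clusters <- clusters[order(ifelse(is.na(num), .Machine$integer.max, num),
                             clusters)]
  tab <- table(factor(a$shared_cluster, levels = clusters),
               factor(a$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = length(clusters),
              dimnames = list(clusters, samples))
  m
}
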