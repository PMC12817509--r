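# Taxonomy assignment for shared-cluster representatives.
#
# Hits (external BLAST outfmt-6 or the built-in pairwise search) are
# sorted by bit score and percent identity, a bit-score gap keeps only
# hits within `gap` of the best, each retained hit's lineage is masked
# per rank by percent-identity floors, and the cluster lineage is the
# most common lineage prefix holding at least `min_fraction` of the
# retained hits, walked from species upward.

#' Taxonomy-assignment parameters
#'
#' @param gap bit-score tolerance below the best hit (default 1): hits
#'   scoring at or below `best - gap` are discarded (the best hit itself
#'   is always retained).
#' @param min_fraction fraction of retained hits the modal lineage
#'   prefix must reach (default 0.6).
#' @param masking if `FALSE`, per-rank identity masking is skipped (gap
#'   filtering and fraction selection still apply).
#' @param thresholds per-rank percent-identity floors; defaults
#'   97 (species), 94.5 (genus), 86.5 (family), 82 (order), 78.5
#'   (class), 75 (phylum), 65 (domain).
#' @return object of class `tax_params`.
#' @export
tax_params <- function(gap = 1, min_fraction = 0.6, masking = TRUE,
                       thresholds = c(domain = 65, phylum = 75,
                                      class = 78.5, order = 82,
                                      family = 86.5, genus = 94.5,
                                      species = 97)) {
  stopifnot(gap >= 0, min_fraction > 0, min_fraction <= 1,
            all(TAX_RANKS %in% names(thresholds)))
  thresholds <- thresholds[TAX_RANKS]
  if (any(diff(thresholds) <= 0))
    stop("thresholds must strictly increase from domain to species")
  structure(list(gap = gap, min_fraction = min_fraction,
                 masking = isTRUE(masking), thresholds = thresholds),
            class = "tax_params")
}

#' Retain hits within the bit-score gap of the best hit
#'
#' Hits are sorted descending by (bit score, percent identity); a hit is
#' retained iff its bit score exceeds `best - gap`. Hits tied with the
#' best bit score are always retained (a literal reading at `gap = 0`
#' would discard the best hit itself).
#'
#' @param hits data.frame with at least `bitscore` and `pident`.
#' @param gap bit-score gap.
#' @return the retained, sorted subset (always >= 1 row).
#' @export
retain_hits <- function(hits, gap = 1) {
  if (!nrow(hits)) stop("retain_hits: empty hit set")
  ord <- order(-hits$bitscore, -hits$pident)
  sorted <- hits[ord, , drop = FALSE]
  keep <- sorted$bitscore > sorted$bitscore[1] - gap
  keep[sorted$bitscore == sorted$bitscore[1]] <- TRUE
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask lineage ranks below their percent-identity floors
#'
#' Each rank label is kept iff `pident >= thresholds[rank]`; because the
#' floors decrease from species to domain, the output automatically
#' satisfies masking monotonicity (everything below an unclassified rank
#' is unclassified).
#'
#' @param lineage named character vector of length 7.
#' @param pident percent identity of the hit, in `[0, 100]`.
#' @param params a [tax_params()]; with `masking = FALSE` the lineage is
#'   returned unchanged.
#' @return masked lineage.
#' @export
mask_lineage <- function(lineage, pident, params = tax_params()) {
  if (!params$masking) return(lineage)
  out <- lineage
  out[pident < params$thresholds[TAX_RANKS]] <- "unclassified"
  setNames(out, TAX_RANKS)
}

#' Select a consensus lineage from retained (masked) hits
#'
#' Walks ranks from species upward. At rank r the frequency of each
#' distinct lineage prefix (domain..r) among the hits is computed; if the
#' modal prefix reaches `min_fraction` of the hits and its label at r is
#' not "unclassified", that prefix is returned, completed with
#' "unclassified" below r. Ties between equally frequent prefixes are
#' broken by higher mean percent identity, then lexicographically. If no
#' rank qualifies, the all-"unclassified" lineage is returned.
#'
#' @param retained data.frame with the 7 rank columns (already masked)
#'   and `pident`.
#' @param params a [tax_params()].
#' @return named character vector of length 7.
#' @export
select_taxonomy <- function(retained, params = tax_params()) {
  stopifnot(nrow(retained) > 0)
  n <- nrow(retained)
  for (r in 7:1) {
    prefix <- do.call(paste, c(unname(retained[TAX_RANKS[seq_len(r)]]),
                               sep = ";"))
    tab <- table(prefix)
    frac <- as.numeric(tab) / n
    best <- max(frac)
    if (best < params$min_fraction) next
    cand <- names(tab)[frac == best]
    if (length(cand) > 1) {
      mp <- vapply(cand, function(p) mean(retained$pident[prefix == p]),
                   numeric(1))
      cand <- cand[order(-mp, cand)]
    }
    labs <- strsplit(cand[1], ";", fixed = TRUE)[[1]]
    if (labs[r] == "unclassified") next
    return(setNames(c(labs, rep("unclassified", 7 - r)), TAX_RANKS))
  }
  setNames(rep("unclassified", 7), TAX_RANKS)
}

# Built-in pairwise search: align a representative against every
# reference, compute percent identity and a score-proportional bit-score
# surrogate. Exists so the pipeline runs without an external BLAST; when
# an external outfmt-6 file is supplied it is authoritative.
builtin_search <- function(query, reference, max_hits = 50L,
                           band = 120L) {
  hits <- lapply(seq_len(nrow(reference)), function(i) {
    a <- .overlap_identity_cpp(reference$seq[i], query, band = band)
    if (!isTRUE(a$ok) || a$aln_len == 0) return(NULL)
    data.frame(ref_id = reference$ref_id[i],
               pident = 100 * a$matches / a$aln_len,
               bitscore = a$score / 2)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || !nrow(hits)) return(NULL)
  hits <- hits[order(-hits$bitscore, -hits$pident), , drop = FALSE]
  head(hits, max_hits)
}

# Attach the 7 rank columns of `reference` to a hits data.frame keyed by
# ref id.
join_lineages <- function(hits, reference, id_col = "ref_id") {
  idx <- match(hits[[id_col]], reference$ref_id)
  if (anyNA(idx))
    stop("hits reference id(s) absent from reference: ",
         paste(unique(hits[[id_col]][is.na(idx)]), collapse = ", "))
  cbind(hits, reference[idx, TAX_RANKS, drop = FALSE],
        row.names = NULL)
}

#' Assign a masked 7-rank lineage to every cluster
#'
#' Obtains up to 50 hits per cluster — from a precomputed BLAST
#' outfmt-6 file when `hits_path` is given, else from the built-in
#' pairwise search against `reference` — then applies
#' [retain_hits()], per-hit [mask_lineage()] and [select_taxonomy()].
#' Clusters with no hits get the all-"unclassified" lineage.
#'
#' @param rep_seqs named character vector: cluster id -> representative.
#' @param reference reference data.frame from [parse_reference_fasta()]
#'   (needed for lineages even with `hits_path`).
#' @param params a [tax_params()].
#' @param hits_path optional path to BLAST tabular hits (query ids must
#'   be the cluster ids).
#' @return named list: cluster id -> lineage (length-7 character).
#' @export
classify_clusters <- function(rep_seqs, reference,
                              params = tax_params(), hits_path = NULL) {
  if (is.character(reference) && length(reference) == 1)
    reference <- parse_reference_fasta(reference)
  if (!nrow(reference)) stop("reference is empty")
  ext_hits <- if (!is.null(hits_path)) parse_blast_tabular(hits_path)
  unclassified <- setNames(rep("unclassified", 7), TAX_RANKS)
  out <- lapply(names(rep_seqs), function(cl) {
    hits <- if (!is.null(ext_hits)) {
      h <- ext_hits[[cl]]
      if (!is.null(h) && nrow(h)) {
        h$ref_id <- h$sseqid
        h
      }
    } else {
      builtin_search(rep_seqs[[cl]], reference)
    }
    if (is.null(hits) || !nrow(hits)) return(unclassified)
    hits <- join_lineages(hits, reference)
    retained <- retain_hits(hits, params$gap)
    for (i in seq_len(nrow(retained)))
      retained[i, TAX_RANKS] <- mask_lineage(
        unlist(retained[i, TAX_RANKS]), retained$pident[i], params)
    select_taxonomy(retained, params)
  })
  names(out) <- names(rep_seqs)
  out
}

#' Collapse a cluster count table to a taxonomy rank
#'
#' Row labels become serialized lineage prefixes down to `rank`
#' (including "unclassified" bins); counts of clusters sharing a prefix
#' are summed, so the grand total is preserved.
#'
#' @param table integer feature table (rows = cluster ids).
#' @param taxonomy named list: cluster id -> lineage.
#' @param rank rank name (see [TAX_RANKS]) or index 1-7.
#' @return integer matrix with lineage-prefix row names.
#' @export
collapse_by_rank <- function(table, taxonomy, rank) {
  if (is.character(rank)) rank <- match(rank, TAX_RANKS)
  stopifnot(!is.na(rank), rank >= 1, rank <= 7)
  clusters <- rownames(table)
  missing <- setdiff(clusters, names(taxonomy))
  if (length(missing))
    stop("clusters without lineage: ", paste(missing, collapse = ", "))
  labels <- vapply(taxonomy[clusters], format_lineage, "", upto = rank)
  m <- rowsum(table, group = labels, reorder = TRUE)
  storage.mode(m) <- "integer"
  m
}
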