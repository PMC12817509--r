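# Mock-community evaluation: observed/expected taxa ratio (OET),
# taxonomy accuracy rate (TAR), taxonomy detection rate (TDR),
# Bray-Curtis distance to a theoretical profile, and observed-vs-
# expected abundance regression, with the filtering policies used for
# community standards (per-sample relative-abundance floor and a
# minimum number of samples a taxon must appear in).

#' Construct a community profile
#'
#' @param abundances named non-negative numeric vector
#'   (taxon -> abundance); normalized to sum to 1.
#' @param sample_id sample identifier.
#' @return object of class `community_profile` (named numeric vector with
#'   a `sample_id` attribute).
#' @export
community_profile <- function(abundances, sample_id = "sample") {
  stopifnot(!is.null(names(abundances)), all(abundances >= 0))
  if (anyDuplicated(names(abundances)))
    stop("duplicate taxon labels in profile")
  tot <- sum(abundances)
  if (tot <= 0) stop("profile sums to zero")
  structure(abundances / tot, sample_id = sample_id,
            class = "community_profile")
}

#' Filter observed profiles before metric calculation
#'
#' Drops, per sample, taxa below `min_relab`, then drops taxa present in
#' fewer than `min_samples` samples (presence evaluated after the
#' abundance floor). No renormalization is applied, preserving absolute
#' comparison semantics. The gut-standard policy is `min_relab = 0,
#' min_samples = 2`; the DNA-standard policy is `min_relab = 0.01,
#' min_samples = 2`.
#'
#' @param profiles list of [community_profile()]s.
#' @param min_relab per-sample relative-abundance floor.
#' @param min_samples minimum samples a taxon must be seen in.
#' @return list of filtered profiles (plain named numeric vectors).
#' @export
filter_observed <- function(profiles, min_relab = 0, min_samples = 2L) {
  stopifnot(length(profiles) > 0)
  kept <- lapply(profiles, function(p) {
    v <- unclass(p)
    attributes(v) <- list(names = names(p))
    v[v > 0 & v >= min_relab]
  })
  presence <- table(unlist(lapply(kept, names)))
  good <- names(presence)[presence >= min_samples]
  out <- lapply(seq_along(kept), function(i) {
    v <- kept[[i]][names(kept[[i]]) %in% good]
    attr(v, "sample_id") <- attr(profiles[[i]], "sample_id")
    v
  })
  names(out) <- names(profiles)
  out
}

#' Observed/expected taxa metrics
#'
#' OET = |observed| / |expected|; TAR = |observed & expected| /
#' |observed| (fraction of observed taxa that were expected); TDR =
#' |observed & expected| / |expected| (fraction of expected taxa that
#' are observed). An empty observed set yields TAR 0 with
#' `tar_defined = FALSE` rather than NaN.
#'
#' @param observed character vector (or set) of observed taxa.
#' @param expected character vector of expected taxa (non-empty).
#' @return list with `oet`, `tar`, `tdr`, `tar_defined`.
#' @export
taxa_metrics <- function(observed, expected) {
  observed <- unique(as.character(observed))
  expected <- unique(as.character(expected))
  if (!length(expected)) stop("expected taxa set is empty")
  tp <- length(intersect(observed, expected))
  if (!length(observed)) {
    warning("empty observed set: TAR undefined, reported as 0")
    return(list(oet = 0, tar = 0, tdr = 0, tar_defined = FALSE))
  }
  list(oet = length(observed) / length(expected),
       tar = tp / length(observed),
       tdr = tp / length(expected),
       tar_defined = TRUE)
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum(|p - q|) / sum(p + q)` over the union of taxa with zero fill.
#'
#' @param p,q named numeric abundance vectors.
#' @return distance in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  taxa <- union(names(p), names(q))
  pv <- setNames(rep(0, length(taxa)), taxa)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  denom <- sum(pv + qv)
  if (denom <= 0) stop("both profiles are all-zero")
  sum(abs(pv - qv)) / denom
}

#' Regression of observed on expected relative abundances
#'
#' Ordinary least squares over the taxon union (zero-filled); returns
#' the slope-test p-value and r-squared.
#'
#' @param observed,expected named numeric abundance vectors.
#' @return list with `p_value` and `r_squared`.
#' @export
abundance_regression <- function(observed, expected) {
  taxa <- union(names(observed), names(expected))
  if (length(taxa) < 3) stop("need at least 3 taxa for regression")
  ov <- setNames(rep(0, length(taxa)), taxa)
  ev <- ov
  ov[names(observed)] <- observed
  ev[names(expected)] <- expected
  if (var(ev) == 0) stop("zero variance in expected abundances")
  fit <- lm(ov ~ ev)
  # a perfect fit (observed == expected) is a legitimate input; silence
  # summary.lm's reliability warning for that case
  s <- suppressWarnings(summary(fit))
  list(p_value = unname(s$coefficients[2, 4]),
       r_squared = unname(s$r.squared))
}

#' Evaluate observed profiles against a theoretical profile
#'
#' Applies [filter_observed()] and then computes OET/TAR/TDR,
#' Bray-Curtis distance and the abundance regression per sample.
#'
#' @param profiles list of observed [community_profile()]s.
#' @param expected the theoretical [community_profile()].
#' @param min_relab,min_samples filtering policy (see
#'   [filter_observed()]).
#' @param rename optional named character vector harmonizing observed
#'   taxon labels (`old = new`); collisions after renaming are an error.
#' @return data.frame with one row per sample: `sample`, `oet`, `tar`,
#'   `tdr`, `bc`, `p_value`, `r_squared`.
#' @export
evaluate_profiles <- function(profiles, expected, min_relab = 0,
                              min_samples = 1L, rename = NULL) {
  if (!is.null(rename)) {
    profiles <- lapply(profiles, function(p) {
      nm <- names(p)
      hit <- nm %in% names(rename)
      nm[hit] <- rename[nm[hit]]
      if (anyDuplicated(nm))
        stop("taxon label collision after harmonization: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
      setNames(unclass(p), nm)
    })
  }
  filtered <- filter_observed(profiles, min_relab, min_samples)
  rows <- lapply(seq_along(filtered), function(i) {
    obs <- filtered[[i]]
    m <- taxa_metrics(names(obs), names(expected))
    reg <- tryCatch(abundance_regression(obs, unclass(expected)),
                    error = function(e) list(p_value = NA_real_,
                                             r_squared = NA_real_))
    data.frame(
      sample = attr(obs, "sample_id") %||% names(filtered)[i] %||%
        as.character(i),
      oet = m$oet, tar = m$tar, tdr = m$tdr,
      bc = bray_curtis(obs, unclass(expected)),
      p_value = reg$p_value, r_squared = reg$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
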