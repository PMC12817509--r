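# Hierarchical density-based clustering with a cluster-selection distance.
#
# This is the HDBSCAN family of algorithms: mutual-reachability distances
# (core distance = distance to the min_samples-th neighbour), a
# single-linkage hierarchy, condensation of that hierarchy with a minimum
# cluster size, excess-of-mass cluster selection, and a selection-epsilon
# rule that merges any selected cluster born below `select_epsilon` into
# its first ancestor born at or above it. A single cluster (the root) may
# be selected, so unimodal data yields one cluster rather than all noise.
# Everything is deterministic.

# Lambda = 1/height, capped so that zero heights (duplicated points) stay
# finite.
.LAMBDA_MAX <- 1e12

.lambda <- function(h) ifelse(h <= 1e-12, .LAMBDA_MAX, 1 / h)

#' Density-based clustering of embedded points
#'
#' @param coords numeric matrix of embedded coordinates (rows = points).
#' @param min_cluster_size smallest group reported as a cluster; smaller
#'   groups and unattached points are noise.
#' @param select_epsilon cluster-selection distance: selected clusters
#'   that split off below this distance are merged into their enclosing
#'   cluster. Higher values merge or grow clusters, never split them.
#' @param min_samples neighbourhood size for the core distance; defaults
#'   to `min_cluster_size`.
#' @return integer vector of cluster labels (`1..k`), `NA` for noise.
#' @export
density_cluster <- function(coords, min_cluster_size = 10L,
                            select_epsilon = 0.5,
                            min_samples = min_cluster_size) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < max(2L, min_cluster_size)) return(rep(NA_integer_, n))
  d <- as.matrix(dist(coords))
  k <- min(min_samples, n - 1L)
  core <- apply(d, 1L, function(r) sort(r, partial = k + 1L)[k + 1L])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- hclust(as.dist(mr), method = "single")
  condensed_tree_labels(hc, n, min_cluster_size, select_epsilon)
}

# Build the condensed tree from a single-linkage hclust object, run
# excess-of-mass selection with the epsilon rule, and return labels.
condensed_tree_labels <- function(hc, n, mcs, eps) {
  merges <- hc$merge
  heights <- hc$height
  nm <- n - 1L

  # leaves under each internal node
  leafset <- vector("list", nm)
  sizes <- integer(nm)
  for (i in seq_len(nm)) {
    kids <- merges[i, ]
    mem <- integer(0)
    for (kk in kids)
      mem <- c(mem, if (kk < 0) -kk else leafset[[kk]])
    leafset[[i]] <- mem
    sizes[i] <- length(mem)
  }
  node_size <- function(kk) if (kk < 0) 1L else sizes[kk]

  # condensed clusters (vector-of-attributes representation)
  birth_h <- Inf           # root
  birth_lambda <- 0
  parent <- 0L
  node <- nm               # merge index whose subtree is the membership
  fall_sum <- 0            # sum of lambda_fallout * count
  fall_cnt <- 0L
  children <- list(integer(0))
  n_cl <- 1L

  new_cluster <- function(p, h, nd) {
    n_cl <<- n_cl + 1L
    birth_h[n_cl] <<- h
    birth_lambda[n_cl] <<- .lambda(h)
    parent[n_cl] <<- p
    node[n_cl] <<- nd
    fall_sum[n_cl] <<- 0
    fall_cnt[n_cl] <<- 0L
    children[[n_cl]] <<- integer(0)
    children[[p]] <<- c(children[[p]], n_cl)
    n_cl
  }
  fall_out <- function(cl, cnt, h) {
    fall_sum[cl] <<- fall_sum[cl] + cnt * .lambda(h)
    fall_cnt[cl] <<- fall_cnt[cl] + cnt
  }

  cl_of <- integer(nm)     # merge node -> condensed cluster (0 = stripped)
  cl_of[nm] <- 1L
  for (i in rev(seq_len(nm))) {
    cl <- cl_of[i]
    if (cl == 0L) next
    kids <- merges[i, ]
    s <- vapply(kids, node_size, integer(1))
    h <- heights[i]
    big <- s >= mcs
    if (all(big)) {
      # true split: current points all leave cl; two new clusters are born
      fall_out(cl, sum(s), h)
      for (j in 1:2) cl_of[kids[j]] <- new_cluster(cl, h, kids[j])
    } else if (any(big)) {
      # the small side is stripped as it falls out of the live cluster
      fall_out(cl, sum(s[!big]), h)
      keep <- kids[big]
      if (keep > 0) cl_of[keep] <- cl
      else fall_out(cl, 1L, h)   # unreachable (leaf >= mcs needs mcs <= 1)
    } else {
      fall_out(cl, sum(s), h)
    }
  }

  # stability and excess-of-mass selection (children have larger ids, so a
  # reverse sweep is bottom-up)
  stability <- fall_sum - birth_lambda * fall_cnt
  sel_stab <- numeric(n_cl)
  selected <- logical(n_cl)
  for (cl in rev(seq_len(n_cl))) {
    ch <- children[[cl]]
    if (!length(ch)) {
      selected[cl] <- TRUE
      sel_stab[cl] <- stability[cl]
    } else {
      cs <- sum(sel_stab[ch])
      if (stability[cl] >= cs) {
        selected[cl] <- TRUE
        sel_stab[cl] <- stability[cl]
      } else {
        sel_stab[cl] <- cs
      }
    }
  }
  # topmost selected clusters form the flat selection
  flat <- integer(0)
  stack <- 1L
  while (length(stack)) {
    cl <- stack[1]; stack <- stack[-1]
    if (selected[cl]) flat <- c(flat, cl)
    else stack <- c(stack, children[[cl]])
  }

  # epsilon rule: clusters born below eps climb to the first ancestor born
  # at or above it (the root, born at Inf, always qualifies)
  if (eps > 0 && length(flat)) {
    flat <- unique(vapply(flat, function(cl) {
      while (birth_h[cl] < eps && parent[cl] != 0L) cl <- parent[cl]
      cl
    }, integer(1)))
    # drop clusters nested under another selected cluster
    is_desc <- vapply(flat, function(cl) {
      p <- parent[cl]
      while (p != 0L) {
        if (p %in% flat) return(TRUE)
        p <- parent[p]
      }
      FALSE
    }, logical(1))
    flat <- flat[!is_desc]
  }

  labels <- rep(NA_integer_, n)
  if (length(flat)) {
    members <- lapply(flat, function(cl) leafset[[node[cl]]])
    ord <- order(vapply(members, min, integer(1)))
    for (j in seq_along(ord))
      labels[members[[ord[j]]]] <- j
  }
  labels
}
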