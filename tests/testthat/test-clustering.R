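# Two-stage clustering scheme: embed-and-cluster, representative
# subsampling, the at-least-half inheritance rule, and count tables.

test_that("reads from two divergent species form two pure clusters", {
  ref <- make_reference_set(2, 900, divergence = 0.12, seed = 31)
  noise <- noise_model(0.01, 0.01, 0.01)
  set.seed(32)
  origin <- rep(1:2, each = 100)
  seqs <- vapply(origin, function(i) noisy_read(ref$seq[i], noise)$seq, "")
  prof <- kmer_profiles(seqs, 5)
  rownames(prof) <- sprintf("r%03d", seq_along(seqs))
  lab <- embed_and_cluster(prof, cluster_params())
  expect_equal(length(unique(na.omit(lab))), 2L)
  for (cl in unique(na.omit(lab))) {
    purity <- max(table(origin[which(lab == cl)])) / sum(lab == cl, na.rm = TRUE)
    expect_gte(purity, 0.95)
  }
})

test_that("identical reads give one cluster and tiny inputs only noise", {
  prof <- kmer_profiles(rep(strrep("ACGGTTCA", 40), 50), 5)
  rownames(prof) <- sprintf("r%02d", 1:50)
  lab <- embed_and_cluster(prof, cluster_params())
  expect_equal(unname(unique(lab)), 1L)
  expect_equal(sum(is.na(lab)), 0L)

  small <- kmer_profiles(replicate(5, random_dna(300)), 5)
  rownames(small) <- paste0("s", 1:5)
  expect_true(all(is.na(embed_and_cluster(small, cluster_params()))))
})

test_that("representative picking honours the cap and the seed", {
  rds <- reads_df(replicate(99, random_dna(50)))
  expect_equal(nrow(pick_representatives(rds, cap = 100, seed = 1)), 99L)
  big <- reads_df(replicate(250, random_dna(50)))
  got <- pick_representatives(big, cap = 100, seed = 1)
  expect_equal(nrow(got), 100L)
  expect_equal(length(unique(got$read_id)), 100L)
  expect_identical(got, pick_representatives(big, cap = 100, seed = 1))
  expect_false(identical(got$read_id,
                         pick_representatives(big, cap = 100, seed = 2)$read_id))
})

test_that("inheritance rule: majority, plurality-below-half, exact half", {
  # 60 of 100 representatives land in shared cluster 3
  expect_equal(unname(inheritance_decisions(
    list(u = rep(c(3L, 7L), c(60, 40))))), 3L)
  # 40/35/25 split: no shared cluster reaches half -> new cluster
  expect_true(is.na(inheritance_decisions(
    list(u = rep(c(1L, 2L, 3L), c(40, 35, 25))))))
  # exactly half inherits ("at least half"), noise in the denominator
  expect_equal(unname(inheritance_decisions(
    list(u = c(rep(2L, 50), rep(NA, 50))))), 2L)
})

test_that("inheritance decisions match brute-force recomputation", {
  oracle <- function(lab) {
    n <- length(lab)
    shared <- sort(unique(lab[!is.na(lab)]))
    best_f <- -1
    best_s <- NA_integer_
    for (s in shared) {
      f <- sum(!is.na(lab) & lab == s) / n
      if (f > best_f) {
        best_f <- f
        best_s <- s
      } # ties keep the lower label (shared is sorted ascending)
    }
    if (best_f >= 0.5) best_s else NA_integer_
  }
  set.seed(33)
  for (i in 1:500) {
    n_unique <- sample(1:10, 1)
    labs <- lapply(seq_len(n_unique), function(j) {
      nrep <- sample(2:20, 1)
      v <- sample(c(NA_integer_, 1:4), nrep, replace = TRUE)
      # exercise the exact-half boundary often
      if (runif(1) < 0.3) v[seq_len(nrep %/% 2)] <- 1L
      v
    })
    names(labs) <- paste0("u", seq_len(n_unique))
    got <- inheritance_decisions(labs)
    want <- vapply(labs, oracle, integer(1))
    expect_identical(got, want)
  }
})

test_that("within-sample clustering namespaces clusters by sample", {
  ref <- make_reference_set(2, 800, divergence = 0.12, seed = 34)
  noise <- noise_model(0.01, 0.005, 0.005)
  set.seed(35)
  mk <- function(sample) {
    origin <- rep(1:2, each = 40)
    seqs <- vapply(origin, function(i) noisy_read(ref$seq[i], noise)$seq, "")
    reads_df(seqs, sample = sample)
  }
  by_sample <- list(sA = mk("sA"), sB = mk("sB"))
  within <- cluster_within_samples(by_sample, cluster_params())
  uniq <- unique(na.omit(unlist(within)))
  expect_equal(length(uniq), 4L)
  expect_true(all(grepl("^sA::|^sB::", uniq)))
  # identical input and seed reproduce the labelling
  expect_identical(within, cluster_within_samples(by_sample, cluster_params()))

  tiny <- list(sC = reads_df(replicate(4, random_dna(300)), "sC"))
  expect_true(all(is.na(cluster_within_samples(tiny, cluster_params())$sC)))
})

test_that("between-sample merge inherits full read sets and renumbers", {
  ref <- make_reference_set(2, 800, divergence = 0.12, seed = 36)
  noise <- noise_model(0.01, 0.005, 0.005)
  set.seed(37)
  mk <- function(sample, n1, n2) {
    origin <- rep(1:2, c(n1, n2))
    seqs <- vapply(origin, function(i) noisy_read(ref$seq[i], noise)$seq, "")
    cbind(reads_df(seqs, sample = sample), origin = origin)
  }
  a <- mk("sA", 40, 30)
  b <- mk("sB", 35, 25)
  uc <- list(`sA::1` = a[a$origin == 1, ], `sA::2` = a[a$origin == 2, ],
             `sB::1` = b[b$origin == 1, ], `sB::2` = b[b$origin == 2, ])
  merged <- merge_between_samples(uc, cluster_params())
  asg <- merged$assignment
  # every read assigned to exactly one shared cluster
  expect_equal(nrow(asg), 130L)
  expect_equal(anyDuplicated(asg$read_id), 0L)
  shared <- sort(unique(asg$shared_cluster))
  expect_equal(shared, c("Cluster_0", "Cluster_1"))
  # same-species unique clusters from both samples merged together
  sp1 <- asg$shared_cluster[asg$unique_cluster %in% c("sA::1", "sB::1")]
  expect_equal(length(unique(sp1)), 1L)
  # Cluster_0 is the larger shared cluster
  expect_gte(sum(asg$shared_cluster == "Cluster_0"),
             sum(asg$shared_cluster == "Cluster_1"))
})

test_that("cluster tables count non-noise reads per sample", {
  asg <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    sample_id = rep(c("s1", "s2"), 50),
    unique_cluster = "u",
    shared_cluster = c(rep("Cluster_0", 90), rep(NA, 10)))
  tab <- build_cluster_table(asg)
  expect_equal(sum(tab), 90L)
  expect_equal(dim(tab), c(1L, 2L))
  expect_true(all(tab[1, ] > 0))

  one <- data.frame(read_id = sprintf("r%03d", 1:100), sample_id = "s1",
                    unique_cluster = "u", shared_cluster = "Cluster_0")
  expect_equal(unname(build_cluster_table(one)[1, 1]), 100L)
})
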