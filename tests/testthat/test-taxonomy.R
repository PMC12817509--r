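mk_hits <- function(bitscores, pidents = rep(99, length(bitscores))) {
  lin <- t(replicate(length(bitscores),
                     parse_lineage(lineage_string("Gx", "Gx sp1"))))
  colnames(lin) <- TAX_RANKS
  cbind(data.frame(bitscore = bitscores, pident = pidents),
        as.data.frame(lin))
}

test_that("bit-score gap retention keeps hits above best minus gap", {
  got <- retain_hits(mk_hits(c(500, 499.5, 499.0)), gap = 1)
  expect_equal(got$bitscore, c(500, 499.5))   # 499.0 <= 499 is discarded
  expect_equal(nrow(retain_hits(mk_hits(500), gap = 1)), 1L)
  # gap 0: the literal rule would discard everything; best hits survive
  got0 <- retain_hits(mk_hits(c(500, 500, 498)), gap = 0)
  expect_equal(got0$bitscore, c(500, 500))
  # sorting is by bitscore then pident
  got2 <- retain_hits(mk_hits(c(500, 500), c(97, 99)), gap = 5)
  expect_equal(got2$pident, c(99, 97))
})

test_that("per-rank identity masking matches the threshold table at boundaries", {
  lin <- parse_lineage(lineage_string("Gx", "Gx sp1"))
  deepest_kept <- function(pident) {
    m <- mask_lineage(lin, pident, tax_params())
    kept <- which(m != "unclassified")
    if (!length(kept)) 0L else max(kept)
  }
  # pident -> deepest retained rank index (7 species ... 1 domain, 0 none)
  cases <- c("100" = 7, "97" = 7, "96.9" = 6, "94.5" = 6, "94.4" = 5,
             "86.5" = 5, "82" = 4, "78.5" = 3, "75" = 2, "65" = 1,
             "64.9" = 0)
  for (p in names(cases))
    expect_equal(deepest_kept(as.numeric(p)), unname(cases[p]),
                 info = paste("pident", p))
  # masking monotonicity on random identities
  set.seed(51)
  for (i in 1:50) {
    m <- mask_lineage(lin, runif(1, 50, 100), tax_params())
    u <- m == "unclassified"
    expect_true(all(diff(u) >= 0))   # once unclassified, stays unclassified
  }
  # masking disabled leaves the lineage alone
  expect_equal(mask_lineage(lin, 10, tax_params(masking = FALSE)), lin)
})

test_that("consensus selection walks ranks with the 0.6 fraction rule", {
  lineA <- parse_lineage(lineage_string("Gshare", "Gshare spA"))
  lineB <- parse_lineage(lineage_string("Gshare", "Gshare spB"))
  lineX <- parse_lineage(lineage_string("Gother", "Gother spX"))
  df <- function(lins, pid = 99) {
    m <- do.call(rbind, lins)
    out <- as.data.frame(m)
    names(out) <- TAX_RANKS
    out$pident <- pid
    out
  }
  # 7 of 10 hits share the full lineage -> species-level call
  sel <- select_taxonomy(df(c(rep(list(lineA), 7), rep(list(lineX), 3))),
                         tax_params())
  expect_equal(unname(sel["species"]), "Gshare spA")
  # 5+5 same-genus species -> genus-level call with species unclassified
  sel2 <- select_taxonomy(df(c(rep(list(lineA), 5), rep(list(lineB), 5))),
                          tax_params())
  expect_equal(unname(sel2["genus"]), "Gshare")
  expect_equal(unname(sel2["species"]), "unclassified")
  # a single hit is returned as-is
  expect_equal(select_taxonomy(df(list(lineA))), lineA)
})

test_that("gap retention + consensus selection match a brute-force enumerator", {
  set.seed(52)
  mismatches <- 0L
  for (i in 1:200) {
    hits <- random_hits(sample(1:20, 1), n_lineages = sample(1:5, 1))
    gap <- sample(c(0, 1, 5, 20), 1)
    got <- pipeline_taxonomy_decision(hits, gap, 0.6)
    want <- oracle_taxonomy(hits, gap, 0.6)
    if (!identical(got, want)) mismatches <- mismatches + 1L
    # retention invariants
    ret <- retain_hits(hits, gap)
    expect_gte(nrow(ret), 1L)
    expect_true(all(ret$bitscore > ret$bitscore[1] - gap |
                      ret$bitscore == ret$bitscore[1]))
  }
  expect_equal(mismatches, 0L)
})

test_that("cluster classification via the built-in search", {
  set.seed(53)
  refA <- random_dna(800)
  refB <- local({ # same genus, ~5% divergent from A
    s <- strsplit(refA, "")[[1]]
    k <- sample(800, 40)
    s[k] <- vapply(s[k], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(s, collapse = "")
  })
  refX <- random_dna(800)
  ref <- tiny_reference(c(refA, refB, refX),
                        genus = c("Gsame", "Gsame", "Gfar"),
                        species = c("Gsame spA", "Gsame spB", "Gfar spX"))
  # representative identical to one reference -> its full lineage
  tax <- classify_clusters(c(Cluster_0 = refA), ref, tax_params())
  expect_equal(unname(tax$Cluster_0["species"]), "Gsame spA")
  # unrelated representative -> all-unclassified (below the domain floor)
  taxu <- classify_clusters(c(Cluster_0 = random_dna(800)), ref, tax_params())
  expect_true(all(taxu$Cluster_0 == "unclassified"))
})

test_that("equidistant same-genus references force a genus-level call", {
  # synthetic hit table: two hits at pident 95, tied bitscore, same genus
  lineA <- parse_lineage(lineage_string("Gsame", "Gsame spA"))
  lineB <- parse_lineage(lineage_string("Gsame", "Gsame spB"))
  h <- as.data.frame(rbind(lineA, lineB))
  names(h) <- TAX_RANKS
  h$pident <- 95
  h$bitscore <- 700
  ret <- retain_hits(h, gap = 1)
  for (i in 1:2)
    ret[i, TAX_RANKS] <- mask_lineage(unlist(ret[i, TAX_RANKS]), 95,
                                      tax_params())
  sel <- select_taxonomy(ret, tax_params())
  expect_equal(unname(sel["genus"]), "Gsame")
  expect_equal(unname(sel["species"]), "unclassified")
})

test_that("rank collapse is additive and conserves the total", {
  tab <- matrix(c(10L, 5L, 3L), 3, 1,
                dimnames = list(paste0("Cluster_", 0:2), "s1"))
  linA <- parse_lineage(lineage_string("G1", "G1 spA"))
  linB <- linA                     # same species, different cluster
  linC <- linA
  linC["species"] <- "unclassified"
  taxonomy <- list(Cluster_0 = linA, Cluster_1 = linB, Cluster_2 = linC)
  sp <- collapse_by_rank(tab, taxonomy, "species")
  expect_equal(nrow(sp), 2L)
  expect_equal(unname(sp[grep("s__G1 spA$", rownames(sp)), 1]), 15L)
  expect_equal(unname(sp[grep("s__unclassified$", rownames(sp)), 1]), 3L)
  dom <- collapse_by_rank(tab, taxonomy, "domain")
  expect_equal(nrow(dom), 1L)
  expect_equal(sum(dom), sum(tab))
  for (r in TAX_RANKS)
    expect_equal(sum(collapse_by_rank(tab, taxonomy, r)), sum(tab))
  expect_error(collapse_by_rank(tab, taxonomy[1:2], "genus"), "Cluster_2")
})
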