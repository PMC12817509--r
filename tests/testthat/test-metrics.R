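test_that("observed-taxa filtering applies the abundance floor and sample count", {
  p1 <- community_profile(c(A = 0.6, B = 0.395, C = 0.005), "s1")
  p2 <- community_profile(c(A = 0.5, B = 0.495, C = 0.005), "s2")
  p3 <- community_profile(c(A = 0.7, D = 0.3), "s3")
  # taxon below 1% everywhere disappears under the DNA-standard policy
  f <- filter_observed(list(p1, p2, p3), min_relab = 0.01, min_samples = 2)
  expect_false("C" %in% unlist(lapply(f, names)))
  # taxon in a single sample disappears under the gut-standard policy
  f2 <- filter_observed(list(p1, p2, p3), min_relab = 0, min_samples = 2)
  expect_false("D" %in% unlist(lapply(f2, names)))
  expect_true("C" %in% names(f2[[1]]))
  # the identity policy changes nothing
  f3 <- filter_observed(list(p1), min_relab = 0, min_samples = 1)
  expect_equal(names(f3[[1]]), names(p1))
  expect_equal(as.numeric(f3[[1]]), as.numeric(p1))
})

test_that("OET/TAR/TDR follow their set definitions", {
  exp8 <- paste0("sp", 1:8)
  m <- taxa_metrics(exp8, exp8)
  expect_equal(c(m$oet, m$tar, m$tdr), c(1, 1, 1))

  m2 <- taxa_metrics(c(exp8, "fp1"), exp8)
  expect_equal(m2$oet, 1.125)
  expect_equal(round(m2$tar, 3), 0.889)
  expect_equal(m2$tdr, 1)

  m3 <- taxa_metrics(c(exp8[1:6], paste0("fp", 1:9)), exp8)
  expect_equal(m3$oet, 1.875)
  expect_equal(m3$tar, 0.4)
  expect_equal(m3$tdr, 0.75)

  expect_error(taxa_metrics("a", character(0)), "empty")
  expect_warning(m0 <- taxa_metrics(character(0), exp8), "TAR undefined")
  expect_equal(m0$tar, 0)
  expect_false(m0$tar_defined)
})

test_that("OET equals TDR/TAR on random set pairs", {
  set.seed(61)
  pool <- paste0("t", 1:30)
  for (i in 1:100) {
    expected <- sample(pool, sample(1:20, 1))
    observed <- sample(pool, sample(1:20, 1))
    m <- taxa_metrics(observed, expected)
    expect_equal(m$tdr == 1, all(expected %in% observed))
    expect_equal(m$tar == 1, all(observed %in% expected))
    if (m$tar > 0)
      expect_equal(m$oet, m$tdr / m$tar)
  }
})

test_that("Bray-Curtis distance: identity, disjointness, worked example", {
  expect_equal(bray_curtis(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5)), 0)
  expect_equal(bray_curtis(c(A = 1), c(B = 1)), 1)
  expect_equal(bray_curtis(c(A = 0.6, B = 0.4), c(A = 0.4, B = 0.6)), 0.2)
  expect_error(bray_curtis(c(A = 0), c(B = 0)), "all-zero")
  # symmetry and triangle inequality spot checks
  set.seed(62)
  for (i in 1:20) {
    p <- setNames(runif(5), paste0("x", 1:5))
    q <- setNames(runif(5), paste0("x", c(1:3, 6:7)))
    r <- setNames(runif(4), paste0("x", c(2, 4, 6, 8)))
    expect_equal(bray_curtis(p, q), bray_curtis(q, p))
    expect_lte(bray_curtis(p, r),
               bray_curtis(p, q) + bray_curtis(q, r) + 1e-12)
  }
})

test_that("abundance regression matches a hand-rolled OLS oracle", {
  expected <- setNames(c(.3, .2, .15, .1, .1, .05, .05, .05), paste0("s", 1:8))
  perf <- abundance_regression(expected, expected)
  expect_equal(perf$r_squared, 1)

  set.seed(63)
  observed <- setNames(sample(expected), names(expected))
  got <- abundance_regression(observed, expected)
  # closed-form OLS on the same 8 taxa
  x <- as.numeric(expected)
  y <- as.numeric(observed[names(expected)])
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  yhat <- mean(y) + beta * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  se <- sqrt(sum((y - yhat)^2) / (8 - 2) / sum((x - mean(x))^2))
  p <- 2 * pt(abs(beta / se), df = 6, lower.tail = FALSE)
  expect_equal(got$r_squared, r2)
  expect_equal(got$p_value, p)

  expect_error(abundance_regression(c(A = .5, B = .5), c(A = .5, B = .5)),
               "3 taxa")
  expect_error(abundance_regression(setNames(runif(4), letters[1:4]),
                                    setNames(rep(.25, 4), letters[1:4])),
               "variance")
})

test_that("profile evaluation combines filtering and all metrics per sample", {
  w <- c(.3, .2, .15, .1, .1, .06, .05, .04)
  expected <- community_profile(setNames(w, paste0("sp", 1:8)), "expected")
  same <- community_profile(setNames(w, paste0("sp", 1:8)), "s1")
  rep1 <- evaluate_profiles(list(same), expected)
  expect_equal(nrow(rep1), 1L)
  expect_equal(c(rep1$oet, rep1$tar, rep1$tdr, rep1$bc), c(1, 1, 1, 0))
  expect_equal(rep1$r_squared, 1)

  # a 0.9% taxon is dropped under the >= 1% policy
  ab <- c(setNames(w * 0.991, paste0("sp", 1:8)), extra = 0.009)
  low <- community_profile(ab, "s1")
  rep2 <- evaluate_profiles(list(low, low), expected, min_relab = 0.01,
                            min_samples = 2)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$oet, c(1, 1))

  # harmonization renames observed labels before comparison
  renamed <- community_profile(
    setNames(rep(1 / 8, 8), c(paste0("sp", 1:7), "old_name")), "s1")
  rep3 <- evaluate_profiles(list(renamed), expected,
                            rename = c(old_name = "sp8"))
  expect_equal(rep3$tar, 1)
  clash <- community_profile(setNames(c(.5, .5), c("sp1", "old")), "s1")
  expect_error(evaluate_profiles(list(clash), expected,
                                 rename = c(old = "sp1")), "collision")
})
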