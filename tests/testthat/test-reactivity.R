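test_that("raw reactivity is the NAI minus DMSO rate difference", {
  expect_equal(rawReactivity(0.05, 0.01), 0.04)
  expect_equal(rawReactivity(c(0.03, 0.03), c(0.03, 0.03)), c(0, 0))
  expect_true(is.na(rawReactivity(0.05, NA)))
  expect_true(is.na(rawReactivity(NA, 0.01)))
  expect_equal(rawReactivity(0.01, 0.05), -0.04)   # negatives preserved
  expect_error(rawReactivity(c(1, 2), 1), "length")
})

test_that("boxplot normalization behaves on constant and outlier profiles", {
  prof <- normalizeProfile(rep(0.5, 100), "t")
  expect_equal(normFactor(prof), 0.5)
  expect_equal(reactivity(prof), rep(1, 100))

  # single huge outlier: excluded from f, retained (normalized > 1) in output
  raw <- c(rep(0.5, 100), 100)
  prof <- normalizeProfile(raw, "t")
  expect_equal(normFactor(prof), 0.5)
  expect_equal(reactivity(prof)[101], 200)

  expect_warning(p0 <- normalizeProfile(rep(0, 50), "t"), "not normalized")
  expect_true(all(is.na(reactivity(p0))))
  expect_warning(p1 <- normalizeProfile(c(1, 2, NA, NA), "t"), "not normalized")
  expect_true(all(is.na(reactivity(p1))))

  # the mean of the top 10% of post-exclusion normalized scores is 1
  set.seed(8)
  raw <- rgamma(200, 1.2, 3)
  prof <- normalizeProfile(raw, "t")
  s <- reactivity(prof)
  q <- quantile(raw, c(.25, .75), names = FALSE)
  keep <- raw[raw <= q[2] + 1.5 * (q[2] - q[1])]
  top <- sort(keep, decreasing = TRUE)[seq_len(ceiling(0.1 * length(keep)))]
  expect_equal(mean(top / normFactor(prof)), 1, tolerance = 1e-9)

  # scale equivariance: multiplying raw scores by c > 0 leaves s unchanged
  prof2 <- normalizeProfile(raw * 7.3, "t")
  expect_equal(reactivity(prof2), s, tolerance = 1e-12)
})

test_that("masking nulls low-coverage and high-background positions", {
  prof <- new("ReactivityProfile", transcript = "t", sequence = NA_character_,
              score = c(1, 2, 3), coverage = c(999, 1000, 5000),
              normFactor = 1)
  m <- maskProfile(prof, minCoverage = 1000)
  expect_equal(reactivity(m), c(NA, 2, 3))
  m2 <- maskProfile(prof, minCoverage = 1, dmsoRate = c(0.01, 0.2, 0.01),
                    maxBackground = 0.05)
  expect_equal(reactivity(m2), c(1, NA, 3))    # m1A-like site masked
  clean <- maskProfile(prof, minCoverage = 100)
  expect_identical(reactivity(clean), reactivity(prof))
})

test_that("replicate correlation handles identical, inverted and null pairs", {
  sim <- simulateReplicateCounts(nBases = 1500, covRange = c(600, 6000),
                                 seed = 41)
  rc <- replicateCorrelation(sim$rep1, sim$rep1, cutoffs = c(500), seed = 1)
  expect_true(all(abs(rc[["500"]] - 1) < 1e-12))

  # anti-correlated rates (synthetic): r = -1 in every window
  r1 <- sim$rep1
  cnt <- eventCounts(r1)
  inv <- cnt
  inv[, "mismatch"] <- positionCoverage(r1) - cnt[, "mismatch"]
  r2 <- new("MutationCounts", transcript = "inv", counts = inv,
            coverage = positionCoverage(r1))
  rcInv <- replicateCorrelation(r1, r2, cutoffs = c(500), seed = 1)
  expect_true(all(rcInv[["500"]] < -0.99))

  # two pure-noise replicates: mean window r near 0
  set.seed(42)
  mkNoise <- function() {
    ev <- rbinom(2500, 4000, 0.01)
    cnt <- matrix(0L, 2500, 8, dimnames = list(NULL, mutationClasses()))
    cnt[, "mismatch"] <- ev
    new("MutationCounts", transcript = "n", counts = cnt,
        coverage = rep(4000L, 2500))
  }
  rcN <- replicateCorrelation(mkNoise(), mkNoise(), cutoffs = c(500), seed = 1)
  expect_gt(length(rcN[["500"]]), 200)
  expect_lt(abs(mean(rcN[["500"]])), 0.15)
})

test_that("median window correlation grows with the coverage cutoff", {
  sim <- simulateReplicateCounts(nBases = 4000, covRange = c(300, 9000),
                                 seed = 7)
  rc <- replicateCorrelation(sim$rep1, sim$rep2,
                             cutoffs = c(500, 1000, 2000, 3000, 4000, 5000),
                             seed = 7)
  med <- vapply(rc, median, 1.0)
  expect_true(all(diff(med) >= -1e-9))
})

test_that("structure AUC follows the ties-half convention and its symmetry", {
  ref <- secondaryStructure("GGGGAAAACCCC", "((((....))))")
  hi <- c(rep(0.1, 4), rep(0.9, 4), rep(0.1, 4))
  expect_equal(structureAuc(hi, ref), 1.0)
  expect_equal(structureAuc(rep(0.5, 12), ref), 0.5)

  s4 <- c(0.9, 0.7, 0.4, 0.2)
  ref4 <- secondaryStructure("GGGGAAAACCCC", "((((....))))")
  # labels: unpaired, paired, unpaired, paired on 4 scored positions
  sc <- rep(NA_real_, 12)
  sc[c(5, 1, 6, 2)] <- s4
  expect_equal(structureAuc(sc, ref4), 0.75)
  expect_equal(structureAuc(sc, ref4),
               bruteAuc(s4, c(TRUE, FALSE, TRUE, FALSE)))

  # AUC(-s) = 1 - AUC(s), exactly
  set.seed(9)
  sc2 <- runif(12)
  expect_equal(structureAuc(-sc2, ref), 1 - structureAuc(sc2, ref))

  allPaired <- secondaryStructure("GGGGAAAACCCC", "((((....))))")
  expect_error(structureAuc(c(rep(NA, 4), runif(4), rep(NA, 4)), allPaired),
               "paired and one unpaired")
})

test_that("scoreTranscript combines replicates by summing counts", {
  mk <- function(ev, cov) {
    cnt <- matrix(0L, length(cov), 8, dimnames = list(NULL, mutationClasses()))
    cnt[, "mismatch"] <- as.integer(ev)
    new("MutationCounts", transcript = "t", counts = cnt,
        coverage = as.integer(cov))
  }
  n <- 20
  nai1 <- mk(rep(30, n), rep(1000, n))
  nai2 <- mk(rep(0, n), rep(1000, n))
  dmso <- mk(rep(10, n), rep(2000, n))
  prof <- scoreTranscript(list(nai1, nai2), dmso, minCoverage = 100)
  # combined NAI rate 30/2000 = 0.015 (not the mean of 0.03 and 0),
  # DMSO 0.005 -> raw 0.01 everywhere -> normalized to 1
  expect_equal(reactivity(prof), rep(1, n))
  expect_equal(normFactor(prof), 0.01)
})

test_that("SHAPE file round trip encodes NA as -999", {
  s <- c(0.5, NA, 1.2, -0.3)
  path <- tempfile(fileext = ".shape")
  writeShapeFile(s, path)
  expect_true(any(grepl("-999", readLines(path))))
  expect_equal(readShapeFile(path), s)
})
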