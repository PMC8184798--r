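test_that("simple folds match intuition and the enumeration oracle", {
  expect_equal(dotBracket(foldConstrained("AAAAAAAAAAAA")),
               "............")
  s <- foldConstrained("GGGGAAAACCCC")
  expect_equal(dotBracket(s), "((((....))))")
  expect_equal(attr(s, "energy"), enumerateMfe("GGGGAAAACCCC")$energy,
               tolerance = 1e-6)

  # strong reactivity on the outermost stem positions opens them
  prof <- rep(NA_real_, 12)
  prof[c(1, 12)] <- 3.0
  s2 <- foldConstrained("GGGGAAAACCCC", prof)
  pt <- pairTable(s2)
  expect_equal(pt[1], 0L)
  expect_equal(pt[12], 0L)
  expect_equal(attr(s2, "energy"), enumerateMfe("GGGGAAAACCCC", prof)$energy,
               tolerance = 1e-6)

  expect_error(foldConstrained("GGGGAXAACCCC"), "invalid")
  expect_error(foldConstrained("GGGCCC"), "shorter")
})

test_that("DP optimum equals exhaustive enumeration on random sequences", {
  set.seed(101)
  for (rep in 1:40) {
    len <- sample(8:14, 1)
    sq <- randomSequence(len)
    prof <- if (rep %% 2 == 0) runif(len, -0.5, 3) else NULL
    got <- foldConstrained(sq, prof)
    want <- enumerateMfe(sq, prof)
    expect_equal(attr(got, "energy"), want$energy, tolerance = 1e-6,
                 label = paste("energy for", sq))
    # the returned structure really attains the reported energy
    expect_equal(structureEnergy(sq, got, prof), attr(got, "energy"),
                 tolerance = 1e-6)
  }
})

test_that("DP optimum is exact on an exhaustive two-letter sweep", {
  # every AU-alphabet sequence of length 8: folds are dominated by weak
  # AU/UA stacks and the empty structure, a good degenerate-tie stress
  seqs <- do.call(paste0, expand.grid(rep(list(c("A", "U")), 8)))
  for (sq in seqs) {
    got <- foldConstrained(sq)
    want <- enumerateMfe(sq)
    expect_equal(attr(got, "energy"), want$energy, tolerance = 1e-6,
                 label = sq)
  }
})

test_that("pseudo-energy terms respect the declared conventions", {
  pe <- pseudoEnergies(c(0, 1, -2, NA))
  expect_equal(pe[1], -0.6)                      # s = 0 -> intercept
  expect_equal(pe[2], 1.8 * log(2) - 0.6)
  expect_equal(pe[3], -0.6)                      # negative treated as 0
  expect_equal(pe[4], 0)                         # missing contributes 0

  # monotone in s at and above 0
  s <- seq(0, 4, by = 0.25)
  expect_true(all(diff(pseudoEnergies(s)) > 0))

  # zero-profile neutrality: energy differs from unconstrained by
  # intercept * (paired count), structure unchanged
  sq <- "GGGGGAAAACCCCC"
  free <- foldConstrained(sq)
  zero <- foldConstrained(sq, rep(0, 14))
  expect_equal(dotBracket(zero), dotBracket(free))
  nPaired <- sum(pairTable(free) > 0)
  expect_equal(attr(zero, "energy"), attr(free, "energy") - 0.6 * nPaired,
               tolerance = 1e-9)
})

test_that("feature extraction finds terminal loops and classifies runs", {
  f <- extractFeatures(secondaryStructure("GGGGAAAACCCC", "((((....))))"))
  expect_equal(f$terminal_loop$span, c(5L, 8L))
  expect_equal(f$terminal_loop$size, 4L)
  expect_false(any(f$single_stranded_regions$type == "bulge"))

  s2 <- secondaryStructure("GGGGAAGGAAAACCAACCCC", "((((..((....))..))))")
  f2 <- extractFeatures(s2)
  expect_equal(f2$terminal_loop$span, c(9L, 12L))
  ssr <- f2$single_stranded_regions
  expect_setequal(ssr$type[ssr$start %in% c(5, 15)],
                  c("internal-loop", "internal-loop"))

  s3 <- secondaryStructure("GGGAGGAAAACCCCC", "(((.((....)))))")
  f3 <- extractFeatures(s3)
  ssr3 <- f3$single_stranded_regions
  bulge <- ssr3[ssr3$type == "bulge", ]
  expect_equal(nrow(bulge), 1L)
  expect_equal(bulge$start, 4L)
  expect_equal(bulge$arm, "5p-arm")

  expect_error(extractFeatures(secondaryStructure("AAAA", "....")),
               "no hairpin")
})

test_that("central loop selection prefers the loop nearest the midpoint", {
  # cloverleaf-like: two hairpins; the central one anchors
  db <- "((....))((((....))))((....))"
  sq <- strrep("A", nchar(db))
  pt <- dotBracketToPairs(db)
  st <- new("SecondaryStructure", sequence = sq, pairTable = pt)
  expect_equal(centralLoop(st), c(13L, 16L))
})

test_that("structure comparison partitions positions into the four classes", {
  a <- secondaryStructure("GGGAAAACCC", "(((....)))")
  expect_true(all(compareStructures(a, a) == "identical"))

  a2 <- secondaryStructure("GGAAAACC", "((....))")
  b2 <- secondaryStructure("GGAAAACC", "(((..)))")
  cmp <- compareStructures(a2, b2)
  expect_equal(which(cmp == "ss-in-a-paired-in-b"), c(3L, 6L))
  expect_equal(which(cmp == "identical"), c(1L, 2L, 4L, 5L, 7L, 8L))
  expect_equal(sum(table(cmp)), 8L)

  # different partners case
  c1 <- secondaryStructure("GCGAAAAACGC", "(.(....).).")
  expect_error(compareStructures(a2, c1), "length")
  cmp2 <- compareStructures(
    secondaryStructure("GGGAAAACCCC", "((.(....)))"),
    secondaryStructure("GGGAAAACCCC", "(.((....)))"))
  expect_true(any(cmp2 == "both-paired-different-partner"))
})

test_that("dot-bracket and CT files round trip", {
  st <- secondaryStructure("GGGGAAAACCCC", "((((....))))")
  db <- tempfile(fileext = ".db")
  writeDotBracket(list(x = st), db)
  back <- readDotBracket(db)
  expect_equal(pairTable(back$x), pairTable(st))

  ct <- tempfile(fileext = ".ct")
  writeCt(st, ct, id = "x")
  expect_equal(pairTable(readCt(ct)), pairTable(st))
})

test_that("structure validity rejects malformed pairings", {
  expect_error(secondaryStructure("GGGAAACCC", "((((...))"), "unbalanced")
  expect_error(new("SecondaryStructure", sequence = "GAAAC",
                   pairTable = c(2L, 1L, 0L, 0L, 0L)), "enclose")
  expect_error(new("SecondaryStructure", sequence = "GAAAAC",
                   pairTable = c(6L, 0L, 0L, 0L, 0L, 2L)), "involution")
})
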