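mkRead <- function(pos, cigar, seq, qname = "r1", flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, rname = "ref", pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

REF30 <- "ACGUACGUACGUACGUACGUACGUACGUAC"

test_that("single events are parsed and placed correctly", {
  expect_equal(nrow(parseReadMutations(mkRead(1, "30M", REF30), REF30)), 0)

  mut <- REF30
  substr(mut, 12, 12) <- "C"           # reference has G at 12
  ev <- parseReadMutations(mkRead(1, "30M", mut), REF30)
  expect_equal(ev$mtype, "mismatch")
  expect_equal(ev$ref_position, 12L)

  # 5M2D5M: deletion of ref 6-7, right-alignable? ref ACGUA CG UACGU:
  # deleted "CG" at 6-7; following base U != C so no shift
  rd <- mkRead(1, "5M2D5M", paste0(substr(REF30, 1, 5), substr(REF30, 8, 12)))
  ev <- parseReadMutations(rd, REF30)
  expect_equal(ev$mtype, "multi_deletion")
  expect_equal(ev$ref_span, 2L)
  expect_equal(ev$ref_position, 7L)    # 3'-most deleted base

  # two mismatches separated by one matched base merge into one event
  mut2 <- REF30
  substr(mut2, 10, 10) <- "G"   # ref C
  substr(mut2, 12, 12) <- "A"   # ref U
  ev <- parseReadMutations(mkRead(1, "30M", mut2), REF30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$mtype, "multi_mismatch")
  expect_equal(ev$ref_position, 12L)
  expect_equal(ev$ref_span, 3L)

  # beyond the merge distance they stay separate
  mut3 <- REF30
  substr(mut3, 10, 10) <- "G"   # ref C
  substr(mut3, 14, 14) <- "A"   # ref C
  ev <- parseReadMutations(mkRead(1, "30M", mut3), REF30)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$mtype, c("mismatch", "mismatch"))

  expect_error(parseReadMutations(mkRead(1, "31M", REF30, qname = "bad"),
                                  REF30), "bad")
})

test_that("mixed merged events are classified by net reference change", {
  # mismatch + 1-nt deletion nearby: net loss -> complex_deletion
  sq <- paste0(substr(REF30, 1, 9), "A", substr(REF30, 12, 30))
  sq <- sub("^(.{7})U", "\\1G", sq)    # mismatch at ref 8 (U -> G)
  rd <- mkRead(1, "10M1D19M", sq)
  ev <- parseReadMutations(rd, REF30)
  expect_equal(ev$mtype[1], "complex_deletion")

  # mismatch + insertion: net gain -> complex_insertion
  mut <- paste0(substr(REF30, 1, 10), "G", substr(REF30, 11, 30))
  substr(mut, 9, 9) <- "C"             # ref A at 9
  ev <- parseReadMutations(mkRead(1, "10M1I20M", mut), REF30)
  expect_equal(ev$mtype, "complex_insertion")

  # insertion + deletion within the merge distance, net zero ->
  # multi_mismatch label
  sq <- paste0(substr(REF30, 1, 5), "G", substr(REF30, 6, 7),
               substr(REF30, 9, 30))
  ev <- parseReadMutations(mkRead(1, "5M1I2M1D22M", sq), REF30)
  expect_equal(ev$mtype, "multi_mismatch")
})

test_that("deletions in repeats are right-aligned", {
  ref <- "ACGGGGUACGUACG"
  # delete one G of the G-run starting at 3: placement shifts to 3'-most G
  rd <- mkRead(1, "2M1D11M", paste0("AC", substr(ref, 4, 14)))
  ev <- parseReadMutations(rd, ref)
  expect_equal(ev$mtype, "deletion")
  expect_equal(ev$ref_position, 6L)
})

test_that("soft clips and flag/mapq filters behave as documented", {
  ev <- parseReadMutations(mkRead(3, "3S10M", paste0("GGG",
                                                     substr(REF30, 3, 12))),
                           REF30)
  expect_equal(nrow(ev), 0)

  reads <- rbind(mkRead(1, "30M", REF30, "a"),
                 mkRead(1, "30M", REF30, "b", flag = 0x100L),
                 mkRead(1, "30M", REF30, "c", mapq = 0L))
  mc <- countMutations(reads, REF30)
  expect_true(all(positionCoverage(mc) == 1))   # only the primary survives
})

test_that("counting conserves coverage and matches per-read parsing", {
  reads <- rbind(mkRead(1, "30M", REF30, "a"),
                 mkRead(5, "10M", substr(REF30, 5, 14), "b"),
                 mkRead(1, "15M2D13M",
                        paste0(substr(REF30, 1, 15), substr(REF30, 18, 30)),
                        "c"))
  mc <- countMutations(reads, REF30)
  expect_equal(sum(positionCoverage(mc)), 30L + 10L + 30L)
  expect_equal(sum(eventCounts(mc)[, "multi_deletion"]), 1L)

  empty <- countMutations(mkRead(1, "30M", REF30)[0, ], REF30)
  expect_true(all(positionCoverage(empty) == 0))
  expect_true(all(eventCounts(empty) == 0))

  # one mismatch among 10 reads: numerator 1, denominator 10 at position 7
  mut <- REF30
  substr(mut, 7, 7) <- "A"
  reads10 <- do.call(rbind, c(list(mkRead(1, "30M", mut, "m")),
                              lapply(1:9, function(i)
                                mkRead(1, "30M", REF30, paste0("p", i)))))
  mc10 <- countMutations(reads10, REF30)
  expect_equal(sum(eventCounts(mc10)[7, ]), 1L)
  expect_equal(positionCoverage(mc10)[7], 10L)
  expect_equal(mutationRate(mc10, 1)[7], 0.1)
})

test_that("mutation rates mask low-coverage positions", {
  cnt <- matrix(0L, 4, 8, dimnames = list(NULL, mutationClasses()))
  cnt[1, "mismatch"] <- 5L
  mc <- new("MutationCounts", transcript = "t", counts = cnt,
            coverage = c(100L, 400L, 1000L, 0L))
  expect_equal(mutationRate(mc, 1)[1], 0.05)
  expect_equal(mutationRate(mc, 500), c(NA, NA, 0, NA))
})

test_that("parser is idempotent and matches the brute-force oracle", {
  spec <- simSpec(n_transcripts = 1, stem_len = 10, loop_len = 6, depth = 400,
                  mod_rate_ss = 0.3, mod_rate_ds = 0.15,
                  background_rate = 0.1, seed = 21)
  hp <- makeHairpinSet(spec)
  reads <- simulateMapReads(hp$sequence[1], hp$structure[1], spec, "NAI")
  seen <- character(0)
  for (i in seq_len(nrow(reads))) {
    got <- parseReadMutations(reads[i, ], hp$sequence[1])
    again <- parseReadMutations(reads[i, ], hp$sequence[1])
    expect_identical(got, again)
    want <- oracleParseRead(reads$pos[i], reads$cigar[i], reads$seq[i],
                            hp$sequence[1])
    expect_identical(got, want)
    seen <- union(seen, got$mtype)
  }
  expect_gt(length(seen), 4)   # high rates exercise the merged classes
})

test_that("SAM round trip preserves reads and counts", {
  spec <- simSpec(n_transcripts = 1, stem_len = 8, loop_len = 4, depth = 50,
                  mod_rate_ss = 0.1, mod_rate_ds = 0.05,
                  background_rate = 0.02, seed = 31)
  hp <- makeHairpinSet(spec)
  reads <- simulateMapReads(hp$sequence[1], hp$structure[1], spec, "NAI")
  reads$rname <- hp$id[1]
  sam <- tempfile(fileext = ".sam")
  writeSamReads(reads, stats::setNames(nchar(hp$sequence[1]), hp$id[1]), sam)
  back <- readSamReads(sam)
  expect_equal(nrow(back), nrow(reads))
  mc1 <- countMutations(reads, hp$sequence[1])
  mc2 <- countMutations(back, hp$sequence[1])
  expect_equal(eventCounts(mc1), eventCounts(mc2))
  expect_equal(positionCoverage(mc1), positionCoverage(mc2))

  fa <- tempfile(fileext = ".fasta")
  writeReferenceFasta(stats::setNames(hp$sequence[1], hp$id[1]), fa)
  prof <- profileSam(sam, fa)
  expect_equal(eventCounts(prof[[hp$id[1]]]), eventCounts(mc1))
})

test_that("count TSV round trip is lossless", {
  cnt <- matrix(rpois(16, 2), 2, 8, dimnames = list(NULL, mutationClasses()))
  storage.mode(cnt) <- "integer"
  mc <- new("MutationCounts", transcript = "t1", counts = cnt,
            coverage = c(50L, 60L))
  path <- tempfile(fileext = ".tsv")
  writeMutationCountsTsv(list(t1 = mc), path)
  back <- readMutationCountsTsv(path)
  expect_equal(eventCounts(back$t1), eventCounts(mc))
  expect_equal(positionCoverage(back$t1), positionCoverage(mc))
})
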