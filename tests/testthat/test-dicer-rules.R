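# a hand-buildable coordinate model with one C5'/O3' pair per residue
mkModel <- function(xyz, energy = NA_real_) {
  atoms <- data.frame(resno = rep(seq_len(nrow(xyz)), each = 2),
                      atom = rep(c("C5'", "O3'"), nrow(xyz)),
                      x = rep(xyz[, 1], each = 2),
                      y = rep(xyz[, 2], each = 2),
                      z = rep(xyz[, 3], each = 2), stringsAsFactors = FALSE)
  new("CoordinateModel", atoms = atoms, energy = energy)
}

test_that("terminus distances are Euclidean and name missing atoms", {
  m <- mkModel(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(terminusDistance(m, 1, 1), 0)
  expect_equal(terminusDistance(m, 1, 2), 5)       # 3-4-5 triangle
  expect_error(terminusDistance(m, 1, 9), "residue 9")

  noO3 <- m
  noO3@atoms <- noO3@atoms[noO3@atoms$atom != "O3'", ]
  expect_error(terminusDistance(noO3, 1, 2), "O3'")
})

test_that("helix model distances match the chord formula on both strands", {
  spec <- helixSpec(n_bp = 30)
  model <- buildHelixCoordinates(spec)
  chord <- function(n) sqrt((n * spec$rise)^2 +
                            (2 * spec$radius * sin(n * spec$twist * pi / 360))^2)
  # strand 2 residues sit n steps apart along the same cylinder
  expect_equal(terminusDistance(model, 31, 31 + 10), chord(10),
               tolerance = 1e-6)
  expect_equal(terminusDistance(model, 1, 11), chord(10), tolerance = 1e-6)
})

test_that("dicing distances take medians and honor the model cap", {
  ann <- mirnaAnnotation("mir", strrep("A", 44), c(1, 19), c(26, 44))
  mk3 <- function(d) {
    xyz <- matrix(0, 44, 3)
    xyz[44, ] <- c(d, 0, 0)           # O3' of last nt at distance d from C5'
    xyz[26, ] <- c(0, 0, 0)           # first nt of 3p span at origin
    mkModel(xyz)
  }
  models <- lapply(c(58, 59, 60), mk3)
  d <- dicingDistances(models, ann)
  expect_equal(unname(d["D_3p_miRNA"]), 59)      # odd-count median
  single <- dicingDistances(models[2], ann)
  expect_equal(unname(single["D_3p_miRNA"]), 59)

  expect_error(dicingDistances(list(), ann), "empty")

  # median over duplicated model lists and reordered lists is unchanged
  dup <- dicingDistances(c(models, models), ann)
  expect_equal(dup, d)
  expect_equal(dicingDistances(rev(models), ann), d)

  # more than 50 models: the 50 lowest-energy are used
  many <- lapply(1:60, function(k) {
    m <- mk3(50 + k)                  # distance grows with k
    m@energy <- as.numeric(k)
    m
  })
  capped <- dicingDistances(many, ann)
  expect_equal(unname(capped["D_3p_miRNA"]),
               median(50 + 1:50))
  noE <- lapply(many, function(m) { m@energy <- NA_real_; m })
  expect_warning(all60 <- dicingDistances(noE, ann), "energies absent")
  expect_equal(unname(all60["D_3p_miRNA"]), median(50 + 1:60))
})

test_that("jittered model ensembles keep the median within 1 Angstrom", {
  set.seed(81)
  spec <- helixSpec(n_bp = 22)
  ann <- mirnaAnnotation("mir", strrep("A", 44), c(1, 20), c(25, 44))
  clean <- dicingDistances(list(buildHelixCoordinates(spec)), ann)
  models <- jitteredHelixModels(50, spec, sd = 0.5)
  noisy <- dicingDistances(models, ann)
  expect_lt(abs(noisy["D_3p_miRNA"] - clean["D_3p_miRNA"]), 1)
  expect_lt(abs(noisy["D_5p_miRNA"] - clean["D_5p_miRNA"]), 1)

  # rigid motion of every model leaves the medians unchanged
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- lapply(models, rigidTransform, rotation = rot,
                  translation = c(-3, 8, 2))
  expect_equal(dicingDistances(moved, ann), noisy, tolerance = 1e-9)
})


test_that("loop-counting rule matches hand annotation and a brute-force scan", {
  nCase <- 0
  for (cs in loopRuleCases) {
    n <- nchar(cs$db)
    sq <- strrep("A", n)
    st <- secondaryStructure(sq, cs$db)
    s3 <- cs$s3
    ann <- mirnaAnnotation("m", sq, cs$s5, s3)
    got <- suppressMessages(loopCountingCheck(st, ann))
    expect_equal(unname(got["rule_3p"]), cs$r3,
                 label = paste("3p case", cs$db, s3[1]))
    expect_equal(unname(got["rule_5p"]), cs$r5,
                 label = paste("5p case", cs$db, cs$s5[2]))
    # brute-force re-derivation from the pair table
    pt <- pairTable(st)
    p <- s3[1]
    brute3 <- p - 3 >= 1 && pt[p - 1] > 0 && pt[p - 2] > 0 && pt[p - 3] == 0
    q <- cs$s5[2]
    brute5 <- q + 1 <= n && pt[q + 1] == 0
    expect_equal(unname(got["rule_3p"]), brute3)
    expect_equal(unname(got["rule_5p"]), brute5)
    nCase <- nCase + 2
  }
  expect_gte(nCase, 20)
})

test_that("rule classification respects the distance window and tol monotonicity", {
  lc <- c(rule_3p = TRUE, rule_5p = FALSE)
  d <- c(D_5p_miRNA = 61.5, D_3p_miRNA = 59.5, D_5p_arm = NA, D_3p_arm = NA)
  cls <- classifyRules(d, lc)
  expect_true(cls[["three_prime_counting"]])
  expect_false(cls[["five_prime_counting"]])
  expect_true(cls[["loop_counting"]])

  d2 <- c(D_5p_miRNA = 59, D_3p_miRNA = 57.9, D_5p_arm = NA, D_3p_arm = NA)
  expect_false(classifyRules(d2, lc)[["three_prime_counting"]])

  # enlarging tol never removes a member
  tols <- c(0, 0.5, 1, 2)
  for (dd in list(d, d2)) {
    memb <- vapply(tols, function(tt)
      sum(classifyRules(dd, lc, tol = tt)), 1L)
    expect_true(all(diff(memb) >= 0))
  }
})

test_that("isoform comparison ranks by distance and reports shares", {
  ann <- mirnaAnnotation("mir", strrep("A", 44), c(1, 19), c(26, 44))
  mkAt <- function(d) {
    xyz <- matrix(0, 44, 3)
    xyz[44, ] <- c(d, 0, 0)
    mkModel(xyz)
  }
  # offset shifts the 3p start; residues 25..27 all at the origin here
  mk0 <- function(d) {
    xyz <- matrix(0, 44, 3); xyz[44, ] <- c(d, 0, 0); mkModel(xyz)
  }
  models <- list(`-1` = list(mk0(55)), `0` = list(mk0(59)),
                 `1` = list(mk0(63)))
  res <- compareIsoforms(models, ann, c(`-1` = 15, `0` = 80, `1` = 5))
  expect_true(res$annotated_closest)
  expect_equal(res$in_range_share, 0.8)
  expect_equal(res$table$deviation, c(4, 0, 4))

  expect_error(compareIsoforms(models[1], ann, c(`-1` = 1)), ">= 2")
  expect_error(compareIsoforms(models, ann,
                               c(`-1` = 0, `0` = 0, `1` = 0)), "zero")

  # monotone share-vs-deviation fixture: Spearman correlation positive
  set.seed(91)
  offs <- as.character(1:10)
  dists <- 59 + seq(0, 9) * 1.5
  models10 <- stats::setNames(lapply(dists, function(d) list(mk0(d))), offs)
  ann10 <- mirnaAnnotation("m", strrep("A", 44), c(1, 19), c(26, 44),
                           offsets = 1:10)
  shares <- rev(seq(5, 50, by = 5)) + rnorm(10, 0, 0.5)
  # distances were built for offset 0; offsets shift the measured residue,
  # all residues coincide at the origin so the distance is offset-free
  res10 <- compareIsoforms(models10, ann10,
                           stats::setNames(shares, offs))
  rho <- cor(res10$table$share, -res10$table$deviation, method = "spearman")
  expect_gt(rho, 0)
})

test_that("PDB round trip preserves coordinates, energies and atom dialects", {
  models <- jitteredHelixModels(3, helixSpec(n_bp = 6), sd = 0.3,
                                energies = c(3, 1, 2))
  path <- tempfile(fileext = ".pdb")
  writePdbModels(models, path)
  back <- readPdbModels(path)
  expect_length(back, 3)
  expect_equal(vapply(back, modelEnergy, 1.0), c(3, 1, 2))
  expect_equal(terminusDistance(back[[1]], 1, 12),
               terminusDistance(models[[1]], 1, 12), tolerance = 1e-3)

  # legacy star dialect normalizes to the primed names
  lines <- readLines(path)
  lines <- gsub("C5'", "C5*", lines)
  lines <- gsub("O3'", "O3*", lines)
  path2 <- tempfile(fileext = ".pdb")
  writeLines(lines, path2)
  back2 <- readPdbModels(path2)
  expect_true(all(c("C5'", "O3'") %in% back2[[1]]@atoms$atom))
})

test_that("rule tables assemble the per-substrate Venn membership", {
  set.seed(95)
  spec <- helixSpec(n_bp = 22)
  sq <- strrep("A", 44)
  db <- paste0(strrep("(", 20), "....", strrep(")", 20))
  ann <- list(m1 = mirnaAnnotation("m1", sq, c(1, 18), c(25, 44)))
  st <- list(m1 = secondaryStructure(sq, db))
  mods <- list(m1 = jitteredHelixModels(10, spec, sd = 0.2))
  tab <- ruleTable(mods, ann, st)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$venn_cell %in% apply(expand.grid(0:1, 0:1, 0:1), 1,
                                       paste0, collapse = ""))
  expect_false(is.na(tab$D_5p_arm))
})
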