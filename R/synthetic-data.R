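#' @include AllClasses.R structures.R
NULL

#' Simulation specification for synthetic MaP data
#'
#' Bundles the parameters of the synthetic hairpin cohort: how many
#' transcripts, stem and loop sizes, the per-nucleotide modification-induced
#' mutation probabilities at single-stranded (\code{mod_rate_ss}) and paired
#' (\code{mod_rate_ds}) positions, the DMSO-like background rate, read depth
#' and the seed. Defaults describe the benchmark cohort used throughout the
#' package: 50 hairpins with 15-bp stems and 9-nt loops probed at 2000x depth
#' with a 10-fold single-stranded/paired signal contrast over a 0.002
#' background.
#'
#' @param n_transcripts Number of hairpin transcripts.
#' @param stem_len Stem length in base pairs.
#' @param loop_len Hairpin loop length in nt (>= 3).
#' @param mod_rate_ss Modification-induced mutation probability per nt at
#'   single-stranded positions.
#' @param mod_rate_ds Same, at paired positions.
#' @param background_rate Background (DMSO-like) mutation probability per nt.
#' @param depth Reads per transcript.
#' @param seed Integer seed.
#' @return A list of class \code{SimSpec}.
#' @export
#' @examples
#' simSpec(n_transcripts = 2, depth = 100, seed = 7)
simSpec <- function(n_transcripts = 50, stem_len = 15, loop_len = 9,
                    mod_rate_ss = 0.02, mod_rate_ds = 0.002,
                    background_rate = 0.002, depth = 2000, seed = 1) {
  if (loop_len < 3) stop("loop_len must be >= 3 (minimum hairpin loop)")
  if (depth < 0) stop("depth must be non-negative")
  if (!(background_rate >= 0 && background_rate <= mod_rate_ds &&
        mod_rate_ds <= mod_rate_ss && mod_rate_ss <= 1))
    stop("rates must satisfy 0 <= background_rate <= mod_rate_ds <= mod_rate_ss <= 1")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mod_rate_ss = mod_rate_ss, mod_rate_ds = mod_rate_ds,
                 background_rate = background_rate,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "SimSpec")
}

#' Idealized helix specification
#'
#' Geometry of the idealized double helix used as a stand-in coordinate
#' model: base pairs, helical rise per step, twist per step and cylinder
#' radius. Defaults (2.81 Angstrom rise, 32.7 degree twist, 9.0 Angstrom
#' radius) approximate an A-form-like duplex; they are test-fixture
#' constants, not biological claims.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param rise Rise per step, Angstrom.
#' @param twist Twist per step, degrees, in (0, 180).
#' @param radius Cylinder radius, Angstrom.
#' @return A list of class \code{HelixSpec}.
#' @export
helixSpec <- function(n_bp, rise = 2.81, twist = 32.7, radius = 9.0) {
  if (n_bp < 1) stop("n_bp must be >= 1")
  if (rise <= 0 || radius <= 0) stop("rise and radius must be positive")
  if (twist <= 0 || twist >= 180) stop("twist must be in (0, 180) degrees")
  structure(list(n_bp = as.integer(n_bp), rise = rise, twist = twist,
                 radius = radius), class = "HelixSpec")
}

RNA_BASES <- c("A", "C", "G", "U")
RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Generate a set of hairpin references with known structures
#'
#' Each transcript is a perfect Watson-Crick hairpin: a random 5' stem
#' strand, a random unpaired loop, and the reverse complement of the stem.
#' The emitted dot-bracket is forced by construction.
#'
#' @param spec A \code{\link{simSpec}}.
#' @return data.frame with columns id, sequence, structure (dot-bracket).
#' @export
#' @examples
#' makeHairpinSet(simSpec(n_transcripts = 3, stem_len = 4, loop_len = 4))
makeHairpinSet <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  n <- spec$n_transcripts
  ids <- sprintf("hairpin_%03d", seq_len(n))
  seqs <- character(n)
  db <- paste0(strrep("(", spec$stem_len), strrep(".", spec$loop_len),
               strrep(")", spec$stem_len))
  for (i in seq_len(n)) {
    stem <- sample(RNA_BASES, spec$stem_len, replace = TRUE)
    loop <- sample(RNA_BASES, spec$loop_len, replace = TRUE)
    seqs[i] <- paste(c(stem, loop, rev(RNA_COMP[stem])), collapse = "")
  }
  data.frame(id = ids, sequence = seqs, structure = db,
             stringsAsFactors = FALSE)
}

# proportions of simulated event types; parser tests cover the remaining
# classes with hand-built reads
SIM_EVENT_MIX <- c(mismatch = 0.70, deletion = 0.15, insertion = 0.15)

#' Simulate full-length MaP reads for one transcript
#'
#' Every read spans the full reference (full-length library contract). Under
#' the NAI condition the per-position mutation probability is the
#' modification rate for that position's pairedness plus the background;
#' under DMSO it is the background alone. Each mutation event is a mismatch,
#' a 1-nt deletion or a 1-nt insertion with fixed proportions 70/15/15.
#'
#' @param reference Reference sequence.
#' @param structure Dot-bracket of the reference (same length).
#' @param spec A \code{\link{simSpec}} supplying the rates and depth.
#' @param condition "NAI" or "DMSO".
#' @param seed Seed for this read set (default: the spec seed).
#' @return data.frame of aligned reads with columns qname, flag, rname, pos,
#'   mapq, cigar, seq.
#' @export
simulateMapReads <- function(reference, structure, spec,
                             condition = c("NAI", "DMSO"),
                             seed = spec$seed) {
  condition <- match.arg(condition)
  if (!nzchar(reference)) stop("empty reference")
  n <- nchar(reference)
  if (nchar(structure) != n) stop("structure length must equal sequence length")
  set.seed(seed)
  depth <- spec$depth
  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      stringsAsFactors = FALSE)
  if (depth == 0) return(empty)
  paired <- dotBracketToPairs(structure) > 0
  p <- if (condition == "NAI") {
    ifelse(paired, spec$mod_rate_ds, spec$mod_rate_ss) + spec$background_rate
  } else rep(spec$background_rate, n)
  p <- pmin(p, 1)
  refChars <- strsplit(reference, "")[[1]]
  # event indicator matrix, reads x positions
  ev <- matrix(stats::runif(depth * n) < rep(p, each = depth), nrow = depth)
  cigars <- rep(sprintf("%dM", n), depth)
  seqs <- rep(reference, depth)
  hit <- which(rowSums(ev) > 0)
  for (r in hit) {
    posns <- which(ev[r, ])
    types <- sample(names(SIM_EVENT_MIX), length(posns), replace = TRUE,
                    prob = SIM_EVENT_MIX)
    bases <- refChars
    insAfter <- rep("", n)      # bases inserted after each reference position
    deleted <- rep(FALSE, n)
    for (k in seq_along(posns)) {
      i <- posns[k]
      if (types[k] == "mismatch") {
        bases[i] <- sample(setdiff(RNA_BASES, refChars[i]), 1)
      } else if (types[k] == "deletion") {
        deleted[i] <- TRUE
      } else {
        insAfter[i] <- sample(RNA_BASES, 1)
      }
    }
    # build read sequence and CIGAR by walking the reference
    ops <- character(0); lens <- integer(0)
    pushOp <- function(op, len) {
      if (length(ops) && ops[length(ops)] == op) {
        lens[length(lens)] <<- lens[length(lens)] + len
      } else { ops <<- c(ops, op); lens <<- c(lens, len) }
    }
    out <- character(0)
    for (i in seq_len(n)) {
      if (deleted[i]) pushOp("D", 1L)
      else { pushOp("M", 1L); out <- c(out, bases[i]) }
      if (nzchar(insAfter[i])) { pushOp("I", 1L); out <- c(out, insAfter[i]) }
    }
    cigars[r] <- paste0(lens, ops, collapse = "")
    seqs[r] <- paste(out, collapse = "")
  }
  data.frame(qname = sprintf("read_%06d", seq_len(depth)), flag = 0L,
             rname = "ref", pos = 1L, mapq = 60L, cigar = cigars, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Simulate a two-condition count table with planted log2 effects
#'
#' Condition-A proportions are drawn (or supplied); condition-B proportions
#' equal the A proportions scaled by \code{2^effect} and renormalized. Counts
#' are multinomial draws at \code{total_reads} per condition.
#'
#' @param n_transcripts Number of transcripts.
#' @param planted_log2_effects Numeric vector of per-transcript log2 effects.
#' @param total_reads Total reads per condition (> 0).
#' @param seed Integer seed.
#' @param baseline_props Optional condition-A proportions (summing to 1);
#'   random by default.
#' @return data.frame with columns transcript, count_a, count_b,
#'   true_effect.
#' @export
simulateCountTables <- function(n_transcripts, planted_log2_effects,
                                total_reads, seed, baseline_props = NULL) {
  if (total_reads <= 0) stop("total_reads must be > 0")
  if (any(!is.finite(planted_log2_effects)))
    stop("planted_log2_effects must be finite")
  stopifnot(length(planted_log2_effects) == n_transcripts)
  set.seed(seed)
  pA <- if (is.null(baseline_props)) {
    w <- stats::rgamma(n_transcripts, shape = 2); w / sum(w)
  } else baseline_props / sum(baseline_props)
  pB <- pA * 2^planted_log2_effects
  pB <- pB / sum(pB)
  data.frame(transcript = sprintf("tx_%03d", seq_len(n_transcripts)),
             count_a = as.integer(stats::rmultinom(1, total_reads, pA)),
             count_b = as.integer(stats::rmultinom(1, total_reads, pB)),
             true_effect = planted_log2_effects,
             stringsAsFactors = FALSE)
}

# phase offset (degrees) separating the two strands on the cylinder;
# arbitrary fixture constant, recorded in PDB REMARK output
HELIX_STRAND2_PHASE <- 150

#' Build an idealized helical coordinate model
#'
#' Places one tracked point per residue per strand on a cylinder: residue k
#' of strand 1 sits at angle k*twist and height k*rise; strand 2 runs
#' antiparallel at a fixed 150-degree phase offset, its residue pairing
#' strand-1 residue n_bp+1-j sharing that residue's height. The C5' and O3'
#' atoms of a residue are coincident in this idealization, so the chord
#' distance between residues n steps apart on one strand obeys
#' d(n) = sqrt((n*rise)^2 + (2*radius*sin(n*twist/2))^2).
#'
#' Residues 1..n_bp are strand 1 (5' arm), residues n_bp+1..2*n_bp continue
#' the chain back along strand 2 (3' arm), so the numbering matches a
#' hairpin read 5' to 3'.
#'
#' @param spec A \code{\link{helixSpec}}.
#' @param energy Optional model energy for ranking.
#' @return A \linkS4class{CoordinateModel} with 2*n_bp residues.
#' @export
buildHelixCoordinates <- function(spec, energy = NA_real_) {
  stopifnot(inherits(spec, "HelixSpec"))
  n <- spec$n_bp
  k1 <- seq_len(n)
  th1 <- k1 * spec$twist * pi / 180
  x1 <- spec$radius * cos(th1); y1 <- spec$radius * sin(th1)
  z1 <- k1 * spec$rise
  # strand 2 residue n + j pairs strand-1 residue n + 1 - j
  j <- seq_len(n)
  kp <- n + 1 - j
  th2 <- (kp * spec$twist + HELIX_STRAND2_PHASE) * pi / 180
  x2 <- spec$radius * cos(th2); y2 <- spec$radius * sin(th2)
  z2 <- kp * spec$rise
  resno <- rep(c(k1, n + j), each = 2)
  atoms <- data.frame(resno = resno,
                      atom = rep(c("C5'", "O3'"), times = 2 * n),
                      x = rep(c(x1, x2), each = 2),
                      y = rep(c(y1, y2), each = 2),
                      z = rep(c(z1, z2), each = 2),
                      stringsAsFactors = FALSE)
  new("CoordinateModel", atoms = atoms, energy = energy)
}

#' Apply a rigid motion or coordinate jitter to a model
#'
#' Utilities for building model ensembles: \code{rigidTransform} applies a
#' rotation matrix and translation; \code{jitterModel} adds isotropic
#' Gaussian noise of standard deviation \code{sd} Angstrom to every atom.
#'
#' @param model A \linkS4class{CoordinateModel}.
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation.
#' @return A transformed \linkS4class{CoordinateModel}.
#' @export
rigidTransform <- function(model, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model@atoms$x <- xyz[, 1]; model@atoms$y <- xyz[, 2]; model@atoms$z <- xyz[, 3]
  model
}

#' @rdname rigidTransform
#' @param sd Noise standard deviation in Angstrom.
#' @export
jitterModel <- function(model, sd = 0.5) {
  k <- nrow(model@atoms)
  model@atoms$x <- model@atoms$x + stats::rnorm(k, 0, sd)
  model@atoms$y <- model@atoms$y + stats::rnorm(k, 0, sd)
  model@atoms$z <- model@atoms$z + stats::rnorm(k, 0, sd)
  model
}

#' Simulate the three structure-profile archetypes
#'
#' Generates reactivity profiles mimicking the three substrate families the
#' clustering stage separates: (1) hairpin-like profiles with high
#' reactivity in the central +/-5 nt and low flanks (pre-miRNA-like), (2)
#' moderate centers with loose flanks (snoRNA-like), and (3) a
#' chessboard-like alternation (cloverleaf/tRNA-like). All transcripts are
#' 101-nt hairpins whose loop center sits at position 51, so the aligned
#' matrix has no missing columns. Gaussian noise of standard deviation
#' \code{noiseSd} is added per position.
#'
#' @param nPerClass Transcripts per archetype.
#' @param noiseSd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return List with \code{profiles} (named list of numeric vectors),
#'   \code{structures} (matched \linkS4class{SecondaryStructure} list) and
#'   \code{labels} (integer archetype of each transcript).
#' @export
simulateArchetypeProfiles <- function(nPerClass = 60L, noiseSd = 0.2,
                                      seed = 1L) {
  set.seed(seed)
  len <- 101L
  db <- paste0(strrep("(", 46L), strrep(".", 9L), strrep(")", 46L))
  d <- seq_len(len) - 51L      # distance from the loop center
  base <- list(
    ifelse(abs(d) <= 5, 1.5, 0.15),
    ifelse(abs(d) <= 5, 0.8, 0.45),
    0.7 + 0.5 * sin(d * pi / 4)
  )
  profiles <- list(); structures <- list(); labels <- integer(0)
  for (cls in 1:3) {
    for (i in seq_len(nPerClass)) {
      id <- sprintf("arch%d_%03d", cls, i)
      sq <- paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
      profiles[[id]] <- base[[cls]] + stats::rnorm(len, 0, noiseSd)
      structures[[id]] <- secondaryStructure(sq, db)
      labels <- c(labels, cls)
    }
  }
  list(profiles = profiles, structures = structures, labels = labels)
}

#' Simulate replicate mutation-count tables
#'
#' Draws a shared per-base true mutation rate (gamma-distributed), assigns
#' each base a sequencing coverage log-uniform over \code{covRange}, and
#' generates two independent binomial replicates. Used to study how the
#' replicate correlation of mutation rates grows with coverage.
#'
#' @param nBases Number of bases.
#' @param covRange Coverage range (log-uniform).
#' @param rateShape,rateRate Gamma parameters of the true rate
#'   distribution (defaults give mean 0.02).
#' @param seed Integer seed.
#' @return List of two \linkS4class{MutationCounts} plus the true rates.
#' @export
simulateReplicateCounts <- function(nBases = 3000L, covRange = c(300, 8000),
                                    rateShape = 4, rateRate = 200,
                                    seed = 1L) {
  set.seed(seed)
  rate <- pmin(stats::rgamma(nBases, shape = rateShape, rate = rateRate), 0.5)
  cov <- as.integer(round(10^stats::runif(nBases, log10(covRange[1]),
                                          log10(covRange[2]))))
  mk <- function(tag) {
    ev <- stats::rbinom(nBases, cov, rate)
    cnt <- matrix(0L, nBases, 8, dimnames = list(NULL, mutationClasses()))
    cnt[, "mismatch"] <- ev
    new("MutationCounts", transcript = tag, counts = cnt,
        coverage = cov)
  }
  list(rep1 = mk("rep1"), rep2 = mk("rep2"), rate = rate)
}
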