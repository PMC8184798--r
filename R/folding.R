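#' @include AllClasses.R structures.R energy-params.R
NULL

seqToCode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "T"] <- "U"
  code <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) stop("invalid characters in sequence (A/C/G/U/T only)")
  code
}

#' SHAPE-constrained minimum-free-energy folding
#'
#' Predicts the pseudoknot-free MFE structure of an RNA under the package's
#' nearest-neighbor energy model (see \code{\link{energyModel}}), optionally
#' restrained by a reactivity profile through the Deigan pseudo-energy
#' dG_SHAPE(i) = slope * ln(s_i + 1) + intercept added once for every paired
#' nucleotide. Negative reactivities are treated as 0 and missing ones
#' contribute nothing, so with no profile the prediction reduces to the
#' unconstrained MFE. Deterministic; ties are broken by a fixed search
#' order.
#'
#' @param sequence RNA sequence over A/C/G/U (T accepted).
#' @param profile Optional \linkS4class{ReactivityProfile} or numeric score
#'   vector of the same length.
#' @param params \code{\link{pseudoEnergyParams}} (slope 1.8, intercept
#'   -0.6 by default).
#' @param model Energy model from \code{\link{energyModel}}.
#' @return A \linkS4class{SecondaryStructure}; the optimal energy in
#'   kcal/mol is attached as attribute \code{"energy"}.
#' @export
#' @examples
#' s <- foldConstrained("GGGGAAAACCCC")
#' dotBracket(s)
#' attr(s, "energy")
foldConstrained <- function(sequence, profile = NULL,
                            params = pseudoEnergyParams(),
                            model = energyModel()) {
  n <- nchar(sequence)
  if (n < 8) stop("sequence shorter than 8 nt has no foldable structure")
  code <- seqToCode(sequence)
  pe <- if (is.null(profile)) rep(0, n) else {
    s <- if (is(profile, "ReactivityProfile")) reactivity(profile) else profile
    if (length(s) != n) stop("profile length must match the sequence")
    pseudoEnergies(s, params)
  }
  if (length(model$hairpin) < n) model <- energyModel(maxLen = n)
  res <- .foldDP(code, pe, model$stack, model$hairpin, model$bulge,
                 model$internal, model$ml_a, model$ml_b, model$ml_c,
                 model$max_loop, model$min_hairpin)
  out <- new("SecondaryStructure", sequence = toupper(chartr("T", "U", sequence)),
             pairTable = as.integer(res$pairs))
  attr(out, "energy") <- res$energy
  out
}

#' Score a structure under the folding energy model
#'
#' Loop-decomposition re-scoring of an explicit structure, independent of
#' the dynamic program: stacking terms for adjacent pairs, hairpin, bulge
#' and internal-loop penalties by unpaired size, affine multiloop cost, and
#' the pseudo-energy of every paired nucleotide. External (exterior-loop)
#' bases are free.
#'
#' @param sequence RNA sequence.
#' @param structure A \linkS4class{SecondaryStructure}, dot-bracket string
#'   or pair table.
#' @param profile Optional reactivity scores (vector or
#'   \linkS4class{ReactivityProfile}).
#' @param params \code{\link{pseudoEnergyParams}}.
#' @param model Energy model.
#' @return Total free energy, kcal/mol.
#' @export
structureEnergy <- function(sequence, structure, profile = NULL,
                            params = pseudoEnergyParams(),
                            model = energyModel()) {
  n <- nchar(sequence)
  pt <- if (is(structure, "SecondaryStructure")) pairTable(structure)
        else if (is.character(structure)) dotBracketToPairs(structure)
        else as.integer(structure)
  stopifnot(length(pt) == n)
  if (length(model$hairpin) < n) model <- energyModel(maxLen = max(400L, n))
  code <- seqToCode(sequence)
  pcode <- function(i, j) {
    a <- code[i]; b <- code[j]
    key <- paste0(c("A", "C", "G", "U")[a + 1], c("A", "C", "G", "U")[b + 1])
    m <- match(key, PAIR_NAMES)
    if (is.na(m)) stop("non-canonical pair ", key, " at (", i, ",", j, ")")
    m
  }
  pe <- if (is.null(profile)) rep(0, n) else {
    s <- if (is(profile, "ReactivityProfile")) reactivity(profile) else profile
    pseudoEnergies(s, params)
  }
  children <- function(i, j) {
    # pairs directly enclosed by (i, j); i = 0, j = n + 1 for external
    out <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (pt[k] > k) { out[[length(out) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    out
  }
  loopEnergy <- function(i, j) {
    # energy of the loop closed by (i, j) plus everything inside
    kids <- children(i, j)
    e <- pe[i] + pe[j]
    if (!length(kids)) {
      e <- e + model$hairpin[j - i - 1L]
    } else if (length(kids) == 1) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      u <- (k - i - 1L) + (j - l - 1L)
      e <- e + if (u == 0) model$stack[pcode(i, j), pcode(k, l)]
               else if (k == i + 1L || l == j - 1L) model$bulge[u]
               else model$internal[u]
      e <- e + loopEnergy(k, l)
    } else {
      u <- (j - i - 1L) - sum(vapply(kids, function(p) p[2] - p[1] + 1L, 1L))
      e <- e + model$ml_a + model$ml_b * (length(kids) + 1L) + model$ml_c * u
      for (p in kids) e <- e + loopEnergy(p[1], p[2])
    }
    e
  }
  top <- {
    out <- list(); k <- 1L
    while (k <= n) {
      if (pt[k] > k) { out[[length(out) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    out
  }
  sum(vapply(top, function(p) loopEnergy(p[1], p[2]), 1.0))
}

# ---- structure features ------------------------------------------------

hairpinLoops <- function(pt) {
  # spans (first..last unpaired nt) of all hairpin loops
  out <- list()
  for (i in which(pt > seq_along(pt))) {
    j <- pt[i]
    if (j - i - 1 >= 1 && all(pt[(i + 1):(j - 1)] == 0))
      out[[length(out) + 1L]] <- c(i + 1L, j - 1L)
  }
  out
}

#' Locate the central (terminal) hairpin loop
#'
#' Among all hairpin loops, selects the one whose loop center is nearest the
#' sequence midpoint; ties go to the larger loop, then to the 5'-most. This
#' is the loop used as the alignment anchor and as the terminal loop of
#' hairpin-like substrates.
#'
#' @param structure A \linkS4class{SecondaryStructure}.
#' @return Integer c(first, last) span of the loop, or NULL if the
#'   structure has no hairpin loop.
#' @export
centralLoop <- function(structure) {
  pt <- pairTable(structure)
  loops <- hairpinLoops(pt)
  if (!length(loops)) return(NULL)
  mid <- (length(pt) + 1) / 2
  centers <- vapply(loops, function(sp) (sp[1] + sp[2]) / 2, 1.0)
  sizes <- vapply(loops, function(sp) sp[2] - sp[1] + 1L, 1L)
  ord <- order(abs(centers - mid), -sizes,
               vapply(loops, `[`, 1L, 1))
  loops[[ord[1]]]
}

#' Extract secondary-structure features
#'
#' Finds the terminal loop (central-loop rule), splits the molecule into a
#' 5p arm (5' of the loop) and a 3p arm (3' of it), and classifies every
#' maximal single-stranded run as terminal loop, bulge (unpaired
#' nucleotides on one strand only, between two helices) or internal loop
#' (unpaired on both strands), with an arm label.
#'
#' @param structure A \linkS4class{SecondaryStructure}.
#' @return List with \code{terminal_loop} (list: span, size) and
#'   \code{single_stranded_regions} (data.frame: start, end, type, arm).
#' @export
extractFeatures <- function(structure) {
  pt <- pairTable(structure)
  n <- length(pt)
  tl <- centralLoop(structure)
  if (is.null(tl)) stop("structure has no hairpin loop")
  runs <- rle(pt == 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ss <- data.frame(start = starts[runs$values], end = ends[runs$values])
  type <- character(nrow(ss)); arm <- character(nrow(ss))
  for (r in seq_len(nrow(ss))) {
    a <- ss$start[r]; b <- ss$end[r]
    if (a == tl[1] && b == tl[2]) {
      type[r] <- "terminal-loop"; arm[r] <- "loop"
      next
    }
    arm[r] <- if (b < tl[1]) "5p-arm" else if (a > tl[2]) "3p-arm" else "loop"
    if (a == 1 || b == n) {
      type[r] <- "external"          # dangling end outside the outermost helix
      next
    }
    # one-sided (bulge) iff the flanking pairs close around the run on the
    # other strand with no unpaired partner-side gap
    left <- pt[a - 1L]; right <- pt[b + 1L]
    type[r] <- if (abs(left - right) == 1L) "bulge" else "internal-loop"
  }
  ss$type <- type; ss$arm <- arm
  list(terminal_loop = list(span = tl, size = tl[2] - tl[1] + 1L),
       single_stranded_regions = ss[ss$type != "external", , drop = FALSE])
}

#' Per-position comparison of two structures
#'
#' Classifies each position of two equal-length structures as identical
#' (same pairing state and partner), single-stranded in the first but
#' paired in the second, the opposite, or paired in both with different
#' partners.
#'
#' @param a,b \linkS4class{SecondaryStructure} objects of equal length.
#' @return Factor vector with levels \code{identical},
#'   \code{ss-in-a-paired-in-b}, \code{paired-in-a-ss-in-b},
#'   \code{both-paired-different-partner}.
#' @export
compareStructures <- function(a, b) {
  pa <- pairTable(a); pb <- pairTable(b)
  if (length(pa) != length(pb)) stop("structures have different lengths")
  cls <- ifelse(pa == pb, "identical",
         ifelse(pa == 0, "ss-in-a-paired-in-b",
         ifelse(pb == 0, "paired-in-a-ss-in-b",
                "both-paired-different-partner")))
  factor(cls, levels = c("identical", "ss-in-a-paired-in-b",
                         "paired-in-a-ss-in-b",
                         "both-paired-different-partner"))
}
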