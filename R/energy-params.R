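#' @useDynLib icShapeMaP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# 1.75 RT at 37 C (kcal/mol), used for logarithmic loop-size extrapolation
LOOP_EXTRAP_COEF <- 1.75 * 0.001987 * 310.15

buildStackTable <- function() {
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  # rows: closing pair (i,j); cols: stacked pair (i+1, j-1); kcal/mol,
  # Turner-style values for WC stacks, approximate values for GU wobbles
  m["AU", ] <- c(-0.93, -1.10, -2.24, -2.08, -0.55, -1.36)
  m["UA", ] <- c(-1.33, -0.93, -2.35, -2.11, -1.00, -1.27)
  m["CG", ] <- c(-2.11, -2.08, -3.26, -2.36, -1.41, -2.11)
  m["GC", ] <- c(-2.35, -2.24, -3.42, -3.26, -1.53, -2.51)
  m["GU", ] <- c(-1.27, -1.36, -2.51, -2.11, -0.50, 1.29)
  m["UG", ] <- c(-1.00, -0.55, -2.11, -1.41, 0.30, -0.50)
  # enforce the physical symmetry stack[(i,j)->(k,l)] == stack[(l,k)->(j,i)]
  revp <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  sym <- m
  for (p1 in PAIR_NAMES) for (p2 in PAIR_NAMES)
    sym[p1, p2] <- (m[p1, p2] + m[revp[p2], revp[p1]]) / 2
  sym
}

#' Energy parameters of the folding model
#'
#' The simplified nearest-neighbor model used by
#' \code{\link{foldConstrained}} and \code{\link{structureEnergy}}:
#' stacking free energies for the six pair types (Watson-Crick plus GU),
#' length-indexed hairpin/bulge/internal-loop initiation penalties with
#' logarithmic extrapolation beyond the tabulated sizes, and an affine
#' multiloop cost (closing penalty \code{ml_a}, per-branch \code{ml_b},
#' per-unpaired-nucleotide \code{ml_c}). Energies are kcal/mol at 37C. No
#' dangles, no coaxial stacking, no terminal-pair penalties.
#'
#' @param maxLen Longest loop size for which penalty vectors are
#'   precomputed.
#' @return List with elements stack (6x6 matrix), hairpin, bulge, internal
#'   (numeric vectors indexed by loop size), ml_a, ml_b, ml_c, max_loop,
#'   min_hairpin.
#' @export
energyModel <- function(maxLen = 400L) {
  # index s holds the penalty for a loop of s unpaired nucleotides;
  # beyond the tabulated sizes, extrapolate by 1.75 RT ln(s / s_max)
  sizeTable <- function(vals, minSize, n, forbidden = 1e7) {
    maxSize <- minSize + length(vals) - 1L
    s <- seq_len(n)
    out <- rep(forbidden, n)
    inTab <- s >= minSize & s <= maxSize
    out[inTab] <- vals[s[inTab] - minSize + 1L]
    beyond <- s > maxSize
    out[beyond] <- vals[length(vals)] +
      LOOP_EXTRAP_COEF * log(s[beyond] / maxSize)
    out
  }
  hp <- sizeTable(c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4), 3L, maxLen)
  bu <- sizeTable(c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4), 1L, maxLen)
  intp <- sizeTable(c(1.5, 1.6, 1.7, 2.0, 2.2, 2.3, 2.4, 2.5, 2.6), 2L, maxLen)
  list(stack = buildStackTable(),
       hairpin = hp,
       bulge = bu,
       internal = intp,
       ml_a = 3.4, ml_b = 0.4, ml_c = 0.0,
       max_loop = 30L, min_hairpin = 3L)
}

#' SHAPE pseudo-energy parameters
#'
#' Slope and intercept of the Deigan-style per-paired-nucleotide
#' pseudo-energy dG_SHAPE(i) = slope * ln(s_i + 1) + intercept (kcal/mol),
#' with negative reactivities treated as 0 and missing ones contributing
#' nothing. Defaults: slope 1.8, intercept -0.6.
#'
#' @param slope Slope m, kcal/mol.
#' @param intercept Intercept b, kcal/mol.
#' @return List with elements slope and intercept.
#' @export
pseudoEnergyParams <- function(slope = 1.8, intercept = -0.6) {
  list(slope = slope, intercept = intercept)
}

#' Per-nucleotide pseudo-energies from a reactivity profile
#'
#' @param score Numeric reactivity vector (NA allowed) or a
#'   \linkS4class{ReactivityProfile}.
#' @param params \code{\link{pseudoEnergyParams}}.
#' @return Numeric vector: slope * ln(max(s, 0) + 1) + intercept, 0 where s
#'   is NA. Applied once per paired nucleotide during folding.
#' @export
pseudoEnergies <- function(score, params = pseudoEnergyParams()) {
  if (is(score, "ReactivityProfile")) score <- reactivity(score)
  pe <- params$slope * log(pmax(score, 0) + 1) + params$intercept
  pe[is.na(score)] <- 0
  pe
}
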