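#' @import methods
NULL

#' The eight mutation event classes
#'
#' Reverse-transcription mutation events are classified into eight classes:
#' single mismatch, single-nucleotide insertion and deletion, their multi-
#' nucleotide homogeneous counterparts, and heterogeneous "complex" merged
#' events labelled by their net reference-length change.
#'
#' @return Character vector of the eight class names, in canonical order.
#' @export
#' @examples
#' mutationClasses()
mutationClasses <- function() {
  c("mismatch", "insertion", "deletion",
    "multi_mismatch", "multi_insertion", "multi_deletion",
    "complex_insertion", "complex_deletion")
}

#' Per-nucleotide mutation event counts for one transcript
#'
#' Holds, for every reference position of one transcript, the aligned read
#' coverage and the number of mutation events of each of the eight classes
#' whose 3'-most reference position falls there.
#'
#' @slot transcript Transcript identifier.
#' @slot counts Integer matrix, positions x eight event classes.
#' @slot coverage Integer vector of per-position aligned coverage.
#' @export
setClass("MutationCounts",
  representation(transcript = "character",
                 counts = "matrix",
                 coverage = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(colnames(object@counts), mutationClasses()))
      msg <- c(msg, "counts columns must be the eight mutation classes")
    if (nrow(object@counts) != length(object@coverage))
      msg <- c(msg, "counts rows must match coverage length")
    if (any(object@counts < 0) || any(object@coverage < 0))
      msg <- c(msg, "counts and coverage must be non-negative")
    if (any(rowSums(object@counts) > object@coverage))
      msg <- c(msg, "total events per position cannot exceed coverage")
    if (length(msg)) msg else TRUE
  })

#' Per-nucleotide reactivity profile
#'
#' Normalized NAI-minus-DMSO mutation-rate differences per nucleotide.
#' Masked (unreliable) positions are NA. The normalization factor is the
#' divisor applied to raw rate differences (NA before normalization or when
#' the profile could not be normalized).
#'
#' @slot transcript Transcript identifier.
#' @slot sequence Reference sequence (may be NA if unknown).
#' @slot score Numeric vector of reactivities, NA where masked.
#' @slot coverage Numeric vector of per-position coverage (minimum of the
#'   contributing libraries).
#' @slot normFactor Scalar normalization factor.
#' @export
setClass("ReactivityProfile",
  representation(transcript = "character",
                 sequence = "character",
                 score = "numeric",
                 coverage = "numeric",
                 normFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@score) != length(object@coverage))
      msg <- c(msg, "score and coverage lengths differ")
    if (!is.na(object@sequence) &&
        nchar(object@sequence) != length(object@score))
      msg <- c(msg, "sequence length must match score length")
    if (!is.na(object@normFactor) && object@normFactor <= 0)
      msg <- c(msg, "normFactor must be positive once defined")
    if (length(msg)) msg else TRUE
  })

#' Pseudoknot-free RNA secondary structure
#'
#' A sequence with its pair table: \code{pairTable[i]} is the 1-based partner
#' of position i, or 0 when unpaired. Pairing is an involution, no position
#' pairs with itself or its direct neighbor, and pairs nest (no
#' pseudoknots). Structures predicted by \code{\link{foldConstrained}}
#' additionally keep every hairpin loop at 3 nucleotides or more; imported
#' reference structures may carry smaller loops and are accepted.
#'
#' @slot sequence RNA sequence (A/C/G/U; T accepted on input and kept as-is).
#' @slot pairTable Integer partner vector (0 = unpaired).
#' @export
setClass("SecondaryStructure",
  representation(sequence = "character", pairTable = "integer"),
  validity = function(object) {
    n <- nchar(object@sequence)
    pt <- object@pairTable
    if (length(pt) != n) return("pairTable length must equal sequence length")
    if (any(pt < 0 | pt > n)) return("pairTable entries out of range")
    idx <- which(pt > 0)
    if (any(pt[idx] == idx)) return("a position cannot pair with itself")
    if (!all(pt[pt[idx]] == idx)) return("pairing must be an involution")
    if (any(abs(pt[idx] - idx) < 2))
      return("a pair must enclose at least one nucleotide")
    # pseudoknot-freedom: pairs must nest
    op <- idx[pt[idx] > idx]
    if (length(op) > 1) {
      for (i in op) {
        j <- pt[i]
        inner <- op[op > i & op < j]
        if (any(pt[inner] > j)) return("crossing pairs (pseudoknot) not allowed")
      }
    }
    TRUE
  })

#' RNA tertiary coordinate model
#'
#' Per-residue named-atom coordinates in Angstrom, with an optional model
#' energy used for ranking. Residue numbering is 1-based and aligned to the
#' transcript sequence. Legacy atom-name dialects (C5*/O3*) are normalized to
#' C5'/O3' on construction.
#'
#' @slot atoms data.frame with columns resno, atom, x, y, z.
#' @slot energy Scalar model energy (NA when unknown).
#' @export
setClass("CoordinateModel",
  representation(atoms = "data.frame", energy = "numeric"),
  validity = function(object) {
    need <- c("resno", "atom", "x", "y", "z")
    if (!all(need %in% names(object@atoms)))
      return("atoms must have columns resno, atom, x, y, z")
    if (any(object@atoms$resno < 1))
      return("residue numbers are 1-based")
    TRUE
  })

#' Pre-miRNA annotation
#'
#' A pre-miRNA hairpin with the 1-based inclusive spans of its 5p and 3p
#' mature miRNAs, plus the isoform end offsets considered in isoform
#' comparisons.
#'
#' @slot id Pre-miRNA identifier.
#' @slot sequence Pre-miRNA sequence.
#' @slot span5p Integer of length 2: first and last nt of the 5p miRNA.
#' @slot span3p Integer of length 2: first and last nt of the 3p miRNA.
#' @slot offsets Integer isoform end shifts (e.g. -1, 0, 1).
#' @export
setClass("MirnaAnnotation",
  representation(id = "character", sequence = "character",
                 span5p = "integer", span3p = "integer",
                 offsets = "integer"),
  validity = function(object) {
    n <- nchar(object@sequence)
    s5 <- object@span5p; s3 <- object@span3p
    if (length(s5) != 2 || length(s3) != 2)
      return("spans must have length 2 (first, last)")
    if (s5[1] > s5[2] || s3[1] > s3[2]) return("span start must not exceed end")
    if (s5[1] < 1 || s3[2] > n) return("spans must lie within the sequence")
    if (s5[2] >= s3[1]) return("5p span must lie entirely 5' of the 3p span")
    TRUE
  })

setMethod("show", "MutationCounts", function(object) {
  cat("MutationCounts for", object@transcript, "\n")
  cat(" positions:", length(object@coverage),
      " total events:", sum(object@counts),
      " median coverage:", stats::median(object@coverage), "\n")
})

setMethod("show", "ReactivityProfile", function(object) {
  ok <- sum(!is.na(object@score))
  cat("ReactivityProfile for", object@transcript, "\n")
  cat(" length:", length(object@score), " scored:", ok,
      " normFactor:", format(object@normFactor, digits = 4), "\n")
})

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure (", nchar(object@sequence), " nt, ",
      sum(object@pairTable > 0) / 2, " pairs)\n", sep = "")
  cat(" ", object@sequence, "\n ", dotBracket(object), "\n", sep = "")
})

setMethod("show", "CoordinateModel", function(object) {
  cat("CoordinateModel:", length(unique(object@atoms$resno)), "residues,",
      nrow(object@atoms), "atoms, energy:",
      format(object@energy, digits = 4), "\n")
})

setMethod("show", "MirnaAnnotation", function(object) {
  cat("MirnaAnnotation", object@id, "(", nchar(object@sequence), "nt )\n")
  cat(" 5p:", object@span5p[1], "-", object@span5p[2],
      " 3p:", object@span3p[1], "-", object@span3p[2], "\n")
})
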