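#' @include AllClasses.R folding.R
NULL

# distance target of the 3'/5' counting rules: the Dicer processing-center
# geometry places the cleavage site ~59 Angstrom from the bound terminus
DICING_TARGET_ANGSTROM <- 59
DICING_TOL_ANGSTROM <- 1

#' Construct a pre-miRNA annotation
#'
#' @param id Identifier.
#' @param sequence Pre-miRNA sequence.
#' @param span5p,span3p Integer c(first, last), 1-based inclusive spans of
#'   the mature 5p and 3p miRNAs.
#' @param offsets Isoform end shifts considered by
#'   \code{\link{compareIsoforms}}.
#' @return A \linkS4class{MirnaAnnotation}.
#' @export
mirnaAnnotation <- function(id, sequence, span5p, span3p,
                            offsets = c(-1L, 0L, 1L)) {
  new("MirnaAnnotation", id = id, sequence = toupper(sequence),
      span5p = as.integer(span5p), span3p = as.integer(span3p),
      offsets = as.integer(offsets))
}

atomXyz <- function(model, resno, atom) {
  a <- model@atoms
  hit <- which(a$resno == resno & a$atom == atom)
  if (!length(hit))
    stop("missing atom ", atom, " at residue ", resno)
  as.numeric(a[hit[1], c("x", "y", "z")])
}

#' Euclidean distance between two residue termini
#'
#' Distance in Angstrom between the C5' atom of \code{fromResidue} and the
#' O3' atom of \code{toResidue}.
#'
#' @param model A \linkS4class{CoordinateModel}.
#' @param fromResidue,toResidue 1-based residue indices.
#' @return Distance in Angstrom.
#' @export
terminusDistance <- function(model, fromResidue, toResidue) {
  sqrt(sum((atomXyz(model, fromResidue, "C5'") -
            atomXyz(model, toResidue, "O3'"))^2))
}

selectTopModels <- function(models, nTop = 50L) {
  if (length(models) <= nTop) return(models)
  energies <- vapply(models, modelEnergy, 1.0)
  if (anyNA(energies)) {
    warning("model energies absent: using all ", length(models), " models")
    return(models)
  }
  models[order(energies)[seq_len(nTop)]]
}

#' Median dicing distances over a model ensemble
#'
#' For each coordinate model, measures the four cleavage-geometry distances
#' and reports their medians: D_5p_miRNA (C5' of the pre-miRNA 5' end to O3'
#' of the last 5p-miRNA nucleotide), D_3p_miRNA (C5' of the first 3p-miRNA
#' nucleotide to O3' of the pre-miRNA 3' end), and the arm variants that
#' replace the miRNA boundary with the nucleotide adjacent to the terminal
#' loop. If more than 50 models are supplied the 50 lowest-energy models
#' are used (all models, with a warning, when energies are absent).
#'
#' @param models List of \linkS4class{CoordinateModel}.
#' @param annotation A \linkS4class{MirnaAnnotation}.
#' @param structure Optional \linkS4class{SecondaryStructure} supplying the
#'   terminal loop for the arm distances (NA otherwise).
#' @return Named numeric: D_5p_miRNA, D_3p_miRNA, D_5p_arm, D_3p_arm
#'   (Angstrom).
#' @export
dicingDistances <- function(models, annotation, structure = NULL) {
  if (!length(models)) stop("empty model list")
  models <- selectTopModels(models)
  n <- nchar(annotation@sequence)
  tl <- if (!is.null(structure)) centralLoop(structure) else NULL
  one <- function(m) {
    c(D_5p_miRNA = terminusDistance(m, 1L, annotation@span5p[2]),
      D_3p_miRNA = terminusDistance(m, annotation@span3p[1], n),
      D_5p_arm = if (!is.null(tl) && tl[1] > 1)
        terminusDistance(m, 1L, tl[1] - 1L) else NA_real_,
      D_3p_arm = if (!is.null(tl) && tl[2] < n)
        terminusDistance(m, tl[2] + 1L, n) else NA_real_)
  }
  vals <- vapply(models, one, numeric(4))
  apply(vals, 1, stats::median)
}

#' Loop-counting rule check
#'
#' 3p variant: for p, the first nucleotide of the 3p miRNA, the rule holds
#' iff positions p-1 and p-2 are paired and p-3 is single-stranded (exactly
#' two paired nucleotides between the nearest upstream single-stranded
#' region and the cleavage site, i.e. cleavage 2 nt downstream of a
#' bulge/loop). 5p variant (the 0-nt case of the same family): the position
#' immediately 3' of the last 5p-miRNA nucleotide is single-stranded.
#' Required positions falling outside the sequence make the rule FALSE.
#'
#' @param structure A \linkS4class{SecondaryStructure}.
#' @param annotation A \linkS4class{MirnaAnnotation} on the same sequence.
#' @return Named logical c(rule_3p, rule_5p).
#' @export
loopCountingCheck <- function(structure, annotation) {
  pt <- pairTable(structure)
  stopifnot(length(pt) == nchar(annotation@sequence))
  p <- annotation@span3p[1]
  rule3 <- if (p - 3 < 1) {
    message("rule_3p: positions upstream of the 3p cleavage site missing")
    FALSE
  } else pt[p - 1] > 0 && pt[p - 2] > 0 && pt[p - 3] == 0
  q <- annotation@span5p[2]
  rule5 <- if (q + 1 > length(pt)) {
    message("rule_5p: no position 3' of the 5p miRNA end")
    FALSE
  } else pt[q + 1] == 0
  c(rule_3p = rule3, rule_5p = rule5)
}

#' Classify a pre-miRNA by cleavage-site selection rules
#'
#' Membership triple (one Venn cell): 3'-counting iff |D_3p_miRNA - target|
#' <= tol, 5'-counting iff |D_5p_miRNA - target| <= tol, loop-counting iff
#' the 3p loop-counting rule holds. Defaults: target 59 Angstrom,
#' tolerance 1.
#'
#' @param distances Named numeric from \code{\link{dicingDistances}}.
#' @param loopCheck Named logical from \code{\link{loopCountingCheck}}.
#' @param target,tol Distance-rule target and tolerance (Angstrom).
#' @return Named logical c(loop_counting, three_prime_counting,
#'   five_prime_counting).
#' @export
classifyRules <- function(distances, loopCheck,
                          target = DICING_TARGET_ANGSTROM,
                          tol = DICING_TOL_ANGSTROM) {
  c(loop_counting = unname(loopCheck["rule_3p"]),
    three_prime_counting =
      !is.na(distances["D_3p_miRNA"]) &&
      abs(distances[["D_3p_miRNA"]] - target) <= tol,
    five_prime_counting =
      !is.na(distances["D_5p_miRNA"]) &&
      abs(distances[["D_5p_miRNA"]] - target) <= tol)
}

#' Compare 3p isoforms by dicing distance and expression
#'
#' For each isoform (an offset applied to the annotated 5' end of the 3p
#' miRNA), computes the median D_3p_miRNA over its model set, the deviation
#' from the target distance, and its expression share (reads over total
#' reads on the arm). Reports whether the annotated (offset 0) isoform
#' minimizes the deviation and the total expression share of isoforms
#' within target +/- tol.
#'
#' @param modelsByOffset Named list (names = offsets) of lists of
#'   \linkS4class{CoordinateModel}.
#' @param annotation A \linkS4class{MirnaAnnotation}.
#' @param counts Named numeric of per-isoform read counts (names =
#'   offsets).
#' @param target,tol Distance target and tolerance (Angstrom).
#' @return List with \code{table} (offset, d3p, deviation, share),
#'   \code{annotated_closest} and \code{in_range_share}.
#' @export
compareIsoforms <- function(modelsByOffset, annotation, counts,
                            target = DICING_TARGET_ANGSTROM,
                            tol = DICING_TOL_ANGSTROM) {
  if (length(modelsByOffset) < 2) stop("need >= 2 isoforms")
  offs <- names(modelsByOffset)
  counts <- counts[offs]
  if (anyNA(counts) || sum(counts) <= 0) stop("zero or missing isoform counts")
  n <- nchar(annotation@sequence)
  d3p <- vapply(offs, function(o) {
    p <- annotation@span3p[1] + as.integer(o)
    models <- selectTopModels(modelsByOffset[[o]])
    stats::median(vapply(models, terminusDistance, 1.0,
                         fromResidue = p, toResidue = n))
  }, 1.0)
  share <- as.numeric(counts) / sum(counts)
  tab <- data.frame(offset = as.integer(offs), d3p = d3p,
                    deviation = abs(d3p - target), share = share,
                    row.names = NULL)
  list(table = tab,
       annotated_closest =
         tab$offset[which.min(tab$deviation)] == 0L,
       in_range_share = sum(tab$share[tab$deviation <= tol]))
}

#' Tabulate rule membership for a set of pre-miRNAs
#'
#' Runs \code{\link{dicingDistances}}, \code{\link{loopCountingCheck}} and
#' \code{\link{classifyRules}} per pre-miRNA and assembles the per-substrate
#' rule table (distances, loop flags, Venn cell).
#'
#' @param modelSets Named list of model lists, one per pre-miRNA.
#' @param annotations Matched named list of \linkS4class{MirnaAnnotation}.
#' @param structures Matched named list of
#'   \linkS4class{SecondaryStructure}.
#' @param target,tol Distance-rule parameters.
#' @return data.frame, one row per pre-miRNA.
#' @export
ruleTable <- function(modelSets, annotations, structures,
                      target = DICING_TARGET_ANGSTROM,
                      tol = DICING_TOL_ANGSTROM) {
  ids <- names(modelSets)
  rows <- lapply(ids, function(id) {
    d <- dicingDistances(modelSets[[id]], annotations[[id]], structures[[id]])
    lc <- loopCountingCheck(structures[[id]], annotations[[id]])
    cls <- classifyRules(d, lc, target = target, tol = tol)
    data.frame(pre_mirna = id, t(d), rule_3p = lc[["rule_3p"]],
               rule_5p = lc[["rule_5p"]],
               loop_counting = cls[["loop_counting"]],
               three_prime_counting = cls[["three_prime_counting"]],
               five_prime_counting = cls[["five_prime_counting"]],
               venn_cell = paste0(as.integer(cls), collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a pre-miRNA annotation TSV
#'
#' Columns: id, sequence, start_5p, end_5p, start_3p, end_3p and optionally
#' offsets (comma-separated integers).
#'
#' @param path TSV path.
#' @return Named list of \linkS4class{MirnaAnnotation}.
#' @export
readMirnaAnnotationTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    offs <- if ("offsets" %in% names(tab))
      as.integer(strsplit(as.character(tab$offsets[i]), ",")[[1]])
    else c(-1L, 0L, 1L)
    mirnaAnnotation(tab$id[i], tab$sequence[i],
                    c(tab$start_5p[i], tab$end_5p[i]),
                    c(tab$start_3p[i], tab$end_3p[i]), offs)
  })
  stats::setNames(out, tab$id)
}
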