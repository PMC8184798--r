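#' @include AllClasses.R
NULL

normalizeAtomName <- function(x) {
  # accept legacy PDB dialects C5* / O3*
  x <- gsub("\\*", "'", trimws(x))
  x
}

#' Write coordinate models as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per coordinate model; each model's energy (when
#' known) is recorded on a \code{REMARK 250 ENERGY} line inside its block.
#' Atom names use the C5'/O3' dialect; residues are 1-based, chain A.
#'
#' @param models List of \linkS4class{CoordinateModel}.
#' @param path Output path (.pdb).
#' @return The path, invisibly.
#' @export
writePdbModels <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK 250 IDEALIZED COORDINATE MODELS", con)
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    e <- modelEnergy(models[[m]])
    if (!is.na(e)) writeLines(sprintf("REMARK 250 ENERGY %.4f", e), con)
    a <- models[[m]]@atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)), a$atom, "  N", "A", a$resno, a$x, a$y, a$z, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coordinate models from a PDB file
#'
#' Multi-model files are split on MODEL records (a file without MODEL
#' records yields one model). Coordinates are parsed with bio3d; per-model
#' \code{REMARK 250 ENERGY} lines, when present, populate the model
#' energies. C5*/O3* atom names are normalized to C5'/O3'.
#'
#' @param path PDB path.
#' @return List of \linkS4class{CoordinateModel}.
#' @export
readPdbModels <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    stopifnot(length(ends) == length(starts))
    Map(function(s, e) lines[s:e], starts, ends)
  } else list(lines)
  lapply(blocks, function(bl) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(bl[!grepl("^(MODEL|ENDMDL)", bl)], "END"), tmp)
    pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
    unlink(tmp)
    atoms <- data.frame(resno = pdb$atom$resno,
                        atom = normalizeAtomName(pdb$atom$elety),
                        x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
                        stringsAsFactors = FALSE)
    eLine <- grep("^REMARK 250 ENERGY", bl, value = TRUE)
    e <- if (length(eLine))
      as.numeric(sub("^REMARK 250 ENERGY\\s+", "", eLine[1])) else NA_real_
    new("CoordinateModel", atoms = atoms, energy = e)
  })
}
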