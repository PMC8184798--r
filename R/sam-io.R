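#' Write an in-memory aligned read table as SAM
#'
#' Emits a minimal, valid SAM file (with \code{@HD} and \code{@SQ} header
#' lines) from a read table as produced by \code{\link{simulateMapReads}}.
#'
#' @param reads data.frame with columns qname, flag, rname, pos, mapq,
#'   cigar, seq.
#' @param refLengths Named integer vector of reference lengths, one per
#'   reference named in \code{rname}.
#' @param path Output path (.sam).
#' @return The path, invisibly.
#' @export
writeSamReads <- function(reads, refLengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                     as.integer(refLengths)), con)
  if (nrow(reads)) {
    qual <- vapply(nchar(reads$seq), function(k) strrep("I", k), "")
    # SAM stores DNA bases: U is written as T (normalized back on read)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       reads$qname, as.integer(reads$flag), reads$rname,
                       as.integer(reads$pos), as.integer(reads$mapq),
                       reads$cigar, chartr("Uu", "Tt", reads$seq), qual), con)
  }
  invisible(path)
}

#' Read aligned reads from a SAM (or BAM) file
#'
#' SAM input is converted to BAM in a temporary directory via Rsamtools and
#' scanned; coordinate- or name-sorted input is accepted. Returns the fields
#' the mutation profiler needs.
#'
#' @param path Path to a .sam or .bam file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   seq.
#' @export
readSamReads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar,
             seq = as.character(res$seq), stringsAsFactors = FALSE)
}

#' Read or write reference sequences as FASTA
#'
#' Thin wrappers over Biostrings for the package's reference sets.
#'
#' @param path FASTA path.
#' @return \code{readReferenceFasta}: named character vector of sequences.
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname readReferenceFasta
#' @param seqs Named character vector of sequences.
#' @export
writeReferenceFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
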