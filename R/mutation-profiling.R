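#' @include AllClasses.R
NULL

# default merge distance: consecutive primitive events separated by <= 2
# matched reference bases merge into one multi-/complex- event
DEFAULT_MERGE_SPACER <- 2L

cigarOps <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# right-align a deletion window [a, b] on the reference (3'-most equivalent
# placement in a repeat), without crossing the aligned end
rightAlignDeletion <- function(a, b, refChars, alignedEnd) {
  while (b + 1L <= alignedEnd && refChars[b + 1L] == refChars[a]) {
    a <- a + 1L; b <- b + 1L
  }
  c(a, b)
}

classifyEventGroup <- function(group) {
  types <- group$type
  if (all(types == "mismatch")) {
    if (length(types) == 1) "mismatch" else "multi_mismatch"
  } else if (all(types == "insertion")) {
    if (length(types) == 1 && group$ins[1] == 1) "insertion" else "multi_insertion"
  } else if (all(types == "deletion")) {
    if (length(types) == 1 && group$del[1] == 1) "deletion" else "multi_deletion"
  } else {
    net <- sum(group$ins) - sum(group$del)
    if (net > 0) "complex_insertion"
    else if (net < 0) "complex_deletion"
    else "multi_mismatch"
  }
}

emptyEventFrame <- function() {
  data.frame(mtype = character(), ref_position = integer(),
             ref_span = integer(), read_bases = character(),
             stringsAsFactors = FALSE)
}

mergePrimitives <- function(prim, mergeSpacer) {
  if (is.null(prim) || !nrow(prim)) return(emptyEventFrame())
  prim <- prim[order(prim$left, prim$right), , drop = FALSE]
  grp <- integer(nrow(prim)); g <- 1L; grp[1] <- 1L
  if (nrow(prim) > 1) {
    for (k in 2:nrow(prim)) {
      gap <- prim$left[k] - max(prim$right[which(grp[seq_len(k - 1)] == g)]) - 1L
      if (gap <= mergeSpacer) grp[k] <- g else { g <- g + 1L; grp[k] <- g }
    }
  }
  out <- lapply(split(prim, grp), function(gd) {
    cls <- classifyEventGroup(gd)
    pureIns <- all(gd$type == "insertion")
    data.frame(mtype = cls,
               ref_position = max(gd$right),
               ref_span = if (pureIns) 0L else max(gd$right) - min(gd$left) + 1L,
               read_bases = paste(gd$bases, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$ref_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse the mutation events of one aligned read
#'
#' Walks the CIGAR against the reference, collects primitive events
#' (per-base mismatches, insertion ops, deletion ops), right-aligns
#' ambiguous deletions to their 3'-most placement, merges events separated
#' by at most \code{mergeSpacer} matched reference bases, and classifies
#' each merged event into one of the eight classes (see
#' \code{\link{mutationClasses}}). Multi-nucleotide events report their
#' 3'-most reference position, consistent with reverse-transcriptase
#' misincorporation at the modified nucleotide. A pure insertion is anchored
#' at the reference base 5' of the inserted bases and has ref_span 0.
#'
#' @param read One-row data.frame (or list) with pos, cigar, seq.
#' @param reference Reference sequence the read is aligned to.
#' @param mergeSpacer Maximum matched-base gap merged across (default 2).
#' @return data.frame with columns mtype, ref_position, ref_span,
#'   read_bases, ordered 5' to 3'.
#' @export
#' @examples
#' read <- data.frame(pos = 1, cigar = "5M2D5M", seq = "ACGUAACGUA")
#' parseReadMutations(read, "ACGUACCAACGUA")
parseReadMutations <- function(read, reference,
                               mergeSpacer = DEFAULT_MERGE_SPACER) {
  ops <- cigarOps(read$cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  if (qlen != nchar(read$seq))
    stop("CIGAR/sequence length mismatch for read ",
         if (!is.null(read$qname)) read$qname else "<unnamed>")
  if (any(ops$op == "N"))
    stop("spliced (N) alignments are not supported (read ",
         if (!is.null(read$qname)) read$qname else "<unnamed>", ")")
  # compare in a single alphabet: SAM reads are DNA, references may be RNA
  refChars <- strsplit(chartr("Tt", "UU", toupper(reference)), "")[[1]]
  readChars <- strsplit(chartr("Tt", "UU", toupper(read$seq)), "")[[1]]
  refPos <- as.integer(read$pos); readPos <- 1L
  alignedEnd <- as.integer(read$pos) +
    sum(ops$len[ops$op %in% c("M", "D", "=", "X")]) - 1L
  if (alignedEnd > length(refChars))
    stop("alignment extends past the reference for read ",
         if (!is.null(read$qname)) read$qname else "<unnamed>")
  prim <- list()
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      rr <- refPos:(refPos + len - 1L)
      qq <- readPos:(readPos + len - 1L)
      mm <- which(readChars[qq] != refChars[rr])
      for (i in mm) {
        prim[[length(prim) + 1L]] <- data.frame(
          type = "mismatch", left = rr[i], right = rr[i], ins = 0L, del = 0L,
          bases = readChars[qq[i]], stringsAsFactors = FALSE)
      }
      refPos <- refPos + len; readPos <- readPos + len
    } else if (op == "I") {
      prim[[length(prim) + 1L]] <- data.frame(
        type = "insertion", left = refPos - 1L, right = refPos - 1L,
        ins = len, del = 0L,
        bases = paste(readChars[readPos:(readPos + len - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
      readPos <- readPos + len
    } else if (op == "D") {
      ab <- rightAlignDeletion(refPos, refPos + len - 1L, refChars, alignedEnd)
      prim[[length(prim) + 1L]] <- data.frame(
        type = "deletion", left = ab[1], right = ab[2], ins = 0L, del = len,
        bases = "", stringsAsFactors = FALSE)
      refPos <- refPos + len
    } else if (op == "S") {
      readPos <- readPos + len    # soft clips: neither events nor coverage
    } else if (op == "H") {
      # hard clips consume nothing
    } else stop("unsupported CIGAR op ", op)
  }
  mergePrimitives(do.call(rbind, prim), mergeSpacer)
}

alignedRefLength <- function(cigar) {
  ops <- cigarOps(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
}

#' Count mutation events and coverage over a reference
#'
#' Aggregates \code{\link{parseReadMutations}} over a read set: per-position
#' aligned coverage (reads whose alignment spans the position; soft clips do
#' not count) and per-position event counts by class, each event counted at
#' its 3'-most reference position. Reads with mapping quality 0 or with
#' secondary/supplementary flags are excluded.
#'
#' @param reads data.frame of aligned reads (qname, flag, pos, mapq, cigar,
#'   seq).
#' @param reference Reference sequence.
#' @param transcript Transcript identifier stored in the result.
#' @param minMapq Minimum mapping quality (reads below are excluded;
#'   default 1, i.e. mapq 0 excluded).
#' @param mergeSpacer Merge distance passed to the parser.
#' @return A \linkS4class{MutationCounts}.
#' @export
countMutations <- function(reads, reference, transcript = "ref",
                           minMapq = 1L,
                           mergeSpacer = DEFAULT_MERGE_SPACER) {
  n <- nchar(reference)
  cov <- integer(n)
  cnt <- matrix(0L, nrow = n, ncol = 8,
                dimnames = list(NULL, mutationClasses()))
  if (nrow(reads)) {
    keep <- reads$mapq >= minMapq &
      bitwAnd(reads$flag, 0x100L) == 0L & bitwAnd(reads$flag, 0x800L) == 0L
    reads <- reads[keep, , drop = FALSE]
  }
  if (!nrow(reads)) {
    return(new("MutationCounts", transcript = transcript, counts = cnt,
               coverage = cov))
  }
  reference <- chartr("Tt", "UU", toupper(reference))
  reads$seq <- chartr("Tt", "UU", toupper(reads$seq))
  refInt <- utf8ToInt(reference)
  pureM <- grepl("^\\d+M$", reads$cigar)
  # coverage via difference array
  refLens <- integer(nrow(reads))
  refLens[pureM] <- as.integer(sub("M$", "", reads$cigar[pureM]))
  if (any(!pureM))
    refLens[!pureM] <- vapply(reads$cigar[!pureM], alignedRefLength, 1L)
  starts <- reads$pos
  ends <- starts + refLens - 1L
  if (any(ends > n)) stop("a read extends past the reference")
  tab1 <- tabulate(starts, nbins = n)
  tab2 <- tabulate(ends + 1L, nbins = n + 1L)
  cov <- cumsum(tab1 - tab2[seq_len(n)])
  addEvents <- function(ev) {
    if (!nrow(ev)) return()
    for (r in seq_len(nrow(ev)))
      cnt[ev$ref_position[r], ev$mtype[r]] <<- cnt[ev$ref_position[r], ev$mtype[r]] + 1L
  }
  # fast path: pure-M reads, mismatches only
  idxM <- which(pureM)
  for (i in idxM) {
    span <- starts[i]:ends[i]
    mm <- span[utf8ToInt(reads$seq[i]) != refInt[span]]
    if (!length(mm)) next
    prim <- data.frame(type = "mismatch", left = mm, right = mm,
                       ins = 0L, del = 0L,
                       bases = strsplit(reads$seq[i], "")[[1]][mm - starts[i] + 1L],
                       stringsAsFactors = FALSE)
    addEvents(mergePrimitives(prim, mergeSpacer))
  }
  for (i in which(!pureM)) {
    addEvents(parseReadMutations(reads[i, ], reference, mergeSpacer))
  }
  out <- new("MutationCounts", transcript = transcript, counts = cnt,
             coverage = as.integer(cov))
  stopifnot(sum(cov) == sum(refLens))   # coverage conservation
  out
}

#' Per-position mutation rate
#'
#' Rate = (sum of all eight event-class counts) / coverage per position, NA
#' where coverage falls below \code{minCoverage}.
#'
#' @param counts A \linkS4class{MutationCounts}.
#' @param minCoverage Minimum coverage (positions below become NA).
#' @return Numeric vector of rates with NA at masked positions.
#' @export
mutationRate <- function(counts, minCoverage = 1L) {
  stopifnot(minCoverage >= 1)
  ev <- rowSums(eventCounts(counts))
  cov <- positionCoverage(counts)
  ifelse(cov >= minCoverage, ev / cov, NA_real_)
}

#' Combine replicate mutation counts
#'
#' Final scores combine replicates by summing event counts and coverages
#' before the rate calculation (not by averaging rates afterwards).
#'
#' @param countsList List of \linkS4class{MutationCounts} for the same
#'   transcript.
#' @return A single \linkS4class{MutationCounts}.
#' @export
combineReplicates <- function(countsList) {
  stopifnot(length(countsList) >= 1)
  out <- countsList[[1]]
  for (x in countsList[-1]) {
    stopifnot(length(positionCoverage(x)) == length(positionCoverage(out)))
    out@counts <- out@counts + x@counts
    out@coverage <- out@coverage + x@coverage
  }
  out
}

#' Read or write per-position mutation-count tables
#'
#' TSV layout: transcript, position (1-based), coverage, then one column per
#' event class.
#'
#' @param countsList Named list of \linkS4class{MutationCounts}.
#' @param path Output path.
#' @export
writeMutationCountsTsv <- function(countsList, path) {
  rows <- lapply(countsList, function(x) {
    data.frame(transcript = transcriptId(x),
               position = seq_along(positionCoverage(x)),
               coverage = positionCoverage(x),
               eventCounts(x), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMutationCountsTsv
#' @return \code{readMutationCountsTsv}: named list of
#'   \linkS4class{MutationCounts}.
#' @export
readMutationCountsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$transcript), function(d) {
    d <- d[order(d$position), ]
    cnt <- as.matrix(d[, mutationClasses()])
    dimnames(cnt) <- list(NULL, mutationClasses())
    storage.mode(cnt) <- "integer"
    new("MutationCounts", transcript = d$transcript[1], counts = cnt,
        coverage = as.integer(d$coverage))
  })
}

#' Profile a SAM file against a reference FASTA
#'
#' Convenience wrapper: reads the alignments and the references and returns
#' one \linkS4class{MutationCounts} per reference.
#'
#' @param samPath SAM/BAM path.
#' @param fastaPath Reference FASTA path.
#' @param minMapq,mergeSpacer Passed to \code{\link{countMutations}}.
#' @return Named list of \linkS4class{MutationCounts}.
#' @export
profileSam <- function(samPath, fastaPath, minMapq = 1L,
                       mergeSpacer = DEFAULT_MERGE_SPACER) {
  refs <- readReferenceFasta(fastaPath)
  reads <- readSamReads(samPath)
  out <- list()
  for (id in names(refs)) {
    sub <- reads[reads$rname == id, , drop = FALSE]
    out[[id]] <- countMutations(sub, refs[[id]], transcript = id,
                                minMapq = minMapq, mergeSpacer = mergeSpacer)
  }
  out
}
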