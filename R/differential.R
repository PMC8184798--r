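#' Build a condition count table
#'
#' A per-transcript mapped-read count vector for one condition, with its
#' total. The total is the table's own sum unless an explicit library total
#' is supplied.
#'
#' @param counts Named numeric vector (or data.frame with columns
#'   transcript, count) of mapped-read counts.
#' @param label Condition label, e.g. "RIP", "input", "dead", "WT".
#' @param total Library total (defaults to \code{sum(counts)}).
#' @return List of class \code{ConditionCounts}.
#' @export
conditionCounts <- function(counts, label = "condition", total = NULL) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$count, counts$transcript)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(total)) total <- sum(counts)
  structure(list(counts = counts, label = label, total = total),
            class = "ConditionCounts")
}

logRatioScore <- function(a, b, pseudocount = 0) {
  txs <- union(names(a$counts), names(b$counts))
  ca <- stats::setNames(rep(0, length(txs)), txs)
  cb <- ca
  ca[names(a$counts)] <- a$counts
  cb[names(b$counts)] <- b$counts
  if (a$total <= 0 || b$total <= 0) stop("condition totals must be > 0")
  score <- rep(NA_real_, length(txs))
  if (pseudocount > 0) {
    # non-canonical exploration mode: no transcript is nulled
    score <- log2(((ca + pseudocount) / a$total) /
                  ((cb + pseudocount) / b$total))
  } else {
    ok <- ca > 0 & cb > 0
    score[ok] <- log2((ca[ok] / a$total) / (cb[ok] / b$total))
    nzero <- sum(!ok)
    if (nzero)
      message(nzero,
              " transcript(s) with a zero count in either condition: score set to NA")
  }
  stats::setNames(score, txs)
}

#' RIP enrichment score per transcript
#'
#' score_i = log2( (RIP_i / RIP_total) / (input_i / input_total) ).
#' Transcripts with a zero count in either condition (including transcripts
#' absent from one table) get NA rather than +/-Inf, and are logged.
#'
#' @param rip,input \code{\link{conditionCounts}} for the RIP and
#'   input/DMSO libraries.
#' @param pseudocount Optional pseudocount added to every transcript before
#'   the ratio. The canonical score uses 0 (zero-count transcripts are NA);
#'   positive values are an exploration mode only.
#' @return Named numeric vector of log2 enrichment scores.
#' @export
#' @examples
#' rip <- conditionCounts(c(a = 40, b = 960), "RIP")
#' inp <- conditionCounts(c(a = 10, b = 990), "input")
#' enrichmentScore(rip, inp)["a"]
enrichmentScore <- function(rip, input, pseudocount = 0)
  logRatioScore(rip, input, pseudocount)

#' Dicer cleavage score per transcript
#'
#' score_i = log2( (Dead_i / Dead_total) / (WT_i / WT_total) ): the log2
#' change in a transcript's read proportion between catalytic-dead and
#' wild-type Dicer cells. Higher scores indicate stronger Dicer cleavage.
#'
#' @param dead,wt \code{\link{conditionCounts}} for the catalytic-dead and
#'   wild-type libraries.
#' @inheritParams enrichmentScore
#' @return Named numeric vector of log2 cleavage scores.
#' @export
cleavageScore <- function(dead, wt, pseudocount = 0)
  logRatioScore(dead, wt, pseudocount)

#' Classify enriched transcripts
#'
#' Membership iff score > 0 (strictly); NA scores are excluded from both the
#' enriched and non-enriched sets.
#'
#' @param scores Named numeric vector of enrichment (or cleavage) scores.
#' @return Character vector of enriched transcript names.
#' @export
classifyEnriched <- function(scores) {
  names(scores)[!is.na(scores) & scores > 0]
}

#' Score two count-table TSVs
#'
#' Reads two TSVs with columns \code{transcript} and \code{count}, scores
#' them, and returns (optionally writes) a result table.
#'
#' @param pathA,pathB Input TSVs for the numerator and denominator
#'   condition.
#' @param out Optional output TSV path.
#' @return data.frame with transcript, count_a, count_b, score, enriched.
#' @export
scoreCountTables <- function(pathA, pathB, out = NULL) {
  a <- utils::read.table(pathA, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  b <- utils::read.table(pathB, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ca <- conditionCounts(a, "A")
  cb <- conditionCounts(b, "B")
  score <- logRatioScore(ca, cb)
  txs <- names(score)
  countOf <- function(cc) {
    v <- stats::setNames(rep(0, length(txs)), txs)
    v[names(cc$counts)] <- cc$counts
    v
  }
  res <- data.frame(transcript = txs, count_a = countOf(ca),
                    count_b = countOf(cb), score = score,
                    enriched = !is.na(score) & score > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
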