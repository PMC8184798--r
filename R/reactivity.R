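#' @include AllClasses.R mutation-profiling.R
NULL

#' Raw reactivity: NAI minus DMSO mutation rate
#'
#' The raw per-position score is the difference between the mutation rate in
#' the NAI library and in the DMSO control; NA in either input propagates.
#' Negative values are preserved at this stage.
#'
#' @param naiRate,dmsoRate Equal-length numeric rate vectors (NA allowed).
#' @return Numeric vector of raw scores.
#' @export
#' @examples
#' rawReactivity(c(0.05, 0.02), c(0.01, 0.02))
rawReactivity <- function(naiRate, dmsoRate) {
  if (length(naiRate) != length(dmsoRate))
    stop("rate vectors must have equal length")
  naiRate - dmsoRate
}

# boxplot normalization constants: values above Q3 + 1.5 IQR are excluded
# (at most 10% of non-null values), f = mean of the top 10% of the remainder
NORM_OUTLIER_IQR_MULT <- 1.5
NORM_MAX_EXCLUDED_FRAC <- 0.10
NORM_TOP_FRAC <- 0.10

#' Boxplot normalization factor of a raw score vector
#'
#' Excludes outliers above Q3 + 1.5*IQR (capping exclusions at 10% of the
#' non-null values, dropping the largest first), then returns the mean of
#' the top 10% of the remainder.
#'
#' @param raw Numeric vector of raw scores (NA ignored).
#' @return The scalar normalization factor.
#' @export
normalizationFactor <- function(raw) {
  x <- raw[!is.na(raw)]
  if (length(x) < 10) stop("need >= 10 non-null positions to normalize")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  hi <- q[2] + NORM_OUTLIER_IQR_MULT * (q[2] - q[1])
  out <- which(x > hi)
  cap <- floor(NORM_MAX_EXCLUDED_FRAC * length(x))
  if (length(out) > cap)
    out <- out[order(x[out], decreasing = TRUE)[seq_len(cap)]]
  keep <- if (length(out)) x[-out] else x
  nTop <- max(1L, ceiling(NORM_TOP_FRAC * length(keep)))
  mean(sort(keep, decreasing = TRUE)[seq_len(nTop)])
}

#' Normalize a raw score vector into a ReactivityProfile
#'
#' Divides raw scores by the boxplot normalization factor so that the mean
#' of the top 10% of post-exclusion scores equals 1. If fewer than 10
#' positions are usable, or the factor is not positive (e.g. an all-zero
#' profile), the profile is emitted fully NA with a warning and an undefined
#' factor.
#'
#' @param raw Numeric vector of raw scores (NA where unavailable).
#' @param transcript Identifier stored in the profile.
#' @param sequence Optional reference sequence.
#' @param coverage Optional per-position coverage (0 when unknown).
#' @return A \linkS4class{ReactivityProfile}.
#' @export
normalizeProfile <- function(raw, transcript = "tx", sequence = NA_character_,
                             coverage = NULL) {
  n <- length(raw)
  if (is.null(coverage)) coverage <- rep(0, n)
  fail <- function(why) {
    warning("profile ", transcript, " not normalized: ", why)
    new("ReactivityProfile", transcript = transcript, sequence = sequence,
        score = rep(NA_real_, n), coverage = as.numeric(coverage),
        normFactor = NA_real_)
  }
  if (sum(!is.na(raw)) < 10) return(fail("fewer than 10 usable positions"))
  f <- normalizationFactor(raw)
  if (!is.finite(f) || f <= 0) return(fail("non-positive normalization factor"))
  new("ReactivityProfile", transcript = transcript, sequence = sequence,
      score = raw / f, coverage = as.numeric(coverage), normFactor = f)
}

#' Mask unreliable profile positions
#'
#' Positions whose coverage is below \code{minCoverage}, or whose DMSO
#' mutation rate exceeds \code{maxBackground} (endogenous-modification-like
#' sites such as m1A), become NA; everything else is unchanged. The default
#' coverage threshold of 1000x reflects well-covered transcripts; 2000x
#' gives very high-quality scores at higher sequencing cost.
#'
#' @param profile A \linkS4class{ReactivityProfile}.
#' @param minCoverage Minimum coverage (default 1000).
#' @param dmsoRate Optional per-position DMSO rate vector.
#' @param maxBackground Maximum tolerated DMSO rate (default 0.05).
#' @return The masked \linkS4class{ReactivityProfile}.
#' @export
maskProfile <- function(profile, minCoverage = 1000, dmsoRate = NULL,
                        maxBackground = 0.05) {
  stopifnot(minCoverage > 0, maxBackground > 0)
  s <- profile@score
  s[profile@coverage < minCoverage] <- NA_real_
  if (!is.null(dmsoRate)) {
    stopifnot(length(dmsoRate) == length(s))
    s[!is.na(dmsoRate) & dmsoRate > maxBackground] <- NA_real_
  }
  profile@score <- s
  profile
}

#' Score a transcript from NAI and DMSO mutation counts
#'
#' The full per-transcript scoring path: replicate counts are summed,
#' rates computed, the NAI-minus-DMSO difference normalized, and unreliable
#' positions masked. Coverage stored in the profile is the per-position
#' minimum of the combined NAI and DMSO coverage.
#'
#' @param nai,dmso \linkS4class{MutationCounts} or lists of replicate
#'   \linkS4class{MutationCounts}.
#' @param sequence Optional reference sequence.
#' @param minCoverage,maxBackground Masking thresholds (see
#'   \code{\link{maskProfile}}).
#' @return A \linkS4class{ReactivityProfile}.
#' @export
scoreTranscript <- function(nai, dmso, sequence = NA_character_,
                            minCoverage = 1000, maxBackground = 0.05) {
  if (is(nai, "MutationCounts")) nai <- list(nai)
  if (is(dmso, "MutationCounts")) dmso <- list(dmso)
  naiC <- combineReplicates(nai)
  dmsoC <- combineReplicates(dmso)
  naiRate <- mutationRate(naiC, minCoverage = 1L)
  dmsoRate <- mutationRate(dmsoC, minCoverage = 1L)
  cov <- pmin(positionCoverage(naiC), positionCoverage(dmsoC))
  raw <- rawReactivity(naiRate, dmsoRate)
  raw[cov < minCoverage] <- NA_real_
  prof <- normalizeProfile(raw, transcript = transcriptId(naiC),
                           sequence = sequence, coverage = cov)
  maskProfile(prof, minCoverage = minCoverage, dmsoRate = dmsoRate,
              maxBackground = maxBackground)
}

#' Windowed replicate correlation of mutation rates
#'
#' Replicates are first balanced to equal totals by seeded down-sampling of
#' the deeper replicate (per-position hypergeometric thinning). All bases
#' are then pooled and sorted by combined coverage; for each coverage
#' cutoff, the bases above it are windowed (window 50, step 10) along that
#' ordering and the Pearson correlation of the two replicates' mutation
#' rates is computed per window. Windows with zero variance in either
#' replicate are skipped and counted.
#'
#' @param rep1,rep2 \linkS4class{MutationCounts} or lists thereof (one per
#'   transcript), covering the same references.
#' @param window Window size in bases (default 50).
#' @param step Window step (default 10).
#' @param cutoffs Coverage cutoffs (default 500, 1000, 2000, 3000, 4000,
#'   5000).
#' @param seed Seed for the down-sampling.
#' @return Named list (one element per cutoff) of numeric vectors of window
#'   Pearson r, with attribute "skipped" giving the per-cutoff count of
#'   zero-variance windows.
#' @export
replicateCorrelation <- function(rep1, rep2, window = 50L, step = 10L,
                                 cutoffs = c(500, 1000, 2000, 3000, 4000, 5000),
                                 seed = 1L) {
  if (is(rep1, "MutationCounts")) rep1 <- list(rep1)
  if (is(rep2, "MutationCounts")) rep2 <- list(rep2)
  stopifnot(length(rep1) == length(rep2))
  ev1 <- unlist(lapply(rep1, function(x) rowSums(eventCounts(x))))
  cov1 <- unlist(lapply(rep1, positionCoverage))
  ev2 <- unlist(lapply(rep2, function(x) rowSums(eventCounts(x))))
  cov2 <- unlist(lapply(rep2, positionCoverage))
  stopifnot(length(cov1) == length(cov2))
  set.seed(seed)
  t1 <- sum(cov1); t2 <- sum(cov2)
  thin <- function(ev, cov, p) {
    newCov <- stats::rbinom(length(cov), cov, p)
    newEv <- ifelse(newCov > 0,
                    stats::rhyper(length(cov), m = ev, n = cov - ev, k = newCov),
                    0L)
    list(ev = newEv, cov = newCov)
  }
  if (t1 > t2) { d <- thin(ev1, cov1, t2 / t1); ev1 <- d$ev; cov1 <- d$cov }
  if (t2 > t1) { d <- thin(ev2, cov2, t1 / t2); ev2 <- d$ev; cov2 <- d$cov }
  covMin <- pmin(cov1, cov2)
  ord <- order(covMin, decreasing = TRUE)
  out <- list(); skipped <- integer(length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    sel <- ord[covMin[ord] > cutoffs[ci]]
    rs <- numeric(0); nskip <- 0L
    if (length(sel) >= window) {
      startAt <- seq(1L, length(sel) - window + 1L, by = step)
      for (s in startAt) {
        idx <- sel[s:(s + window - 1L)]
        r1 <- ev1[idx] / cov1[idx]
        r2 <- ev2[idx] / cov2[idx]
        if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
          nskip <- nskip + 1L
        } else rs <- c(rs, stats::cor(r1, r2))
      }
    }
    out[[as.character(cutoffs[ci])]] <- rs
    skipped[ci] <- nskip
  }
  attr(out, "skipped") <- stats::setNames(skipped, as.character(cutoffs))
  out
}

#' ROC AUC of reactivity scores against a reference structure
#'
#' Area under the ROC curve for the scores as a predictor of the unpaired
#' state (higher score = more likely unpaired), with tied score pairs
#' counted as one half. NA scores are excluded.
#'
#' @param profile A \linkS4class{ReactivityProfile} or a numeric score
#'   vector.
#' @param reference A \linkS4class{SecondaryStructure} of the same length.
#' @return AUC in [0, 1].
#' @export
structureAuc <- function(profile, reference) {
  s <- if (is(profile, "ReactivityProfile")) reactivity(profile) else profile
  pt <- pairTable(reference)
  stopifnot(length(s) == length(pt))
  ok <- !is.na(s)
  s <- s[ok]
  unpaired <- (pt == 0)[ok]
  nPos <- sum(unpaired); nNeg <- sum(!unpaired)
  if (nPos == 0 || nNeg == 0)
    stop("need at least one paired and one unpaired scored position")
  # Mann-Whitney formulation: ties counted half through midranks
  r <- rank(s)
  (sum(r[unpaired]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Read or write SHAPE reactivity files
#'
#' The de facto two-column SHAPE dialect consumed by folding tools:
#' whitespace-delimited \code{position score}, 1-based, with NA encoded as
#' -999.
#'
#' @param profile A \linkS4class{ReactivityProfile} or numeric vector.
#' @param path File path.
#' @export
writeShapeFile <- function(profile, path) {
  s <- if (is(profile, "ReactivityProfile")) reactivity(profile) else profile
  s[is.na(s)] <- -999
  utils::write.table(data.frame(seq_along(s), s), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeShapeFile
#' @return \code{readShapeFile}: numeric vector with NA at -999 entries.
#' @export
readShapeFile <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  s <- numeric(max(tab[[1]]))
  s[] <- NA_real_
  s[tab[[1]]] <- tab[[2]]
  s[!is.na(s) & s <= -999] <- NA_real_
  s
}

#' Write a reactivity profile as a richer TSV
#'
#' Columns: transcript, position, score (NA as -999), coverage, norm_factor.
#'
#' @param profiles Named list of \linkS4class{ReactivityProfile}.
#' @param path Output path.
#' @export
writeProfileTsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    s <- reactivity(p)
    s[is.na(s)] <- -999
    data.frame(transcript = transcriptId(p), position = seq_along(s),
               score = s, coverage = positionCoverage(p),
               norm_factor = normFactor(p), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
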