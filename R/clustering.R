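#' @include AllClasses.R folding.R
NULL

ALIGN_FLANK <- 30L   # columns -30..-1 and +1..+30 around the loop center

#' Align reactivity profiles on their central loops
#'
#' For every transcript, the loop center is the midpoint of the central
#' hairpin loop (floor for even loop sizes); the 30 scores on either side
#' fill the 60 matrix columns (-30..-1, +1..+30 — the center nucleotide
#' itself is excluded). Positions beyond the transcript ends are missing and
#' are imputed, like other missing scores, by the transcript's mean
#' non-missing score. Transcripts with more than 50% missing columns, or
#' without a hairpin loop, are dropped and reported.
#'
#' @param profiles Named list of \linkS4class{ReactivityProfile} (or
#'   numeric score vectors).
#' @param structures Matched named list of
#'   \linkS4class{SecondaryStructure}.
#' @param impute One of "transcript-mean" (default), "zero", "column-mean".
#' @return Numeric matrix (transcripts x 60) with attribute
#'   \code{"dropped"} naming the dropped transcripts.
#' @export
alignProfiles <- function(profiles, structures,
                          impute = c("transcript-mean", "zero", "column-mean")) {
  impute <- match.arg(impute)
  stopifnot(length(profiles) == length(structures))
  ids <- names(profiles)
  if (is.null(ids)) ids <- sprintf("tx_%03d", seq_along(profiles))
  rows <- list(); dropped <- character(0)
  for (t in seq_along(profiles)) {
    s <- profiles[[t]]
    if (is(s, "ReactivityProfile")) s <- reactivity(s)
    loop <- centralLoop(structures[[t]])
    if (is.null(loop)) { dropped <- c(dropped, ids[t]); next }
    center <- floor((loop[1] + loop[2]) / 2)
    posns <- center + c(-(ALIGN_FLANK:1), 1:ALIGN_FLANK)
    vals <- rep(NA_real_, 2 * ALIGN_FLANK)
    inside <- posns >= 1 & posns <= length(s)
    vals[inside] <- s[posns[inside]]
    if (mean(is.na(vals)) > 0.5) { dropped <- c(dropped, ids[t]); next }
    rows[[ids[t]]] <- vals
  }
  if (length(dropped))
    message("dropped ", length(dropped),
            " transcript(s) without a usable aligned profile: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (!length(rows)) {
    m <- matrix(numeric(0), 0, 2 * ALIGN_FLANK)
  } else {
    m <- do.call(rbind, rows)
  }
  colnames(m) <- c(paste0("", -(ALIGN_FLANK:1)), paste0("+", 1:ALIGN_FLANK))
  if (nrow(m)) {
    if (impute == "zero") {
      m[is.na(m)] <- 0
    } else if (impute == "column-mean") {
      cm <- colMeans(m, na.rm = TRUE)
      for (cix in which(colSums(is.na(m)) > 0))
        m[is.na(m[, cix]), cix] <- cm[cix]
    } else {
      for (r in which(rowSums(is.na(m)) > 0))
        m[r, is.na(m[r, ])] <- mean(m[r, ], na.rm = TRUE)
    }
  }
  attr(m, "dropped") <- dropped
  m
}

#' Project an aligned profile matrix onto its top two principal components
#'
#' Columns are mean-centered but not variance-scaled (reactivities share a
#' scale after normalization; variance-scaling would inflate flat flank
#' positions). The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param matrix Aligned profile matrix (rows = transcripts).
#' @return List with \code{coords} (rows x 2), \code{loadings} (columns x
#'   2, unit norm) and \code{explained} (variance fractions of PC1, PC2).
#' @export
pcaProject <- function(matrix) {
  if (nrow(matrix) < 3) stop("need at least 3 rows for PCA")
  if (all(apply(matrix, 2, stats::var) == 0))
    stop("zero total variance: nothing to project")
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  coords <- p$x[, seq_len(k), drop = FALSE]
  for (cix in seq_len(k)) {
    top <- which.max(abs(load[, cix]))
    if (load[top, cix] < 0) {
      load[, cix] <- -load[, cix]
      coords[, cix] <- -coords[, cix]
    }
  }
  if (k < 2) {
    load <- cbind(load, 0); coords <- cbind(coords, 0)
  }
  colnames(load) <- colnames(coords) <- c("PC1", "PC2")
  expl <- (p$sdev^2 / sum(p$sdev^2))[1:2]
  expl[is.na(expl)] <- 0
  list(coords = coords, loadings = load, explained = expl)
}

#' K-means clustering of PCA coordinates
#'
#' Lloyd iterations with 10 random restarts, keeping the best inertia;
#' deterministic under the seed. Cluster labels are renumbered by
#' descending cluster size (label 1 = largest).
#'
#' @param coords Numeric matrix of row coordinates (typically the 2D PCA
#'   projection).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels (1..k), with the kmeans fit in
#'   attribute \code{"fit"}.
#' @export
kmeansCluster <- function(coords, k = 3L, seed = 1L) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop("k cannot exceed the number of rows")
  set.seed(seed)
  dup <- nrow(unique(coords)) < k
  if (dup) warning("fewer distinct points than clusters: degenerate clusters")
  fit <- suppressWarnings(
    stats::kmeans(coords, centers = min(k, nrow(unique(coords))),
                  nstart = 10L, iter.max = 100L, algorithm = "Lloyd"))
  sizes <- table(fit$cluster)
  remap <- stats::setNames(seq_along(sizes),
                           names(sort(sizes, decreasing = TRUE)))
  labels <- as.integer(remap[as.character(fit$cluster)])
  attr(labels, "fit") <- fit
  labels
}

#' Loop-aligned PCA/K-means clustering of reactivity profiles
#'
#' The full clustering stage: align on central loops, project to two
#' principal components, and K-means-cluster the projection.
#'
#' @inheritParams alignProfiles
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return List with matrix, coords, loadings, explained, labels.
#' @export
clusterProfiles <- function(profiles, structures, k = 3L, seed = 1L,
                            impute = "transcript-mean") {
  m <- alignProfiles(profiles, structures, impute = impute)
  proj <- pcaProject(m)
  labels <- kmeansCluster(proj$coords, k = k, seed = seed)
  list(matrix = m, coords = proj$coords, loadings = proj$loadings,
       explained = proj$explained, labels = labels)
}
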