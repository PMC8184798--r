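# Independent oracles used across the suite. These re-derive expected
# results by brute force (alignment re-walk, exhaustive structure
# enumeration, concordant-pair counting) without touching the package's
# internal code paths.

# ---- brute-force mutation parser -------------------------------------

# expand an alignment into explicit columns, collect primitive events,
# right-align deletion runs, merge by the <= spacer matched-base rule and
# classify; written against the documented rules, independently of
# parseReadMutations' implementation
oracleParseRead <- function(pos, cigar, seq, reference, spacer = 2L) {
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  refChars <- strsplit(reference, "")[[1]]
  readChars <- strsplit(seq, "")[[1]]
  rp <- as.integer(pos); qp <- 1L
  cols <- list()   # each: list(ref = index or NA, q = char or NA)
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "=", "X")) {
      for (z in seq_len(lens[k])) {
        cols[[length(cols) + 1L]] <- list(ref = rp, q = readChars[qp])
        rp <- rp + 1L; qp <- qp + 1L
      }
    } else if (ops[k] == "I") {
      for (z in seq_len(lens[k])) {
        cols[[length(cols) + 1L]] <- list(ref = NA, q = readChars[qp])
        qp <- qp + 1L
      }
    } else if (ops[k] == "D") {
      for (z in seq_len(lens[k])) {
        cols[[length(cols) + 1L]] <- list(ref = rp, q = NA)
        rp <- rp + 1L
      }
    } else if (ops[k] == "S") {
      qp <- qp + lens[k]
    }
  }
  alignedEnd <- rp - 1L
  # primitive events
  prim <- data.frame(type = character(), left = integer(), right = integer(),
                     ins = integer(), del = integer(), bases = character(),
                     stringsAsFactors = FALSE)
  i <- 1L
  lastRef <- as.integer(pos) - 1L
  while (i <= length(cols)) {
    cl <- cols[[i]]
    if (!is.na(cl$ref) && !is.na(cl$q)) {
      if (cl$q != refChars[cl$ref])
        prim[nrow(prim) + 1L, ] <- list("mismatch", cl$ref, cl$ref, 0L, 0L, cl$q)
      lastRef <- cl$ref
      i <- i + 1L
    } else if (is.na(cl$ref)) {
      j <- i
      bs <- character(0)
      while (j <= length(cols) && is.na(cols[[j]]$ref)) {
        bs <- c(bs, cols[[j]]$q); j <- j + 1L
      }
      prim[nrow(prim) + 1L, ] <- list("insertion", lastRef, lastRef,
                                      length(bs), 0L, paste(bs, collapse = ""))
      i <- j
    } else {
      j <- i
      while (j <= length(cols) && !is.na(cols[[j]]$ref) && is.na(cols[[j]]$q))
        j <- j + 1L
      a <- cols[[i]]$ref; b <- cols[[j - 1L]]$ref
      while (b + 1L <= alignedEnd && refChars[b + 1L] == refChars[a]) {
        a <- a + 1L; b <- b + 1L
      }
      prim[nrow(prim) + 1L, ] <- list("deletion", a, b, 0L, b - a + 1L, "")
      lastRef <- cols[[j - 1L]]$ref
      i <- j
    }
  }
  if (!nrow(prim)) {
    return(data.frame(mtype = character(), ref_position = integer(),
                      ref_span = integer(), read_bases = character(),
                      stringsAsFactors = FALSE))
  }
  prim <- prim[order(prim$left, prim$right), , drop = FALSE]
  groups <- list(); cur <- prim[1, , drop = FALSE]
  if (nrow(prim) > 1) {
    for (k in 2:nrow(prim)) {
      if (prim$left[k] - max(cur$right) - 1L <= spacer) {
        cur <- rbind(cur, prim[k, ])
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- prim[k, , drop = FALSE]
      }
    }
  }
  groups[[length(groups) + 1L]] <- cur
  rows <- lapply(groups, function(g) {
    cls <- if (all(g$type == "mismatch")) {
      if (nrow(g) == 1) "mismatch" else "multi_mismatch"
    } else if (all(g$type == "insertion")) {
      if (nrow(g) == 1 && g$ins[1] == 1) "insertion" else "multi_insertion"
    } else if (all(g$type == "deletion")) {
      if (nrow(g) == 1 && g$del[1] == 1) "deletion" else "multi_deletion"
    } else {
      net <- sum(g$ins) - sum(g$del)
      if (net > 0) "complex_insertion"
      else if (net < 0) "complex_deletion"
      else "multi_mismatch"
    }
    data.frame(mtype = cls, ref_position = max(g$right),
               ref_span = if (all(g$type == "insertion")) 0L
                          else max(g$right) - min(g$left) + 1L,
               read_bases = paste(g$bases, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- exhaustive structure enumeration --------------------------------

canPairChars <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# all pseudoknot-free pair sets with hairpin loops >= 3, as a list of
# 2-column pair matrices
enumerateStructures <- function(sequence) {
  chars <- strsplit(toupper(chartr("T", "U", sequence)), "")[[1]]
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1L)                       # j unpaired
    for (k in i:(j - 4L)) {
      if (!canPairChars(chars[k], chars[j])) next
      lefts <- if (k - 1L >= i) rec(i, k - 1L) else list(matrix(integer(0), 0, 2))
      ins <- rec(k + 1L, j - 1L)
      for (L in lefts) for (Ii in ins)
        out[[length(out) + 1L]] <- rbind(L, Ii, c(k, j))
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, n), function(m) {
    pt <- integer(n)
    if (nrow(m)) { pt[m[, 1]] <- m[, 2]; pt[m[, 2]] <- m[, 1] }
    pt
  })
}

# minimum energy over all enumerated structures under the shared model
enumerateMfe <- function(sequence, profile = NULL) {
  structs <- enumerateStructures(sequence)
  model <- energyModel(maxLen = max(50L, nchar(sequence)))
  energies <- vapply(structs, function(pt)
    structureEnergy(sequence, pt, profile = profile, model = model), 1.0)
  list(energy = min(energies), pt = structs[[which.min(energies)]])
}

# ---- misc -------------------------------------------------------------

# AUC by explicit concordant-pair counting (ties half)
bruteAuc <- function(scores, unpaired) {
  pos <- scores[unpaired]; neg <- scores[!unpaired]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

randomSequence <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small multi-model ensemble around an ideal helix
jitteredHelixModels <- function(nModels, spec, sd = 0.5, energies = NULL) {
  base <- buildHelixCoordinates(spec)
  lapply(seq_len(nModels), function(k) {
    m <- jitterModel(base, sd = sd)
    m@energy <- if (is.null(energies)) NA_real_ else energies[k]
    m
  })
}

# hand-built loop-counting cases: structure, spans, expected rule outcomes.
# p = first nt of the 3p span; the rule needs p-1, p-2 paired and p-3
# single-stranded. q = last nt of the 5p span; the 5p rule needs q+1
# single-stranded.
# 18-nt hairpin: pairs (1,18)..(7,12), loop 8-11
# bulged 17-nt "((((.((....))))))": pairs (1,17)..(4,14),(6,13),(7,12);
#   loop 8-11, bulge at 5
# 3'-bulged 17-nt "((((((....)).))))": pairs (1,17)..(4,14),(5,12),(6,11);
#   loop 7-10, bulge at 13
loopRuleCases <- list(
  list(db = "(((((((....)))))))", s5 = c(1, 7), s3 = c(14, 18),
       r3 = TRUE,  r5 = TRUE),    # p=14: 13,12 paired, 11 ss; q=7: 8 ss
  list(db = "(((((((....)))))))", s5 = c(1, 11), s3 = c(14, 18),
       r3 = TRUE,  r5 = FALSE),   # q=11: 12 paired
  list(db = "(((((((....)))))))", s5 = c(1, 10), s3 = c(14, 18),
       r3 = TRUE,  r5 = TRUE),    # q=10: 11 ss (5p end at the loop edge)
  list(db = "(((((((....)))))))", s5 = c(1, 7), s3 = c(15, 18),
       r3 = FALSE, r5 = TRUE),    # p=15: p-3=12 paired (no bulge in reach)
  list(db = "(((((((....)))))))", s5 = c(1, 7), s3 = c(13, 18),
       r3 = FALSE, r5 = TRUE),    # p=13: p-2=11 single-stranded
  list(db = "((((.((....))))))", s5 = c(1, 4), s3 = c(8, 17),
       r3 = TRUE,  r5 = TRUE),    # p=8: 7,6 paired, 5 is the bulge
  list(db = "((((.((....))))))", s5 = c(1, 4), s3 = c(14, 17),
       r3 = TRUE,  r5 = TRUE),    # p=14: 13,12 paired, 11 in the loop
  list(db = "((((((....)).))))", s5 = c(1, 6), s3 = c(16, 17),
       r3 = TRUE,  r5 = TRUE),    # p=16: 15,14 paired, 13 is the bulge
  list(db = "((((((....)).))))", s5 = c(1, 6), s3 = c(17, 17),
       r3 = FALSE, r5 = TRUE),    # p=17: p-3=14 paired
  list(db = "(((((((....)))))))", s5 = c(1, 2), s3 = c(3, 18),
       r3 = FALSE, r5 = FALSE)    # p=3: p-3 off the end -> FALSE (logged)
)
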