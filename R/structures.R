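#' @include AllClasses.R
NULL

#' Parse a dot-bracket string into a pair table
#'
#' @param db Dot-bracket string using "(", ")" and "." (no pseudoknot
#'   bracket layers).
#' @return Integer vector of partner indices, 0 for unpaired.
#' @export
#' @examples
#' dotBracketToPairs("((((....))))")
dotBracketToPairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", ".")))
    stop("dot-bracket may only contain '(', ')' and '.'")
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Render a pair table as dot-bracket
#'
#' @param pt Integer partner vector (0 = unpaired).
#' @return Dot-bracket string.
#' @export
pairsToDotBracket <- function(pt) {
  out <- rep(".", length(pt))
  out[pt > seq_along(pt)] <- "("
  out[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(out, collapse = "")
}

#' Construct a SecondaryStructure
#'
#' @param sequence RNA sequence.
#' @param structure Either a dot-bracket string or an integer pair table.
#' @return A \linkS4class{SecondaryStructure}.
#' @export
#' @examples
#' secondaryStructure("GGGGAAAACCCC", "((((....))))")
secondaryStructure <- function(sequence, structure) {
  pt <- if (is.character(structure)) dotBracketToPairs(structure)
        else as.integer(structure)
  new("SecondaryStructure", sequence = toupper(sequence), pairTable = pt)
}

#' Read and write dot-bracket files
#'
#' The dot-bracket file dialect used here is FASTA-like: a ">id" line, the
#' sequence line, then the structure line, per record.
#'
#' @param path File path.
#' @return \code{readDotBracket}: a named list of
#'   \linkS4class{SecondaryStructure} objects.
#' @export
readDotBracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no records in dot-bracket file: ", path)
  out <- list()
  for (h in heads) {
    id <- sub("^>\\s*", "", lines[h])
    out[[id]] <- secondaryStructure(lines[h + 1], lines[h + 2])
  }
  out
}

#' @rdname readDotBracket
#' @param structures Named list of \linkS4class{SecondaryStructure}.
#' @export
writeDotBracket <- function(structures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(structures)) {
    s <- structures[[id]]
    writeLines(c(paste0(">", id), rnaSequence(s), dotBracket(s)), con)
  }
  invisible(path)
}

#' Read and write CT (connectivity table) structure files
#'
#' Standard 6-column CT format: index, base, i-1, i+1, partner (0 if
#' unpaired), index.
#'
#' @param path File path.
#' @return \code{readCt}: a \linkS4class{SecondaryStructure}.
#' @export
readCt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[1])
  body <- utils::read.table(text = lines[2:(n + 1)])
  seq <- paste(body[[2]], collapse = "")
  secondaryStructure(seq, as.integer(body[[5]]))
}

#' @rdname readCt
#' @param structure A \linkS4class{SecondaryStructure}.
#' @param id Record identifier written on the header line.
#' @export
writeCt <- function(structure, path, id = "structure") {
  pt <- pairTable(structure)
  n <- length(pt)
  bases <- strsplit(rnaSequence(structure), "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, id), con)
  writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1) + 1L, 0L),
                     pt, seq_len(n)), con)
  invisible(path)
}
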