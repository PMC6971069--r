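#' Parse a secondary structure from CT or dot-bracket files
#'
#' Both dialects produce identical pair sets on equivalent inputs. Crossing
#' pairs (pseudoknots) are rejected rather than silently dropped: the SSU
#' rRNA models this package targets are nested. An optional sidecar TSV
#' (columns `position`, `helix`) attaches Wuyts-style helix labels.
#'
#' @param path path to the structure file.
#' @param dialect `"ct"` or `"dotbracket"`. A dot-bracket file holds an
#'   optional `>id` header, the sequence line (optional), and the bracket
#'   line using `(`, `)` and `.`.
#' @param helixSidecar optional path to a helix-label TSV.
#' @return A [SecondaryStructure-class].
#' @examples
#' db <- tempfile(fileext = ".db")
#' writeLines(c(">s", "GGAAACC", "((...))"), db)
#' basePairs(parseStructure(db, "dotbracket"))
#' @export
parseStructure <- function(path, dialect = c("ct", "dotbracket"),
                           helixSidecar = NULL) {
  dialect <- match.arg(dialect)
  st <- if (dialect == "ct") .parseCt(path) else .parseDotBracket(path)
  if (!is.null(helixSidecar)) {
    tab <- utils::read.delim(helixSidecar, stringsAsFactors = FALSE)
    if (!all(c("position", "helix") %in% names(tab)))
      .stopf("format error: helix sidecar needs columns position, helix")
    st@helixLabels <- stats::setNames(as.character(tab$helix),
                                      as.integer(tab$position))
    validObject(st)
  }
  st
}

.parseDotBracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- NA_character_
  if (length(lines) && startsWith(lines[1L], ">")) {
    id <- sub("^>\\s*", "", lines[1L]); lines <- lines[-1L]
  }
  if (!length(lines)) .stopf("format error: empty dot-bracket file %s", path)
  isBracket <- grepl("^[().]+$", lines)
  if (!any(isBracket)) .stopf("format error: no bracket line in %s", path)
  bracket <- lines[which(isBracket)[1L]]
  ch <- .chars(bracket)
  stack <- integer(); p <- list()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack)) .stopf("format error: unmatched ')' at position %d", k)
      p[[length(p) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    .stopf("format error: unmatched '(' at position %d", stack[length(stack)])
  pairs <- if (length(p)) do.call(rbind, p) else matrix(integer(), ncol = 2L)
  secondaryStructure(pairs, seqId = id, seqLength = length(ch))
}

.parseCt <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) .stopf("format error: empty CT file %s", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[1L]))
  if (is.na(n)) .stopf("format error: CT header must start with the length")
  id <- if (length(header) > 1L) paste(header[-1L], collapse = " ") else NA_character_
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) .stopf("format error: CT file truncated (%d of %d rows)",
                               length(body), n)
  fields <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  idx <- vapply(fields, function(f) as.integer(f[1L]), integer(1))
  partner <- vapply(fields, function(f) as.integer(f[5L]), integer(1))
  if (!identical(idx, seq_len(n)))
    .stopf("format error: CT rows must be numbered 1..n")
  keep <- partner > 0L & idx < partner
  pairs <- cbind(idx[keep], partner[keep])
  # symmetry check
  pmap <- integer(n); pmap[idx] <- partner
  bad <- which(partner > 0L & pmap[pmax(partner, 1L)] != idx)
  if (length(bad)) .stopf("format error: asymmetric CT pairing at row %d", bad[1L])
  st <- secondaryStructure(pairs, seqId = sub("^>\\s*", "", id), seqLength = n)
  st
}

#' Write a secondary structure
#'
#' @param st a [SecondaryStructure-class].
#' @param path output path.
#' @param dialect `"dotbracket"` or `"ct"`.
#' @param residues the sequence (required for CT, optional for dot-bracket).
#' @return `path`, invisibly.
#' @export
writeStructure <- function(st, path, dialect = c("dotbracket", "ct"),
                           residues = NULL) {
  dialect <- match.arg(dialect)
  n <- if (st@seqLength > 0L) st@seqLength
       else if (!is.null(residues)) nchar(residues)
       else if (nrow(st@pairs)) max(st@pairs) else 0L
  partner <- integer(n)
  if (nrow(st@pairs)) {
    partner[st@pairs[, 1L]] <- st@pairs[, 2L]
    partner[st@pairs[, 2L]] <- st@pairs[, 1L]
  }
  if (dialect == "dotbracket") {
    br <- rep(".", n)
    br[st@pairs[, 1L]] <- "("; br[st@pairs[, 2L]] <- ")"
    lines <- c(paste0(">", st@seqId),
               if (!is.null(residues)) residues,
               paste(br, collapse = ""))
    writeLines(lines, path)
  } else {
    if (is.null(residues)) .stopf("CT output requires residues")
    res <- .chars(residues)
    rows <- sprintf("%d %s %d %d %d %d", seq_len(n), res, seq_len(n) - 1L,
                    c(seq_len(n)[-1L], 0L), partner, seq_len(n))
    writeLines(c(sprintf("%d %s", n, st@seqId), rows), path)
  }
  invisible(path)
}

#' Base-pair complementarity (Watson-Crick plus G-U wobble)
#'
#' In rRNA stems the G.U wobble pair is structurally conserved alongside
#' A.U and G.C; counting it as complementary is what keeps conserved stems
#' from being littered with false "uncoupled" calls.
#'
#' @param b1,b2 single bases. Standard bases give `TRUE`/`FALSE`; any IUPAC
#'   ambiguity code gives `NA` (indeterminate).
#' @return `TRUE`, `FALSE` or `NA`.
#' @examples
#' isComplementary("G", "U")  # TRUE (wobble)
#' isComplementary("A", "G")  # FALSE
#' @export
isComplementary <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  if (.isAmbiguity(b1) || .isAmbiguity(b2) || b1 == .GAP || b2 == .GAP)
    return(NA)
  b2 %in% .COMPLEMENT_SETS[[b1]]
}

#' Map a reference structure onto alignment columns
#'
#' Every pair `(i, j)` of the reference row's structure is mapped to the
#' column pair holding those residues; helix labels travel with their
#' positions; all remaining columns are unpaired.
#'
#' @param st [SecondaryStructure-class] on the ungapped reference row.
#' @param aln a [PairAlignment-class].
#' @param referenceRow `"a"` or `"b"`: which row `st` describes.
#' @return A [StructuredAlignment-class].
#' @export
mapStructure <- function(st, aln, referenceRow = c("a", "b")) {
  referenceRow <- match.arg(referenceRow)
  row <- if (referenceRow == "a") aln@rowA else aln@rowB
  ungappedLen <- sum(.chars(row) != .GAP)
  maxPos <- if (nrow(st@pairs)) max(st@pairs) else 0L
  if (max(maxPos, st@seqLength) > ungappedLen)
    .stopf("consistency error: structure position %d exceeds reference row length %d",
           max(maxPos, st@seqLength), ungappedLen)
  p2c <- .posToCol(row)
  L <- nchar(row)
  partner <- rep(NA_integer_, L)
  helix <- rep(NA_character_, L)
  if (nrow(st@pairs)) {
    ci <- p2c[st@pairs[, 1L]]; cj <- p2c[st@pairs[, 2L]]
    partner[ci] <- cj; partner[cj] <- ci
  }
  if (length(st@helixLabels)) {
    pos <- as.integer(names(st@helixLabels))
    helix[p2c[pos]] <- unname(st@helixLabels)
  }
  new("StructuredAlignment", alignment = aln, partner = partner,
      helix = helix, referenceRow = referenceRow)
}

#' Transfer a template structure onto the aligned query
#'
#' The template (row A) pairing is pushed through the alignment onto the
#' query (row B): a template pair becomes a query pair iff the query has
#' residues at both partner columns. Pairs lost to query gaps are reported
#' in `flags`; transferred pairs whose query bases are non-complementary
#' are kept but flagged, so downstream classification can still call the
#' site "uncoupled" instead of losing it. Helix labels are inherited.
#'
#' @param template [SecondaryStructure-class] on the ungapped row A.
#' @param aln a [PairAlignment-class]; row B is the query.
#' @return A list with `structure`, the query [SecondaryStructure-class]
#'   (positions on the ungapped query), and `flags`, a data.frame with
#'   columns `templateI`, `templateJ`, `reason`
#'   (`gap`/`non_complementary`).
#' @export
transferStructure <- function(template, aln) {
  saln <- mapStructure(template, aln, referenceRow = "a")
  bChars <- .chars(aln@rowB)
  c2pB <- .colToPos(aln@rowB)
  p2cA <- .posToCol(aln@rowA)
  flags <- list()
  qPairs <- list(); qLabels <- character()
  for (k in seq_len(nrow(template@pairs))) {
    i <- template@pairs[k, 1L]; j <- template@pairs[k, 2L]
    ci <- p2cA[i]; cj <- p2cA[j]
    if (bChars[ci] == .GAP || bChars[cj] == .GAP) {
      flags[[length(flags) + 1L]] <- data.frame(
        templateI = i, templateJ = j, reason = "gap")
      next
    }
    qi <- c2pB[ci]; qj <- c2pB[cj]
    comp <- isComplementary(bChars[ci], bChars[cj])
    if (isFALSE(comp)) {
      flags[[length(flags) + 1L]] <- data.frame(
        templateI = i, templateJ = j, reason = "non_complementary")
    }
    qPairs[[length(qPairs) + 1L]] <- c(qi, qj)
    for (pp in c(i, j)) {
      lab <- template@helixLabels[as.character(pp)]
      if (!is.na(lab) && length(lab)) {
        qLabels[as.character(if (pp == i) qi else qj)] <- unname(lab)
      }
    }
  }
  pairs <- if (length(qPairs)) do.call(rbind, qPairs) else matrix(integer(), ncol = 2L)
  qst <- secondaryStructure(pairs, seqId = aln@idB, helixLabels = qLabels,
                            seqLength = sum(bChars != .GAP))
  flagsDf <- if (length(flags)) do.call(rbind, flags)
             else data.frame(templateI = integer(), templateJ = integer(),
                             reason = character())
  list(structure = qst, flags = flagsDf)
}
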