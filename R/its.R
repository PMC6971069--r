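# ITS1/ITS2 support: boundary location, canonical ITS2 motif verification,
# and the helix-region distance used for ITS1 comparisons.

# Decompose a structure into its top-level helices (domains) by 5' order.
# A domain is one outermost pair plus everything nested inside it. Returns
# a list of lists: outer = c(i, j), pairs = matrix of pairs in the domain.
.topLevelHelices <- function(st) {
  p <- st@pairs
  if (!nrow(p)) return(list())
  top <- vapply(seq_len(nrow(p)), function(k) {
    !any(p[, 1L] < p[k, 1L] & p[, 2L] > p[k, 2L])
  }, logical(1))
  outers <- p[top, , drop = FALSE]
  outers <- outers[order(outers[, 1L]), , drop = FALSE]
  lapply(seq_len(nrow(outers)), function(k) {
    i <- outers[k, 1L]; j <- outers[k, 2L]
    inside <- p[p[, 1L] >= i & p[, 2L] <= j, , drop = FALSE]
    list(outer = c(i, j), pairs = inside[order(inside[, 1L]), , drop = FALSE])
  })
}

# Does the region of one domain branch into >= 2 child stems anywhere?
.isBranched <- function(domainPairs) {
  p <- domainPairs
  if (nrow(p) < 2L) return(FALSE)
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1L]; j <- p[k, 2L]
    kids <- p[p[, 1L] > i & p[, 2L] < j, , drop = FALSE]
    if (!nrow(kids)) next
    topKids <- vapply(seq_len(nrow(kids)), function(m) {
      !any(kids[, 1L] < kids[m, 1L] & kids[, 2L] > kids[m, 2L])
    }, logical(1))
    if (sum(topKids) >= 2L) return(TRUE)
  }
  # also: two or more stems directly at the exterior of the domain cannot
  # happen (single outer pair), so only internal multiloops count
  FALSE
}

#' Locate the ITS2 interval of an annotated sequence
#'
#' The primary path simply returns the annotated `ITS2` interval. When no
#' annotation is present, boundaries are recovered from supplied flanking
#' references: the 3' end of the best local match of the 5.8S reference and
#' the 5' start of the best local match of the LSU reference delimit ITS2.
#'
#' @param seq an [AnnotatedSequence-class].
#' @param flank58 optional 5.8S reference sequence (character or
#'   [AnnotatedSequence-class]).
#' @param flankLSU optional LSU reference sequence.
#' @return `c(start, end)`, 1-based inclusive.
#' @export
locateIts2 <- function(seq, flank58 = NULL, flankLSU = NULL) {
  if ("ITS2" %in% names(seq@regions)) {
    iv <- seq@regions["ITS2"]
    return(c(start(iv), end(iv)))
  }
  if (is.null(flank58) || is.null(flankLSU))
    .stopf("unresolvable-boundary error: no ITS2 annotation and no flanking references")
  resOf <- function(x) if (is(x, "AnnotatedSequence")) x@residues else .normalizeResidues(x)
  toDNA <- function(x) Biostrings::DNAString(chartr("U", "T", x))
  subj <- toDNA(seq@residues)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = FALSE)
  hit <- function(pattern) {
    pa <- Biostrings::pairwiseAlignment(toDNA(resOf(pattern)), subj,
                                        type = "local", substitutionMatrix = mat,
                                        gapOpening = 10, gapExtension = 0.5)
    c(Biostrings::start(Biostrings::subject(pa)),
      Biostrings::end(Biostrings::subject(pa)))
  }
  h58 <- hit(flank58); hLSU <- hit(flankLSU)
  s <- h58[2L] + 1L; e <- hLSU[1L] - 1L
  if (s > e) .stopf("unresolvable-boundary error: flank matches overlap or are inverted")
  c(s, e)
}

#' Verify the canonical ITS2 structural motifs
#'
#' Checks the eukaryote-typical ITS2 hallmarks on a supplied structure:
#' a pyrimidine-pyrimidine (U-U type) internal mismatch in helix II, an
#' A-rich region between helices II and III, the literal GGU on the 5'
#' strand of helix III before its apex, and a branched (y-shaped) helix I,
#' the Sphaeropleales signature. Helices are numbered I..IV by the 5' order
#' of their first paired base.
#'
#' @param residues ITS2 residue string.
#' @param st [SecondaryStructure-class] on those residues.
#' @param aWindow minimum A-rich window length (nt, default 4).
#' @param aFrac minimum A fraction within the window (default 0.75).
#' @return A [MotifReport-class]. With fewer than 3 helices all motifs are
#'   reported `FALSE` with a warning.
#' @export
checkMotifs <- function(residues, st, aWindow = 4L, aFrac = 0.75) {
  residues <- .normalizeResidues(residues)
  ch <- .chars(residues)
  doms <- .topLevelHelices(st)
  nH <- length(doms)
  empty <- function(warn) new("MotifReport",
    uuMismatch = FALSE, uuPosition = NA_integer_,
    aRich = FALSE, aRichInterval = c(NA_integer_, NA_integer_),
    gguMotif = FALSE, gguPosition = NA_integer_,
    branchedHelixI = FALSE, helixCount = as.integer(nH), warnings = warn)
  if (nH < 3L) {
    warning("fewer than 3 helices: motif checks not applicable")
    return(empty("fewer than 3 helices"))
  }
  paired <- logical(length(ch))
  paired[c(st@pairs[, 1L], st@pairs[, 2L])] <- TRUE
  pyr <- c("C", "U")

  # U-U type mismatch in helix II: facing unpaired pyrimidines flanked by
  # pairs on both sides within the helix II domain.
  uuPos <- NA_integer_; uu <- FALSE
  p2 <- doms[[2L]]$pairs
  if (nrow(p2) >= 2L) {
    for (k in seq_len(nrow(p2))) {
      i <- p2[k, 1L]; j <- p2[k, 2L]
      # 1x1 internal loop directly inside pair (i, j)?
      if (any(p2[, 1L] == i + 2L & p2[, 2L] == j - 2L) &&
          !paired[i + 1L] && !paired[j - 1L] &&
          ch[i + 1L] %in% pyr && ch[j - 1L] %in% pyr) {
        uu <- TRUE; uuPos <- i + 1L; break
      }
    }
  }

  # A-rich region between helix II and helix III.
  aRich <- FALSE; aIv <- c(NA_integer_, NA_integer_)
  spacer <- seq.int(doms[[2L]]$outer[2L] + 1L, doms[[3L]]$outer[1L] - 1L)
  spacer <- spacer[spacer >= 1L & spacer <= length(ch)]
  if (length(spacer) >= aWindow) {
    isA <- as.integer(ch[spacer] == "A")
    for (w in seq_len(length(spacer) - aWindow + 1L)) {
      win <- w:(w + aWindow - 1L)
      if (mean(isA[win]) >= aFrac) {
        aRich <- TRUE
        aIv <- c(spacer[win[1L]], spacer[win[length(win)]])
        break
      }
    }
  }

  # GGU on the 5' strand of helix III, before its apex (the innermost
  # 5'-side paired position).
  ggu <- FALSE; gguPos <- NA_integer_
  p3 <- doms[[3L]]$pairs
  fiveStart <- doms[[3L]]$outer[1L]
  fiveEnd <- max(p3[, 1L])
  if (fiveEnd - fiveStart + 1L >= 3L) {
    strand <- paste(ch[fiveStart:fiveEnd], collapse = "")
    m <- regexpr("GGU", strand, fixed = TRUE)
    if (m > 0L) { ggu <- TRUE; gguPos <- fiveStart + as.integer(m) - 1L }
  }

  new("MotifReport",
      uuMismatch = uu, uuPosition = uuPos,
      aRich = aRich, aRichInterval = as.integer(aIv),
      gguMotif = ggu, gguPosition = gguPos,
      branchedHelixI = .isBranched(doms[[1L]]$pairs),
      helixCount = as.integer(nH), warnings = character())
}

#' p-distance restricted to helix columns
#'
#' The ITS1 comparison statistic: a gap-aware p-distance computed only over
#' the alignment columns belonging to the shared ("common") helices.
#'
#' @param aln a [PairAlignment-class].
#' @param helixColumns integer vector of alignment columns to keep.
#' @param policy a [GapPolicy-class].
#' @return A fraction on `[0, 1]`.
#' @export
helixRegionDistance <- function(aln, helixColumns, policy = gapPolicy()) {
  if (!length(helixColumns)) .stopf("undefined-distance error: empty column set")
  L <- alignmentLength(aln)
  helixColumns <- sort(unique(as.integer(helixColumns)))
  if (any(helixColumns < 1L | helixColumns > L))
    .stopf("lookup error: helix columns outside the alignment")
  pick <- function(row) paste(.chars(row)[helixColumns], collapse = "")
  sub <- pairAlignment(pick(aln@rowA), pick(aln@rowB), aln@idA, aln@idB,
                       maskColumns = match(intersect(aln@maskColumns, helixColumns),
                                           helixColumns))
  pDistance(sub, policy)
}
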