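#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

#' AnnotatedSequence: an rDNA sequence with region and intron annotations
#'
#' Holds one (RNA-normalised) sequence together with named region intervals
#' (SSU, ITS1, 5.8S, ITS2, LSU, ...), group I intron intervals, and an
#' optional primer mask recording positions that were lower-case on input
#' (the primer-binding region convention). All coordinates are 1-based and
#' inclusive on the ungapped sequence.
#'
#' @slot id single character, the sequence identifier.
#' @slot residues single character string over the RNA IUPAC alphabet.
#' @slot regions named [IRanges::IRanges] of region intervals.
#' @slot introns [IRanges::IRanges] of intron intervals (non-overlapping).
#' @slot primerMask [IRanges::IRanges] of primer-masked intervals.
#' @export
setClass("AnnotatedSequence",
  representation(
    id = "character",
    residues = "character",
    regions = "IRanges",
    introns = "IRanges",
    primerMask = "IRanges"
  ),
  prototype(
    id = NA_character_,
    residues = "",
    regions = IRanges::IRanges(),
    introns = IRanges::IRanges(),
    primerMask = IRanges::IRanges()
  )
)

setValidity("AnnotatedSequence", function(object) {
  msgs <- character()
  n <- nchar(object@residues)
  inside <- function(ir) length(ir) == 0L ||
    (all(start(ir) >= 1L) && all(end(ir) <= n) && all(width(ir) >= 1L))
  if (length(object@id) != 1L) msgs <- c(msgs, "'id' must be length 1")
  if (length(object@residues) != 1L) msgs <- c(msgs, "'residues' must be length 1")
  if (!inside(object@regions)) msgs <- c(msgs, "region intervals must lie within [1, length]")
  if (!inside(object@introns)) msgs <- c(msgs, "intron intervals must lie within [1, length]")
  if (!inside(object@primerMask)) msgs <- c(msgs, "primer mask must lie within [1, length]")
  if (length(object@regions) && is.null(names(object@regions)))
    msgs <- c(msgs, "regions must be named")
  if (length(object@introns) > 1L) {
    ir <- sort(object@introns)
    if (any(start(ir)[-1L] <= end(ir)[-length(ir)]))
      msgs <- c(msgs, "intron intervals must be mutually non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedSequence
#'
#' Input residues may be DNA or RNA, upper- or lower-case: `T` is normalised
#' to `U`, and maximal lower-case runs are recorded in the primer mask before
#' upper-casing. Non-IUPAC characters are a format error naming the offending
#' position.
#'
#' @param id sequence identifier.
#' @param residues sequence string (DNA or RNA, mixed case allowed).
#' @param regions named list of `c(start, end)` integer pairs, or a named
#'   `IRanges`.
#' @param introns list of `c(start, end)` pairs or an `IRanges`.
#' @param primerMask optional `IRanges`/list of masked intervals; derived
#'   from lower-case input runs when `NULL`.
#' @return An [AnnotatedSequence-class] object.
#' @examples
#' s <- annotatedSequence("x", "acgtACGT")
#' primerMask(s)  # positions 1-4
#' @export
annotatedSequence <- function(id, residues, regions = list(), introns = list(),
                              primerMask = NULL) {
  if (!nzchar(residues)) .stopf("format error: empty record '%s'", id)
  lower <- .chars(residues) %in% letters
  mask <- if (is.null(primerMask)) {
    r <- rle(lower)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    IRanges::IRanges(start = starts[r$values], end = ends[r$values])
  } else .asIRanges(primerMask)
  residues <- .normalizeResidues(residues)
  .checkAlphabet(residues, id)
  new("AnnotatedSequence",
      id = as.character(id), residues = residues,
      regions = .asIRanges(regions), introns = .asIRanges(introns),
      primerMask = mask)
}

.asIRanges <- function(x) {
  if (is(x, "IRanges")) return(x)
  if (length(x) == 0L) return(IRanges::IRanges())
  st <- vapply(x, function(v) as.integer(v[1L]), integer(1))
  en <- vapply(x, function(v) as.integer(v[2L]), integer(1))
  IRanges::IRanges(start = st, end = en, names = names(x))
}

#' PairAlignment: a gapped pairwise alignment
#'
#' Two equal-length gapped rows with 1-based column indexing; `-` is the gap
#' symbol. `maskColumns` carries alignment columns covered by either
#' sequence's primer mask.
#'
#' @slot idA,idB identifiers of the two rows.
#' @slot rowA,rowB gapped sequence strings of equal length.
#' @slot maskColumns integer vector of primer-masked columns.
#' @export
setClass("PairAlignment",
  representation(idA = "character", idB = "character",
                 rowA = "character", rowB = "character",
                 maskColumns = "integer"),
  prototype(idA = "a", idB = "b", rowA = "", rowB = "",
            maskColumns = integer())
)

setValidity("PairAlignment", function(object) {
  if (nchar(object@rowA) != nchar(object@rowB))
    return("format error: alignment rows of unequal length")
  TRUE
})

#' Construct a PairAlignment from two gapped rows
#'
#' @param rowA,rowB gapped strings of equal length (gap symbol `-`).
#' @param idA,idB row identifiers.
#' @param maskColumns integer vector of masked columns.
#' @return A [PairAlignment-class].
#' @export
pairAlignment <- function(rowA, rowB, idA = "a", idB = "b",
                          maskColumns = integer()) {
  rowA <- .normalizeResidues(rowA); rowB <- .normalizeResidues(rowB)
  new("PairAlignment", idA = idA, idB = idB, rowA = rowA, rowB = rowB,
      maskColumns = as.integer(maskColumns))
}

#' SecondaryStructure: a nested base-pair set with helix labels
#'
#' Pairs are `(i, j)` with `i < j`, 1-based on the ungapped sequence. The
#' pair set must be pseudoknot-free (properly nested) and each position may
#' occur in at most one pair. Helix labels are free text (Wuyts-style names
#' such as `"49"` or `"E23_4"`) attached to paired positions.
#'
#' @slot seqId identifier of the sequence the structure belongs to.
#' @slot pairs integer matrix with columns `i`, `j`.
#' @slot helixLabels character vector of labels named by position.
#' @slot seqLength length of the underlying sequence (0 if unknown).
#' @export
setClass("SecondaryStructure",
  representation(seqId = "character", pairs = "matrix",
                 helixLabels = "character", seqLength = "integer"),
  prototype(seqId = NA_character_,
            pairs = matrix(integer(), ncol = 2L,
                           dimnames = list(NULL, c("i", "j"))),
            helixLabels = character(), seqLength = 0L)
)

.isNested <- function(p) {
  if (nrow(p) < 2L) return(TRUE)
  p <- p[order(p[, 1L]), , drop = FALSE]
  for (a in seq_len(nrow(p) - 1L)) {
    for (b in (a + 1L):nrow(p)) {
      # i_a < i_b always; crossing iff i_a < i_b < j_a < j_b
      if (p[b, 1L] < p[a, 2L] && p[a, 2L] < p[b, 2L]) return(FALSE)
    }
  }
  TRUE
}

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  msgs <- character()
  if (ncol(p) != 2L) return("'pairs' must have two columns")
  if (nrow(p)) {
    if (any(p[, 1L] >= p[, 2L])) msgs <- c(msgs, "pairs must satisfy i < j")
    if (anyDuplicated(c(p[, 1L], p[, 2L])))
      msgs <- c(msgs, "each position may occur in at most one pair")
    if (object@seqLength > 0L && any(p > object@seqLength))
      msgs <- c(msgs, "pair position exceeds sequence length")
    if (!.isNested(p))
      msgs <- c(msgs, "pseudoknot error: crossing pairs are not allowed")
  }
  if (length(object@helixLabels)) {
    lab <- as.integer(names(object@helixLabels))
    if (any(is.na(lab))) msgs <- c(msgs, "helix labels must be named by position")
    else if (!all(lab %in% c(p[, 1L], p[, 2L])))
      msgs <- c(msgs, "labeled positions must be paired")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SecondaryStructure
#'
#' @param pairs two-column matrix (or data.frame) of paired positions;
#'   rows are unordered, each is flipped so that `i < j`.
#' @param seqId identifier of the underlying sequence.
#' @param helixLabels character vector of helix labels named by position.
#' @param seqLength length of the underlying sequence, if known.
#' @return A [SecondaryStructure-class].
#' @export
secondaryStructure <- function(pairs, seqId = NA_character_,
                               helixLabels = character(), seqLength = 0L) {
  p <- as.matrix(pairs)
  if (length(p) == 0L) p <- matrix(integer(), ncol = 2L)
  storage.mode(p) <- "integer"
  if (nrow(p)) {
    flip <- p[, 1L] > p[, 2L]
    p[flip, ] <- p[flip, c(2L, 1L), drop = FALSE]
    p <- p[order(p[, 1L]), , drop = FALSE]
  }
  dimnames(p) <- list(NULL, c("i", "j"))
  new("SecondaryStructure", seqId = as.character(seqId), pairs = p,
      helixLabels = helixLabels, seqLength = as.integer(seqLength))
}

#' StructuredAlignment: alignment columns with base-pairing context
#'
#' A [PairAlignment-class] whose columns carry the pairing context of one
#' declared reference row's secondary structure: for each column, the
#' partner column (or `NA` when unpaired) and an optional helix label.
#'
#' @slot alignment the underlying [PairAlignment-class].
#' @slot partner integer vector, per column: partner column or `NA`.
#' @slot helix character vector, per column: helix label or `NA`.
#' @slot referenceRow `"a"` or `"b"`, the row the structure came from.
#' @export
setClass("StructuredAlignment",
  representation(alignment = "PairAlignment", partner = "integer",
                 helix = "character", referenceRow = "character")
)

setValidity("StructuredAlignment", function(object) {
  L <- nchar(object@alignment@rowA)
  if (length(object@partner) != L || length(object@helix) != L)
    return("per-column vectors must match the alignment length")
  idx <- which(!is.na(object@partner))
  if (any(object@partner[idx] < 1L | object@partner[idx] > L))
    return("partner columns out of range")
  if (!all(object@partner[object@partner[idx]] == idx))
    return("partner relation must be symmetric")
  if (!object@referenceRow %in% c("a", "b"))
    return("referenceRow must be 'a' or 'b'")
  TRUE
})

#' GapPolicy: how gap columns enter site counts and distances
#'
#' `mode = "count"` treats every column where exactly one row has a gap as
#' one differing site and uses all (unmasked) columns as the denominator;
#' `mode = "exclude"` removes gap-containing columns from both numerator and
#' denominator. Gap-vs-gap columns never count anywhere. Primer-masked and
#' ambiguity-containing columns are excluded by default.
#'
#' @slot mode `"count"` or `"exclude"`.
#' @slot maskPrimer exclude primer-masked columns.
#' @slot maskAmbiguity exclude columns where either row has an IUPAC
#'   ambiguity code.
#' @slot indelAsEvent collapse a maximal gap run into one reported indel
#'   record (site counts remain per-column).
#' @export
setClass("GapPolicy",
  representation(mode = "character", maskPrimer = "logical",
                 maskAmbiguity = "logical", indelAsEvent = "logical"),
  prototype(mode = "count", maskPrimer = TRUE, maskAmbiguity = TRUE,
            indelAsEvent = FALSE)
)

setValidity("GapPolicy", function(object) {
  if (!(length(object@mode) == 1L && object@mode %in% c("count", "exclude")))
    return("mode must be exactly one of 'count', 'exclude'")
  TRUE
})

#' Construct a GapPolicy
#'
#' @param mode `"count"` (gap column = one differing site) or `"exclude"`
#'   (gap columns removed from numerator and denominator).
#' @param maskPrimer,maskAmbiguity,indelAsEvent see [GapPolicy-class].
#' @return A [GapPolicy-class].
#' @export
gapPolicy <- function(mode = c("count", "exclude"), maskPrimer = TRUE,
                      maskAmbiguity = TRUE, indelAsEvent = FALSE) {
  mode <- match.arg(mode)
  new("GapPolicy", mode = mode, maskPrimer = maskPrimer,
      maskAmbiguity = maskAmbiguity, indelAsEvent = indelAsEvent)
}

#' ComparisonReport: site-level comparison of a structured alignment
#'
#' @slot siteChanges data.frame of per-site records (column, partner, helix,
#'   states, context, class).
#' @slot variableSitesWithGaps,variableSitesNoGaps variable-site counts
#'   under the two gap conventions.
#' @slot classCounts named integer vector over the change classes.
#' @slot perHelix named integer vector: substitution columns per helix.
#' @slot distanceWithGaps,distanceNoGaps p-distances under the two gap
#'   conventions.
#' @slot excludedColumns columns dropped by masking (primer/ambiguity).
#' @export
setClass("ComparisonReport",
  representation(siteChanges = "data.frame",
                 variableSitesWithGaps = "integer",
                 variableSitesNoGaps = "integer",
                 classCounts = "integer",
                 perHelix = "integer",
                 distanceWithGaps = "numeric",
                 distanceNoGaps = "numeric",
                 excludedColumns = "integer")
)

#' MotifReport: canonical ITS2 structural-motif checks
#'
#' @slot uuMismatch pyrimidine-pyrimidine (U-U type) internal mismatch in
#'   helix II found; `uuPosition` holds the 5' position of the facing bases.
#' @slot aRich A-rich region between helices II and III found;
#'   `aRichInterval` is its `c(start, end)`.
#' @slot gguMotif literal GGU on the 5' side of helix III before its apex;
#'   `gguPosition` is its start.
#' @slot branchedHelixI helix I region contains at least two child helices.
#' @slot helixCount number of top-level helices.
#' @slot warnings character vector of degeneracy warnings.
#' @export
setClass("MotifReport",
  representation(uuMismatch = "logical", uuPosition = "integer",
                 aRich = "logical", aRichInterval = "integer",
                 gguMotif = "logical", gguPosition = "integer",
                 branchedHelixI = "logical", helixCount = "integer",
                 warnings = "character")
)
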