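# Site-level comparison of two aligned sequences: variable-site detection
# under explicit gap policies, CBC / hemi-CBC / uncoupled classification of
# paired sites, and gap-aware p-distances.

# Column bookkeeping shared by variableSites / pDistance / compareStructured.
# Returns per-column state vectors and the masked / gap-gap / gap / sub /
# variable column index sets after applying the policy's masks.
.columnSets <- function(aln, policy) {
  a <- .chars(aln@rowA); b <- .chars(aln@rowB)
  L <- length(a)
  masked <- logical(L)
  if (policy@maskPrimer && length(aln@maskColumns))
    masked[aln@maskColumns] <- TRUE
  ambig <- vapply(a, .isAmbiguity, logical(1), USE.NAMES = FALSE) |
           vapply(b, .isAmbiguity, logical(1), USE.NAMES = FALSE)
  if (policy@maskAmbiguity) masked <- masked | ambig
  gapGap <- a == .GAP & b == .GAP
  usable <- !masked & !gapGap
  gapCol <- usable & xor(a == .GAP, b == .GAP)
  subCol <- usable & a != .GAP & b != .GAP & a != b
  list(a = a, b = b, L = L, masked = masked, ambig = ambig,
       gapGap = gapGap, usable = usable, gapCol = gapCol, subCol = subCol)
}

#' Variable sites between two aligned rows
#'
#' Under `mode = "count"` a column counts iff the two states differ,
#' residue-vs-gap included; under `mode = "exclude"` gap-containing columns
#' are skipped. Masked (primer / ambiguity) columns and gap-vs-gap columns
#' never count.
#'
#' @param aln a [PairAlignment-class].
#' @param policy a [GapPolicy-class].
#' @return Sorted integer vector of variable column indices.
#' @export
variableSites <- function(aln, policy = gapPolicy()) {
  cs <- .columnSets(aln, policy)
  if (policy@mode == "count") which(cs$subCol | cs$gapCol)
  else which(cs$subCol)
}

#' Classify a paired-site change between two taxa
#'
#' Given the base pair of taxon 1 (`before`) and taxon 2 (`after`) at one
#' structural pair: a CBC changes both sides while conserving
#' complementarity; a hemi-CBC changes exactly one side while conserving
#' complementarity; any change leaving at least one of the two pairs
#' non-complementary is an uncoupled substitution. Identical pairs give
#' `NA` (no change record).
#'
#' @param before,after length-2 character vectors `(base5', base3')` with
#'   no gaps (gaps are routed to indel handling upstream).
#' @return `"CBC"`, `"HEMI_CBC"`, `"UNCOUPLED"` or `NA_character_`.
#' @examples
#' classifyPairChange(c("G", "C"), c("A", "U"))  # CBC
#' classifyPairChange(c("G", "C"), c("G", "U"))  # HEMI_CBC
#' classifyPairChange(c("G", "C"), c("G", "A"))  # UNCOUPLED
#' @export
classifyPairChange <- function(before, after) {
  all4 <- c(before, after)
  if (any(all4 == .GAP)) .stopf("precondition error: gaps must be handled upstream")
  if (any(vapply(all4, .isAmbiguity, logical(1))))
    .stopf("ambiguity error: site with IUPAC ambiguity code must be excluded")
  d1 <- before[1L] != after[1L]; d2 <- before[2L] != after[2L]
  if (!d1 && !d2) return(NA_character_)
  compB <- isTRUE(isComplementary(before[1L], before[2L]))
  compA <- isTRUE(isComplementary(after[1L], after[2L]))
  if (compB && compA) {
    if (d1 && d2) "CBC" else "HEMI_CBC"
  } else "UNCOUPLED"
}

#' Compare two aligned sequences in their structural context
#'
#' Every variable column of the structured alignment is assigned exactly
#' one site-change record: substitutions at unpaired columns are loop
#' substitutions; columns involving a gap (their own states, or the states
#' at their pairing partner) are indels; paired substitutions are
#' classified as CBC / hemi-CBC / uncoupled. A CBC is one record covering
#' its two columns and is counted once per base pair.
#'
#' @param saln a [StructuredAlignment-class].
#' @param policy a [GapPolicy-class].
#' @return A [ComparisonReport-class].
#' @export
compareStructured <- function(saln, policy = gapPolicy()) {
  aln <- saln@alignment
  cs <- .columnSets(aln, policy)
  partner <- saln@partner
  helix <- saln@helix
  a <- cs$a; b <- cs$b
  # a paired column whose partner is masked cannot be assessed: exclude it too
  masked <- cs$masked
  pmask <- !is.na(partner) & masked[ifelse(is.na(partner), 1L, partner)]
  masked <- masked | pmask
  usable <- !masked & !cs$gapGap
  gapCol <- usable & xor(a == .GAP, b == .GAP)
  subCol <- usable & a != .GAP & b != .GAP & a != b
  variable <- which(gapCol | subCol)

  recs <- list()
  consumed <- logical(cs$L)
  addRec <- function(column, partnerCol, helixLab, klass, context) {
    recs[[length(recs) + 1L]] <<- data.frame(
      column = column, partner = if (is.na(partnerCol)) NA_integer_ else partnerCol,
      helix = if (is.na(helixLab)) NA_character_ else helixLab,
      stateA = a[column], stateB = b[column],
      context = context, klass = klass, stringsAsFactors = FALSE)
  }
  for (cc in variable) {
    if (consumed[cc]) next
    p <- partner[cc]
    ctx <- if (is.na(p)) "UNPAIRED" else "PAIRED"
    if (gapCol[cc]) { addRec(cc, p, helix[cc], "INDEL", ctx); next }
    if (is.na(p)) { addRec(cc, p, helix[cc], "LOOP_SUBSTITUTION", ctx); next }
    # paired substitution: does the partner column carry a gap?
    if (a[p] == .GAP || b[p] == .GAP) {
      addRec(cc, p, helix[cc], "INDEL", ctx); next
    }
    i <- min(cc, p); j <- max(cc, p)
    klass <- classifyPairChange(c(a[i], a[j]), c(b[i], b[j]))
    if (identical(klass, "CBC")) {
      addRec(i, j, helix[i], "CBC", "PAIRED")
      consumed[i] <- TRUE; consumed[j] <- TRUE
    } else {
      # hemi-CBC / uncoupled records consume one column each
      addRec(cc, p, helix[cc], klass, "PAIRED")
      consumed[cc] <- TRUE
    }
  }
  site <- if (length(recs)) do.call(rbind, recs)
          else data.frame(column = integer(), partner = integer(),
                          helix = character(), stateA = character(),
                          stateB = character(), context = character(),
                          klass = character(), stringsAsFactors = FALSE)
  site <- site[order(site$column), , drop = FALSE]
  rownames(site) <- NULL
  if (policy@indelAsEvent && any(site$klass == "INDEL")) {
    # collapse each maximal run of consecutive indel columns to one record
    idx <- which(site$klass == "INDEL")
    runStart <- c(TRUE, diff(site$column[idx]) != 1L)
    dropRows <- idx[!runStart]
    if (length(dropRows)) site <- site[-dropRows, , drop = FALSE]
    rownames(site) <- NULL
  }
  klasses <- c("CBC", "HEMI_CBC", "UNCOUPLED", "LOOP_SUBSTITUTION", "INDEL")
  counts <- stats::setNames(integer(length(klasses)), klasses)
  tab <- table(site$klass)
  counts[names(tab)] <- as.integer(tab)

  subRows <- site[site$klass %in% c("CBC", "HEMI_CBC", "UNCOUPLED"), , drop = FALSE]
  helixOf <- function(colIdx) helix[colIdx]
  perCols <- c(subRows$column,
               subRows$partner[subRows$klass == "CBC"],
               site$column[site$klass == "LOOP_SUBSTITUTION"])
  perLab <- helixOf(perCols)
  perLab <- perLab[!is.na(perLab)]
  perHelix <- if (length(perLab)) {
    t2 <- table(perLab)
    stats::setNames(as.integer(t2), names(t2))
  } else stats::setNames(integer(), character())

  distPolicy <- function(mode) {
    p2 <- policy; p2@mode <- mode
    pDistance(aln, p2)
  }
  new("ComparisonReport",
      siteChanges = site,
      variableSitesWithGaps = length(variable),
      variableSitesNoGaps = sum(subCol),
      classCounts = counts,
      perHelix = perHelix,
      distanceWithGaps = distPolicy("count"),
      distanceNoGaps = distPolicy("exclude"),
      excludedColumns = which(masked))
}

#' Gap-aware p-distance between two aligned rows
#'
#' Under `mode = "count"` the distance is (substitution columns + gap
#' columns) / all usable columns; under `mode = "exclude"` it is
#' substitution columns / (usable columns - gap columns). Gap-vs-gap and
#' masked columns are never part of numerator or denominator. The
#' counting-gaps distance is always >= the gaps-excluded distance.
#'
#' @param aln a [PairAlignment-class].
#' @param policy a [GapPolicy-class].
#' @return A fraction on `[0, 1]`.
#' @export
pDistance <- function(aln, policy = gapPolicy()) {
  cs <- .columnSets(aln, policy)
  total <- sum(cs$usable)
  nGap <- sum(cs$gapCol)
  nSub <- sum(cs$subCol)
  if (policy@mode == "count") {
    if (total == 0L) .stopf("undefined-distance error: no usable columns")
    (nSub + nGap) / total
  } else {
    if (total - nGap == 0L)
      .stopf("undefined-distance error: no gap-free usable columns")
    nSub / (total - nGap)
  }
}
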