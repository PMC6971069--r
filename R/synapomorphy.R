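# Mapping alignment changes onto clades of a supplied phylogeny and calling
# synapomorphies, non-homoplasious synapomorphies (NHS) and autapomorphies,
# for single columns and for paired-column couples (CBC/hemi-CBC patterns).

# ---- tree helpers (ape phylo) ------------------------------------------

.tipsUnder <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character()
  todo <- node
  while (length(todo)) {
    nd <- todo[1L]; todo <- todo[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    tips <- kids[kids <= ntip]
    out <- c(out, tree$tip.label[tips])
    todo <- c(todo, kids[kids > ntip])
  }
  out
}

.checkClade <- function(tree, clade) {
  if (!all(clade %in% tree$tip.label))
    .stopf("lookup error: clade tip(s) not in tree: %s",
           paste(setdiff(clade, tree$tip.label), collapse = ", "))
  if (length(clade) > 1L && !ape::is.monophyletic(tree, clade))
    .stopf("topology error: clade {%s} is not monophyletic",
           paste(clade, collapse = ","))
  invisible(TRUE)
}

# Tips of the sister group of `clade` (the other child subtrees of the
# parent of the clade's MRCA). Empty when the clade is the full tip set.
.sisterTips <- function(tree, clade) {
  ntip <- length(tree$tip.label)
  if (length(clade) == ntip) return(character())
  node <- if (length(clade) == 1L) which(tree$tip.label == clade)
          else ape::getMRCA(tree, clade)
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(parent) == 0L) return(setdiff(tree$tip.label, clade))
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], node)
  unlist(lapply(sibs, .tipsUnder, tree = tree))
}

.stateAt <- function(aln, tip, column) {
  if (!(tip %in% names(aln)))
    .stopf("lookup error: tip '%s' absent from alignment", tip)
  substr(aln[[tip]], column, column)
}

# ---- operations --------------------------------------------------------

#' Shared character state of a clade at one alignment column
#'
#' Gaps and ambiguity codes are ordinary states here: an indel shared by a
#' clade can be synapomorphic.
#'
#' @param aln named character vector (or list) of equal-length gapped rows.
#' @param column 1-based column index.
#' @param clade character vector of tip names.
#' @return The shared state, or `"POLYMORPHIC"` if clade members disagree.
#' @export
cladeState <- function(aln, column, clade) {
  aln <- as.list(aln)
  states <- vapply(clade, function(t) .stateAt(aln, t, column), character(1))
  if (length(unique(states)) == 1L) unname(states[1L]) else "POLYMORPHIC"
}

#' Classify one column of an alignment against one clade
#'
#' The clade's fixed state is "derived" when it differs from the state seen
#' in the clade's sister group (direct character mapping against the sister,
#' not ancestral-state reconstruction). A synapomorphy whose derived state
#' occurs in no tip outside the clade is non-homoplasious (NHS). A
#' single-tip clade with a derived state is an autapomorphy. A clade equal
#' to the full tip set has no outside and is never synapomorphic.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param column 1-based column index.
#' @param clade character vector of tip names (must be monophyletic).
#' @param tree a rooted `phylo` with tips matching the alignment names.
#' @return One-row data.frame: `column`, `clade`, `derivedState`, `klass`
#'   (`NHS`, `HOMOPLASIOUS_SYNAPOMORPHY`, `AUTAPOMORPHY`,
#'   `NOT_SYNAPOMORPHIC`), `isIndel`.
#' @export
classifySynapomorphy <- function(aln, column, clade, tree) {
  aln <- as.list(aln)
  .checkClade(tree, clade)
  cl <- function(klass, state = NA_character_) data.frame(
    column = column, clade = paste(sort(clade), collapse = ","),
    derivedState = state, klass = klass,
    isIndel = identical(state, .GAP), stringsAsFactors = FALSE)
  s <- cladeState(aln, column, clade)
  if (identical(s, "POLYMORPHIC")) return(cl("NOT_SYNAPOMORPHIC"))
  sis <- .sisterTips(tree, clade)
  if (!length(sis)) return(cl("NOT_SYNAPOMORPHIC", s))
  sisStates <- vapply(sis, function(t) .stateAt(aln, t, column), character(1))
  if (!any(sisStates != s)) return(cl("NOT_SYNAPOMORPHIC", s))
  if (length(clade) == 1L) return(cl("AUTAPOMORPHY", s))
  outside <- setdiff(names(aln), clade)
  outStates <- vapply(outside, function(t) .stateAt(aln, t, column), character(1))
  if (!any(outStates == s)) cl("NHS", s) else cl("HOMOPLASIOUS_SYNAPOMORPHY", s)
}

#' Classify a paired-column couple against one clade
#'
#' The clade's fixed base pair is compared, as a unit, with the sister
#' group and the rest of the tree. When pairing is conserved (both the
#' clade pair and the sister consensus pair complementary), the paired
#' change is additionally classified as a CBC (both sides changed) or
#' hemi-CBC (one side changed). The NHS criterion applies to the pair as a
#' unit: the clade's pair state must occur in no outside taxon.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param columns length-2 integer vector `(c1, c2)` of partner columns.
#' @param clade character vector of tip names (must be monophyletic).
#' @param tree a rooted `phylo`.
#' @return One-row data.frame: `column`, `partner`, `clade`,
#'   `derivedState` (e.g. `"G:C"`), `klass`, `pairedKlass`
#'   (`CBC` / `HEMI_CBC` / `NA`).
#' @export
classifyPairedSynapomorphy <- function(aln, columns, clade, tree) {
  aln <- as.list(aln)
  .checkClade(tree, clade)
  c1 <- columns[1L]; c2 <- columns[2L]
  cl <- function(klass, state = NA_character_, paired = NA_character_)
    data.frame(column = c1, partner = c2,
               clade = paste(sort(clade), collapse = ","),
               derivedState = state, klass = klass, pairedKlass = paired,
               stringsAsFactors = FALSE)
  s1 <- cladeState(aln, c1, clade); s2 <- cladeState(aln, c2, clade)
  if (identical(s1, "POLYMORPHIC") || identical(s2, "POLYMORPHIC"))
    return(cl("NOT_SYNAPOMORPHIC"))
  pairState <- paste(s1, s2, sep = ":")
  sis <- .sisterTips(tree, clade)
  if (!length(sis)) return(cl("NOT_SYNAPOMORPHIC", pairState))
  sisPairs <- vapply(sis, function(t)
    paste(.stateAt(aln, t, c1), .stateAt(aln, t, c2), sep = ":"), character(1))
  if (!any(sisPairs != pairState)) return(cl("NOT_SYNAPOMORPHIC", pairState))
  # sister consensus pair: the most frequent pair, first-seen on ties
  tab <- table(factor(sisPairs, levels = unique(sisPairs)))
  ref <- strsplit(names(tab)[which.max(tab)], ":", fixed = TRUE)[[1L]]
  d1 <- s1 != ref[1L]; d2 <- s2 != ref[2L]
  noGap <- !any(c(s1, s2, ref) == .GAP)
  compClade <- noGap && isTRUE(isComplementary(s1, s2))
  compRef <- noGap && isTRUE(isComplementary(ref[1L], ref[2L]))
  paired <- if (compClade && compRef && d1 && d2) "CBC"
            else if (compClade && compRef && xor(d1, d2)) "HEMI_CBC"
            else NA_character_
  if (length(clade) == 1L) return(cl("AUTAPOMORPHY", pairState, paired))
  outside <- setdiff(names(aln), clade)
  outPairs <- vapply(outside, function(t)
    paste(.stateAt(aln, t, c1), .stateAt(aln, t, c2), sep = ":"), character(1))
  if (!any(outPairs == pairState)) cl("NHS", pairState, paired)
  else cl("HOMOPLASIOUS_SYNAPOMORPHY", pairState, paired)
}

#' Scan an alignment for clade-supporting changes
#'
#' Every column (and, when a structure is supplied, every paired-column
#' couple) is classified against every requested clade. Output ordering is
#' deterministic: by column, then clade.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param tree a rooted `phylo`.
#' @param clades named list of tip-name vectors.
#' @param structure optional [SecondaryStructure-class] on the *alignment
#'   columns* (positions interpreted as columns); its couples are
#'   additionally classified with [classifyPairedSynapomorphy()].
#' @param keepAll keep `NOT_SYNAPOMORPHIC` rows too (default drops them).
#' @return A data.frame of calls; zero rows when nothing supports any clade.
#' @export
scanSynapomorphies <- function(aln, tree, clades, structure = NULL,
                               keepAll = FALSE) {
  aln <- as.list(aln)
  if (length(unique(nchar(unlist(aln)))) > 1L)
    .stopf("format error: alignment rows of unequal length")
  if (is.null(names(clades)))
    names(clades) <- vapply(clades, paste, character(1), collapse = ",")
  for (cl in clades) .checkClade(tree, cl)
  L <- nchar(aln[[1L]])
  pairedCols <- if (!is.null(structure)) structure@pairs
                else matrix(integer(), ncol = 2L)
  inPair <- c(pairedCols[, 1L], pairedCols[, 2L])
  out <- list()
  for (cc in seq_len(L)) {
    for (nm in names(clades)) {
      if (cc %in% inPair) {
        k <- which(pairedCols[, 1L] == cc)
        if (length(k)) {   # emit the couple once, at its 5' column
          rec <- classifyPairedSynapomorphy(aln, pairedCols[k, ], clades[[nm]], tree)
          rec$cladeName <- nm
          out[[length(out) + 1L]] <- rec
        }
        next
      }
      rec <- classifySynapomorphy(aln, cc, clades[[nm]], tree)
      rec$partner <- NA_integer_
      rec$pairedKlass <- NA_character_
      rec$cladeName <- nm
      rec$isIndel <- NULL
      out[[length(out) + 1L]] <- rec
    }
  }
  cols <- c("column", "partner", "cladeName", "clade", "derivedState",
            "klass", "pairedKlass")
  res <- if (length(out)) {
    res <- do.call(rbind, lapply(out, function(d) d[, cols, drop = FALSE]))
    res[order(res$column, res$cladeName), , drop = FALSE]
  } else {
    stats::setNames(data.frame(integer(), integer(), character(),
                               character(), character(), character(),
                               character(), stringsAsFactors = FALSE), cols)
  }
  if (!keepAll) res <- res[res$klass != "NOT_SYNAPOMORPHIC", , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read clade definitions from TSV
#'
#' Expected columns: `clade_name`, `tips` (comma-separated tip names).
#'
#' @param path path to the TSV file.
#' @return Named list of tip-name vectors.
#' @export
readCladesTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("clade_name", "tips") %in% names(tab)))
    .stopf("format error: clades TSV needs columns clade_name, tips")
  stats::setNames(lapply(strsplit(tab$tips, ","), trimws), tab$clade_name)
}
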