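# Synthetic-data generators with known ground truth. Every generator takes
# one integer seed, uses a private RNG stream, and is byte-deterministic
# for fixed seed + parameters, so each detector can be tested against the
# planted truth without any external data.

.WC <- c(A = "U", U = "A", G = "C", C = "G")
.COMP_PAIRS <- rbind(c("A","U"), c("U","A"), c("G","C"),
                     c("C","G"), c("G","U"), c("U","G"))

#' Generate a pseudoknot-free stem-loop template
#'
#' Builds `nHelices` consecutive stem-loops (strict Watson-Crick stems so
#' every planted wobble is a deliberate change), separated by single-strand
#' linkers, and labels the paired positions of helix k `"Hk"`.
#'
#' @param seed integer seed.
#' @param nHelices number of helices (>= 1).
#' @param helixLen stem length in base pairs.
#' @param loopLen hairpin loop length (nt).
#' @param linkerLen single-strand linker length between helices (nt).
#' @return A list with `seq` ([AnnotatedSequence-class]) and `structure`
#'   ([SecondaryStructure-class]).
#' @export
makeTemplate <- function(seed, nHelices = 5L, helixLen = 8L, loopLen = 5L,
                         linkerLen = 5L) {
  if (nHelices < 1L) .stopf("parameter error: nHelices must be >= 1")
  if (helixLen < 1L || loopLen < 0L || linkerLen < 0L)
    .stopf("parameter error: negative or zero geometry")
  .withSeed(seed, {
    chars <- character(); pairs <- list(); labels <- character()
    rnd <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)
    emit <- function(x) { chars <<- c(chars, x); length(chars) }
    emit(rnd(linkerLen))
    for (h in seq_len(nHelices)) {
      five <- rnd(helixLen)
      start5 <- length(chars) + 1L
      emit(five)
      emit(rnd(loopLen))
      start3 <- length(chars) + 1L
      emit(unname(.WC[rev(five)]))
      for (k in seq_len(helixLen)) {
        i <- start5 + k - 1L
        j <- start3 + helixLen - k
        pairs[[length(pairs) + 1L]] <- c(i, j)
        labels[as.character(i)] <- paste0("H", h)
        labels[as.character(j)] <- paste0("H", h)
      }
      emit(rnd(linkerLen))
    }
    res <- paste(chars, collapse = "")
    st <- secondaryStructure(do.call(rbind, pairs), seqId = "template",
                             helixLabels = labels, seqLength = nchar(res))
    list(seq = annotatedSequence("template", res), structure = st)
  })
}

# all complementary pairs (x', y') with the requested sides differing
.pairCandidates <- function(x, y, changeBoth) {
  keep <- apply(.COMP_PAIRS, 1L, function(p) {
    if (changeBoth) p[1L] != x && p[2L] != y
    else xor(p[1L] != x, p[2L] != y)
  })
  .COMP_PAIRS[keep, , drop = FALSE]
}

#' Plant classified changes into a template
#'
#' Mutates a copy of `seq` so that the pairwise comparison against the
#' original recovers exactly the requested counts: CBCs (both sides of a
#' pair changed, complementarity conserved), hemi-CBCs (one side changed,
#' complementarity conserved), uncoupled substitutions (complementarity
#' broken), loop substitutions (unpaired positions) and indels (deleted
#' runs at unpaired positions). Planted events never overlap and never
#' touch primer-masked positions.
#'
#' @param seq template [AnnotatedSequence-class].
#' @param st its [SecondaryStructure-class].
#' @param counts named integer vector over
#'   `CBC`, `HEMI_CBC`, `UNCOUPLED`, `LOOP_SUBSTITUTION`, `INDEL`
#'   (missing names = 0). `INDEL` counts deleted columns (runs of 1).
#' @param seed integer seed.
#' @return A list: `mutant` ([AnnotatedSequence-class]), `alignment`
#'   (gap-free template row A vs mutant row B with `-` at deleted
#'   positions), and `truth` (planted records + echoed parameters).
#' @export
plantChanges <- function(seq, st, counts, seed) {
  full <- c(CBC = 0L, HEMI_CBC = 0L, UNCOUPLED = 0L,
            LOOP_SUBSTITUTION = 0L, INDEL = 0L)
  full[names(counts)] <- as.integer(counts)
  counts <- full
  ch <- .chars(seq@residues)
  n <- length(ch)
  maskedPos <- if (length(seq@primerMask))
    unlist(lapply(seq_along(seq@primerMask), function(k)
      seq.int(IRanges::start(seq@primerMask)[k], IRanges::end(seq@primerMask)[k])))
  else integer()
  pairRows <- st@pairs
  okPair <- !(pairRows[, 1L] %in% maskedPos | pairRows[, 2L] %in% maskedPos)
  pairRows <- pairRows[okPair, , drop = FALSE]
  paired <- logical(n); paired[c(st@pairs[, 1L], st@pairs[, 2L])] <- TRUE
  unpairedPos <- setdiff(which(!paired), maskedPos)
  nPairChanges <- counts["CBC"] + counts["HEMI_CBC"] + counts["UNCOUPLED"]
  if (nPairChanges > nrow(pairRows))
    .stopf("capacity error: %d paired changes requested (CBC/HEMI_CBC/UNCOUPLED) but only %d usable pairs",
           nPairChanges, nrow(pairRows))
  if (counts["LOOP_SUBSTITUTION"] + counts["INDEL"] > length(unpairedPos))
    .stopf("capacity error: %d unpaired events requested (LOOP_SUBSTITUTION/INDEL) but only %d unpaired positions",
           counts["LOOP_SUBSTITUTION"] + counts["INDEL"], length(unpairedPos))
  .withSeed(seed, {
    mut <- ch
    deleted <- logical(n)
    planted <- list()
    note <- function(kind, i, j, before, after) planted[[length(planted) + 1L]] <<-
      data.frame(kind = kind, i = i, j = j, before = before, after = after,
                 stringsAsFactors = FALSE)
    pairIdx <- if (nrow(pairRows)) sample(nrow(pairRows), nPairChanges) else integer()
    take <- function(k) pairRows[pairIdx[k], ]
    k <- 0L
    for (m in seq_len(counts["CBC"])) {
      k <- k + 1L; pr <- take(k)
      cand <- .pairCandidates(ch[pr[1L]], ch[pr[2L]], changeBoth = TRUE)
      pick <- cand[sample(nrow(cand), 1L), ]
      note("CBC", pr[1L], pr[2L], paste0(ch[pr[1L]], ":", ch[pr[2L]]),
           paste0(pick[1L], ":", pick[2L]))
      mut[pr[1L]] <- pick[1L]; mut[pr[2L]] <- pick[2L]
    }
    for (m in seq_len(counts["HEMI_CBC"])) {
      k <- k + 1L; pr <- take(k)
      cand <- .pairCandidates(ch[pr[1L]], ch[pr[2L]], changeBoth = FALSE)
      pick <- cand[sample(nrow(cand), 1L), ]
      note("HEMI_CBC", pr[1L], pr[2L], paste0(ch[pr[1L]], ":", ch[pr[2L]]),
           paste0(pick[1L], ":", pick[2L]))
      mut[pr[1L]] <- pick[1L]; mut[pr[2L]] <- pick[2L]
    }
    for (m in seq_len(counts["UNCOUPLED"])) {
      k <- k + 1L; pr <- take(k)
      x <- ch[pr[1L]]; y <- ch[pr[2L]]
      bad <- setdiff(c("A", "C", "G", "U"), c(x, .COMPLEMENT_SETS[[y]]))
      pick <- sample(bad, 1L)
      note("UNCOUPLED", pr[1L], pr[2L], paste0(x, ":", y), paste0(pick, ":", y))
      mut[pr[1L]] <- pick
    }
    upool <- sample(unpairedPos)   # shuffled, consumed from the front
    for (m in seq_len(counts["LOOP_SUBSTITUTION"])) {
      p <- upool[1L]; upool <- upool[-1L]
      pick <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
      note("LOOP_SUBSTITUTION", p, NA_integer_, ch[p], pick)
      mut[p] <- pick
    }
    for (m in seq_len(counts["INDEL"])) {
      p <- upool[1L]; upool <- upool[-1L]
      deleted[p] <- TRUE
      note("INDEL", p, NA_integer_, ch[p], "-")
    }
    truth <- list(seed = seed,
                  counts = as.list(counts),
                  planted = if (length(planted)) do.call(rbind, planted)
                            else data.frame())
    rowB <- mut; rowB[deleted] <- "-"
    mutant <- annotatedSequence(paste0(seq@id, "_mut"),
                                paste(mut[!deleted], collapse = ""))
    list(mutant = mutant,
         alignment = pairAlignment(paste(ch, collapse = ""),
                                   paste(rowB, collapse = ""),
                                   idA = seq@id, idB = mutant@id),
         truth = truth)
  })
}

#' Generate a clade alignment with planted diagnostic columns
#'
#' All taxa start from one identical random sequence; for each requested
#' clade, `nhsSpec[[clade]]` columns receive a derived state fixed in the
#' clade and absent outside it (a planted non-homoplasious synapomorphy).
#' Remaining columns are neutral (identical across taxa).
#'
#' @param tree a `phylo` or a Newick string.
#' @param nhsSpec named list: clade name -> number of NHS columns; each
#'   clade name must also appear in `clades`.
#' @param clades named list of tip-name vectors (monophyletic in `tree`).
#' @param nNeutral number of neutral columns.
#' @param seed integer seed.
#' @return A list: `alignment` (named character vector), `truth` (planted
#'   columns and derived states per clade), `tree`.
#' @export
makeCladeAlignment <- function(tree, nhsSpec, clades, nNeutral = 50L, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  for (nm in names(nhsSpec)) {
    if (!nm %in% names(clades))
      .stopf("lookup error: clade '%s' has no tip-set definition", nm)
    .checkClade(tree, clades[[nm]])
  }
  tips <- tree$tip.label
  nPlanted <- sum(unlist(nhsSpec))
  L <- nNeutral + nPlanted
  .withSeed(seed, {
    base <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    rows <- matrix(rep(base, length(tips)), nrow = length(tips), byrow = TRUE,
                   dimnames = list(tips, NULL))
    cols <- sample(L, nPlanted)
    truth <- list(); cidx <- 0L
    for (nm in names(nhsSpec)) {
      take <- integer()
      for (m in seq_len(nhsSpec[[nm]])) {
        cidx <- cidx + 1L
        cc <- cols[cidx]
        derived <- sample(setdiff(c("A", "C", "G", "U"), base[cc]), 1L)
        rows[clades[[nm]], cc] <- derived
        take <- c(take, cc)
        truth[[length(truth) + 1L]] <- data.frame(
          clade = nm, column = cc, base = base[cc], derived = derived,
          stringsAsFactors = FALSE)
      }
    }
    aln <- apply(rows, 1L, paste, collapse = "")
    truthDf <- if (length(truth)) do.call(rbind, truth) else data.frame()
    list(alignment = aln,
         truth = list(seed = seed, planted = truthDf, nNeutral = nNeutral),
         tree = tree)
  })
}

#' Generate an intron-bearing rDNA query and its intron-free reference
#'
#' Emulates the architecture of algal SSU-ITS rDNA: an intron-free
#' reference with annotated SSU / ITS1 / 5.8S / ITS2 / LSU regions, and a
#' query carrying group I intron-like insertion blocks at random interior
#' positions of the named regions. Default region lengths mirror a typical
#' green-algal SSU-ITS read (about 2.7 kb total); default introns are five
#' 300-nt blocks in the SSU, the architecture reported for intron-rich
#' scenedesmacean strains.
#'
#' @param seed integer seed.
#' @param regionLengths named integer vector of region lengths (5' to 3').
#' @param intronSpec named list: region -> vector of intron lengths.
#' @return A list: `query` ([AnnotatedSequence-class], introns slot records
#'   the planted blocks in query coordinates), `reference` (intron-free,
#'   regions annotated), `truth` (insertion points and lengths).
#' @export
makeRdna <- function(seed,
                     regionLengths = c(SSU = 1700L, ITS1 = 250L, `5.8S` = 160L,
                                       ITS2 = 250L, LSU = 400L),
                     intronSpec = list(SSU = rep(300L, 5L))) {
  for (nm in names(intronSpec)) {
    if (!nm %in% names(regionLengths))
      .stopf("parameter error: intron region '%s' not among regions", nm)
    if (any(intronSpec[[nm]] > regionLengths[[nm]]))
      .stopf("parameter error: intron longer than region '%s'", nm)
  }
  .withSeed(seed, {
    total <- sum(regionLengths)
    refChars <- sample(c("A", "C", "G", "U"), total, replace = TRUE)
    ends <- cumsum(regionLengths)
    starts <- ends - regionLengths + 1L
    regIr <- IRanges::IRanges(start = starts, end = ends,
                              names = names(regionLengths))
    reference <- annotatedSequence("reference", paste(refChars, collapse = ""))
    reference@regions <- regIr
    # choose insertion points (reference position after which a block goes),
    # strictly interior and pairwise distinct
    ins <- list()
    for (nm in names(intronSpec)) {
      lens <- intronSpec[[nm]]
      lo <- starts[[nm]] + 10L; hi <- ends[[nm]] - 10L
      # keep insertion points >= 20 nt apart: with closely spaced blocks a
      # single merged gap can out-score two separate gap opens and the
      # planted coordinates would no longer be the unique optimum
      sep <- 20L
      k <- length(lens)
      span <- hi - lo + 1L - (k - 1L) * sep
      if (span < k)
        .stopf("parameter error: region '%s' too short for %d introns",
               nm, k)
      at <- sort(sample(seq.int(lo, lo + span - 1L), k)) +
            (seq_len(k) - 1L) * sep
      for (k in seq_along(lens))
        ins[[length(ins) + 1L]] <- list(after = at[k], len = lens[k])
    }
    ord <- order(vapply(ins, `[[`, numeric(1), "after"))
    ins <- ins[ord]
    qChars <- character(); cursor <- 1L
    qIntrons <- list(); shift <- 0L
    for (b in ins) {
      qChars <- c(qChars, refChars[cursor:b$after])
      block <- sample(c("A", "C", "G", "U"), b$len, replace = TRUE)
      # pin the block: boundary bases must differ from the flanking
      # reference bases, otherwise the insertion can slide in an equally
      # optimal alignment and the planted coordinates become ambiguous
      block[1L] <- sample(setdiff(c("A", "C", "G", "U"),
                                  refChars[b$after + 1L]), 1L)
      block[b$len] <- sample(setdiff(c("A", "C", "G", "U"),
                                     refChars[b$after]), 1L)
      startQ <- b$after + shift + 1L
      qIntrons[[length(qIntrons) + 1L]] <- c(startQ, startQ + b$len - 1L)
      qChars <- c(qChars, block)
      cursor <- b$after + 1L
      shift <- shift + b$len
    }
    qChars <- c(qChars, refChars[cursor:total])
    query <- annotatedSequence("query", paste(qChars, collapse = ""))
    query@introns <- .asIRanges(qIntrons)
    truth <- data.frame(
      after = vapply(ins, `[[`, numeric(1), "after"),
      length = vapply(ins, `[[`, numeric(1), "len"))
    list(query = query, reference = reference,
         truth = list(seed = seed, introns = truth))
  })
}

#' Generate a synthetic ITS2 record with planted motifs
#'
#' Builds a four-helix ITS2-like molecule carrying, by construction, all
#' four canonical motifs — branched helix I, a U-U mismatch in helix II,
#' an A-rich spacer between helices II and III, and GGU on the 5' side of
#' helix III — and optionally knocks exactly one of them out.
#'
#' @param seed integer seed.
#' @param knockout one of `"none"`, `"uu"`, `"arich"`, `"ggu"`, `"branch"`.
#' @return A list: `residues`, `structure`
#'   ([SecondaryStructure-class]), `truth` (expected motif booleans).
#' @export
makeIts2 <- function(seed, knockout = c("none", "uu", "arich", "ggu", "branch")) {
  knockout <- match.arg(knockout)
  .withSeed(seed, {
    chars <- character(); pairs <- list()
    rnd <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)
    put <- function(x) { chars <<- c(chars, x); invisible(length(chars)) }
    stem <- function(five) {   # returns function closing the stem
      s5 <- length(chars) + 1L
      put(five)
      function() {
        s3 <- length(chars) + 1L
        put(unname(.WC[rev(five)]))
        for (k in seq_along(five))
          pairs[[length(pairs) + 1L]] <<- c(s5 + k - 1L,
                                            s3 + length(five) - k)
      }
    }
    put(rnd(3L))
    # helix I: outer stem of 3, branched into two sub-stems unless knocked out
    closeI <- stem(rnd(3L))
    if (knockout == "branch") {
      put(rnd(6L))
    } else {
      closeIa <- stem(rnd(4L)); put(rnd(4L)); closeIa()
      put(rnd(2L))
      closeIb <- stem(rnd(4L)); put(rnd(4L)); closeIb()
    }
    closeI()
    put(rnd(3L))
    # helix II: stacked stems with a 1x1 facing mismatch between them
    mm <- if (knockout == "uu") c("A", "G") else c("U", "U")
    closeIIouter <- stem(rnd(3L))
    put(mm[1L])
    closeIIinner <- stem(rnd(3L)); put(rnd(4L)); closeIIinner()
    put(mm[2L])
    closeIIouter()
    # spacer with A-rich window
    put(if (knockout == "arich") c("U", "G", "C", "G", "U") else c("A", "A", "A", "A", "G"))
    # helix III: GGU leads the 5' strand
    lead <- if (knockout == "ggu") c("G", "A", "U") else c("G", "G", "U")
    closeIII <- stem(c(lead, rnd(5L))); put(rnd(4L)); closeIII()
    put(rnd(3L))
    closeIV <- stem(rnd(6L)); put(rnd(4L)); closeIV()
    put(rnd(3L))
    res <- paste(chars, collapse = "")
    st <- secondaryStructure(do.call(rbind, pairs), seqId = "its2_synth",
                             seqLength = nchar(res))
    expect <- list(uuMismatch = knockout != "uu",
                   aRich = knockout != "arich",
                   gguMotif = knockout != "ggu",
                   branchedHelixI = knockout != "branch",
                   helixCount = 4L)
    list(residues = res, structure = st,
         truth = list(seed = seed, knockout = knockout, motifs = expect))
  })
}
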