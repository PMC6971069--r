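#' Read a (multi-)FASTA file of rDNA sequences
#'
#' Residues are normalised to the RNA alphabet (`T` becomes `U`) and
#' lower-case runs — the convention for primer-binding regions — are
#' recorded in each sequence's primer mask before upper-casing. IUPAC
#' ambiguity codes are retained, never expanded.
#'
#' @param path path to a FASTA file.
#' @param regions optional region annotation table as produced by
#'   [readRegionsTsv()]; matching rows are attached by `seq_id`.
#' @return A list of [AnnotatedSequence-class] objects, named by id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgtACGT"), fa)
#' readFasta(fa)[["x"]]
#' @export
readFasta <- function(path, regions = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("format error: no records in %s", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    res <- as.character(set[[k]])
    if (!nzchar(res)) .stopf("format error: empty record '%s'", ids[k])
    out[[k]] <- annotatedSequence(ids[k], res)
  }
  names(out) <- ids
  if (!is.null(regions)) out <- lapply(out, .attachRegions, regions = regions)
  out
}

.attachRegions <- function(seq, regions) {
  rows <- regions[regions$seq_id == seq@id, , drop = FALSE]
  if (nrow(rows) == 0L) return(seq)
  isIntron <- tolower(rows$region) == "intron"
  reg <- rows[!isIntron, , drop = FALSE]
  intr <- rows[isIntron, , drop = FALSE]
  seq@regions <- IRanges::IRanges(start = reg$start, end = reg$end,
                                  names = reg$region)
  seq@introns <- IRanges::IRanges(start = intr$start, end = intr$end)
  validObject(seq)
  seq
}

#' Write AnnotatedSequences to FASTA
#'
#' Primer-masked positions are written lower-case so the mask round-trips.
#'
#' @param seqs a list of [AnnotatedSequence-class] (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "AnnotatedSequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    res <- .chars(s@residues)
    if (length(s@primerMask)) {
      idx <- unlist(lapply(seq_along(s@primerMask), function(k)
        seq.int(start(s@primerMask)[k], end(s@primerMask)[k])))
      res[idx] <- tolower(res[idx])
    }
    c(paste0(">", s@id), paste(res, collapse = ""))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a region/intron annotation TSV
#'
#' Expected columns: `seq_id`, `region`, `start`, `end` (1-based inclusive).
#' Rows with region `intron` are treated as intron intervals.
#'
#' @param path path to the TSV file.
#' @return A data.frame with the four columns.
#' @export
readRegionsTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "region", "start", "end")
  if (!all(need %in% names(tab)))
    .stopf("format error: annotation TSV needs columns %s",
           paste(need, collapse = ", "))
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab
}

#' Extract an annotated region as a new sequence
#'
#' Intron and primer-mask intervals overlapping the region are clipped and
#' re-based so that the extracted sequence starts at position 1.
#'
#' @param seq an [AnnotatedSequence-class].
#' @param name the region name to extract.
#' @return An [AnnotatedSequence-class] covering only that region.
#' @export
extractRegion <- function(seq, name) {
  if (!(name %in% names(seq@regions)))
    .stopf("lookup error: unknown region '%s' for sequence '%s'", name, seq@id)
  iv <- seq@regions[name]
  s <- start(iv); e <- end(iv)
  clip <- function(ir) {
    if (length(ir) == 0L) return(IRanges::IRanges())
    ir <- IRanges::restrict(ir, start = s, end = e)
    IRanges::shift(ir, -(s - 1L))
  }
  new("AnnotatedSequence",
      id = seq@id,
      residues = substr(seq@residues, s, e),
      regions = IRanges::IRanges(start = 1L, end = e - s + 1L, names = name),
      introns = clip(seq@introns),
      primerMask = clip(seq@primerMask))
}

#' Global pairwise alignment of two annotated sequences
#'
#' Needleman-Wunsch global alignment with affine gaps, used to put a query
#' against an intron-free reference (intron insertions then show up as long
#' gap blocks in the reference row) and to prepare sequences for structure
#' transfer. Defaults: match +2, mismatch -1, gap open -10, gap extend -0.5.
#' Primer masks of both inputs are carried over to alignment columns.
#'
#' @param a,b [AnnotatedSequence-class] objects (rows A and B).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters (penalties
#'   given as the negative values they subtract).
#' @return A [PairAlignment-class].
#' @export
alignGlobal <- function(a, b, match = 2, mismatch = -1,
                        gapOpen = -10, gapExtend = -0.5) {
  if (!nchar(a@residues) || !nchar(b@residues))
    .stopf("precondition error: cannot align an empty sequence")
  toDNA <- function(x) Biostrings::DNAString(chartr("U", "T", x@residues))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    toDNA(a), toDNA(b), type = "global", substitutionMatrix = mat,
    gapOpening = abs(gapOpen), gapExtension = abs(gapExtend))
  ra <- chartr("T", "U", as.character(Biostrings::alignedPattern(pa)))
  rb <- chartr("T", "U", as.character(Biostrings::alignedSubject(pa)))
  mask <- sort(unique(c(.maskToColumns(a, ra), .maskToColumns(b, rb))))
  pairAlignment(ra, rb, idA = a@id, idB = b@id, maskColumns = mask)
}

.maskToColumns <- function(seq, gappedRow) {
  if (length(seq@primerMask) == 0L) return(integer())
  p2c <- .posToCol(gappedRow)
  pos <- unlist(lapply(seq_along(seq@primerMask), function(k)
    seq.int(start(seq@primerMask)[k], end(seq@primerMask)[k])))
  p2c[pos]
}

#' Excise group I introns by insertion-block detection
#'
#' Given an alignment of a query against an intron-free reference, every
#' maximal run of at least `minInsert` consecutive columns where the
#' reference has gaps and the query has residues is excised from the query
#' and reported as one intron. Group I introns in algal rDNA are hundreds of
#' nucleotides long, so the default threshold of 50 nt separates them
#' cleanly from ordinary alignment slop.
#'
#' @param aln a [PairAlignment-class]; by default row A is the query and
#'   row B the intron-free reference.
#' @param minInsert minimum insertion-block length, in nt (>= 1).
#' @param queryRow `"a"` or `"b"`: which row is the query.
#' @return A list with `query`, the intron-free [AnnotatedSequence-class]
#'   (introns slot records the excised blocks in original query
#'   coordinates), and `introns`, an `IRanges` of those intervals.
#' @export
exciseIntrons <- function(aln, minInsert = 50L, queryRow = c("a", "b")) {
  queryRow <- match.arg(queryRow)
  if (minInsert < 1L) .stopf("parameter error: minInsert must be >= 1")
  q <- if (queryRow == "a") aln@rowA else aln@rowB
  r <- if (queryRow == "a") aln@rowB else aln@rowA
  qid <- if (queryRow == "a") aln@idA else aln@idB
  qc <- .chars(q); rc <- .chars(r)
  insert <- rc == .GAP & qc != .GAP
  runs <- rle(insert)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keepRun <- runs$values & runs$lengths >= minInsert
  qpos <- cumsum(qc != .GAP)   # query position at each column
  intronStart <- qpos[starts[keepRun]]
  intronEnd <- qpos[ends[keepRun]]
  drop <- rep(FALSE, length(qc))
  for (k in which(keepRun)) drop[starts[k]:ends[k]] <- TRUE
  kept <- qc[!drop & qc != .GAP]
  seqOut <- annotatedSequence(qid, paste(kept, collapse = ""))
  iv <- IRanges::IRanges(start = as.integer(intronStart),
                         end = as.integer(intronEnd))
  seqOut@introns <- IRanges::IRanges()   # coordinates below are pre-excision
  list(query = seqOut, introns = iv)
}

#' Read a Newick phylogeny
#'
#' @param path path to a Newick file.
#' @return An `ape` `phylo` object with unique, named tips.
#' @export
readTree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) .stopf("format error: unparseable Newick: %s",
                                            conditionMessage(e)))
  if (is.null(tr)) .stopf("format error: unparseable Newick file %s", path)
  if (anyDuplicated(tr$tip.label))
    .stopf("format error: duplicate tip names in %s", path)
  tr
}

#' Write / read tabular reports
#'
#' Reports (data.frames) round-trip losslessly through TSV or JSON.
#'
#' @param report a data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(report, path, dataframe = "columns", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
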