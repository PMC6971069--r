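# Internal helpers shared across modules.

# IUPAC nucleotide alphabet on the RNA side (after T -> U normalisation).
.IUPAC_RNA <- c("A", "C", "G", "U",
                "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.STANDARD_RNA <- c("A", "C", "G", "U")
.GAP <- "-"

# Allowed partners in an rRNA stem: Watson-Crick plus G.U wobble.
.COMPLEMENT_SETS <- list(
  A = "U",
  C = "G",
  G = c("C", "U"),
  U = c("A", "G")
)

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.isAmbiguity <- function(b) !(b %in% c(.STANDARD_RNA, .GAP))

.normalizeResidues <- function(x) {
  x <- toupper(x)
  chartr("T", "U", x)
}

.checkAlphabet <- function(x, id = "<sequence>") {
  ch <- .chars(x)
  bad <- which(!(ch %in% .IUPAC_RNA))
  if (length(bad)) {
    stop(sprintf(
      "format error: non-IUPAC character '%s' at position %d of record '%s'",
      ch[bad[1L]], bad[1L], id), call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards. Generators never leak
# global random state.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("parameter error: 'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Map ungapped residue positions to alignment columns for one gapped row.
.posToCol <- function(gappedRow) {
  ch <- .chars(gappedRow)
  which(ch != .GAP)
}

# Inverse: alignment column -> ungapped position (NA on gap columns).
.colToPos <- function(gappedRow) {
  ch <- .chars(gappedRow)
  pos <- cumsum(ch != .GAP)
  pos[ch == .GAP] <- NA_integer_
  pos
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
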