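# Independent oracles and small fixture builders used across tests.

# Exhaustive maximum-pairing oracle: recursively enumerates every nested
# structure over complementary pairs (A.U, G.C, G.U) with j - i > minLoop
# and returns the maximum pair count. Exponential, fine for n <= 12.
bruteMaxPairs <- function(seq, minLoop = 3L) {
  ch <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  comp <- function(x, y) {
    any(paste0(x, y) == c("AU", "UA", "GC", "CG", "GU", "UG"))
  }
  rec <- function(i, j) {
    if (i >= j || j - i <= minLoop) return(0L)
    best <- rec(i + 1L, j)                 # i unpaired
    for (k in (i + minLoop + 1L):j) {
      if (comp(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(ch) < 2L) return(0L)
  rec(1L, length(ch))
}

# Naive per-column p-distance, written directly from the definition.
naiveDistances <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  gap <- xor(ca == "-", cb == "-")
  sub <- !gap & ca != cb
  list(withGaps = (sum(sub) + sum(gap)) / length(ca),
       noGaps = sum(sub) / (length(ca) - sum(gap)))
}

# Random gapped alignment pair over ACGU- (never a gap-gap column).
randomAlignment <- function(n, pGap = 0.12) {
  bases <- c("A", "C", "G", "U")
  a <- sample(bases, n, replace = TRUE)
  b <- sample(bases, n, replace = TRUE)
  gapIn <- sample(c("a", "b", "none"), n, replace = TRUE,
                  prob = c(pGap / 2, pGap / 2, 1 - pGap))
  a[gapIn == "a"] <- "-"
  b[gapIn == "b"] <- "-"
  pairAlignment(paste(a, collapse = ""), paste(b, collapse = ""))
}

writeTempFasta <- function(..., dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  writeLines(unlist(list(...)), path)
  path
}
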