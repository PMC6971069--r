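#' Maximum base-pairing fold (Nussinov-style)
#'
#' A deliberately simple, brute-force-checkable folder: it returns a nested
#' pair set maximising the number of complementary pairs (A.U, G.C, G.U)
#' subject to a minimum hairpin loop of `minLoop` unpaired bases. It exists
#' so synthetic test structures can be generated and cross-checked without
#' an external thermodynamic folder; it is not an energy model and real
#' ITS2/SSU structures should be supplied from files instead.
#'
#' Traceback is deterministic: position `i` is paired with the smallest
#' legal partner achieving the optimum; leaving `i` unpaired is chosen only
#' when no pairing achieves it.
#'
#' @param seq residue string (RNA; `T` normalised to `U`). Ambiguity codes
#'   never pair.
#' @param minLoop minimum number of unpaired bases enclosed by a pair
#'   (default 3): a pair `(i, j)` requires `j - i > minLoop`.
#' @param seqId id recorded on the returned structure.
#' @return A [SecondaryStructure-class].
#' @examples
#' length(foldMaxPairing("GGGAAACCC"))  # 3 pairs
#' @export
foldMaxPairing <- function(seq, minLoop = 3L, seqId = NA_character_) {
  seq <- .normalizeResidues(seq)
  ch <- .chars(seq)
  n <- length(ch)
  if (n < 1L) .stopf("precondition error: empty sequence")
  if (minLoop < 0L) .stopf("parameter error: minLoop must be >= 0")
  canPair <- function(i, j) isTRUE(isComplementary(ch[i], ch[j]))
  M <- matrix(0L, n, n)
  if (n - 1L >= minLoop + 1L) {
    for (span in seq.int(minLoop + 1L, n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]                      # i unpaired
        for (k in seq.int(i + minLoop + 1L, j)) { # i paired with k
          if (canPair(i, k)) {
            inside <- if (k - i >= 2L) M[i + 1L, k - 1L] else 0L
            rest <- if (k < j) M[k + 1L, j] else 0L
            cand <- 1L + inside + rest
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- list()
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || j - i <= minLoop || M[i, j] == 0L) next
    paired <- FALSE
    for (k in seq.int(i + minLoop + 1L, j)) {   # smallest legal partner first
      if (canPair(i, k)) {
        inside <- if (k - i >= 2L) M[i + 1L, k - 1L] else 0L
        rest <- if (k < j) M[k + 1L, j] else 0L
        if (1L + inside + rest == M[i, j]) {
          pairs[[length(pairs) + 1L]] <- c(i, k)
          if (k - i >= 2L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          paired <- TRUE
          break
        }
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  pm <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), ncol = 2L)
  secondaryStructure(pm, seqId = seqId, seqLength = n)
}
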