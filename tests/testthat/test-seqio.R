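test_that("FASTA reading normalises T to U and records lower-case primer runs", {
  fa <- writeTempFasta(">x", "ACGT")
  s <- readFasta(fa)[["x"]]
  expect_equal(residues(s), "ACGU")
  expect_length(primerMask(s), 0)

  fa2 <- writeTempFasta(">x", "acgtACGU")
  s2 <- readFasta(fa2)[["x"]]
  expect_equal(residues(s2), "ACGUACGU")
  expect_equal(IRanges::start(primerMask(s2)), 1L)
  expect_equal(IRanges::end(primerMask(s2)), 4L)

  expect_error(readFasta(writeTempFasta(">x", "")), "empty record")
  expect_error(annotatedSequence("x", "ACGZ"), "position 4")
})

test_that("region extraction slices residues and re-bases annotations", {
  res <- paste(rep("ACGU", 25), collapse = "")  # 100 nt
  s <- annotatedSequence("x", res,
                         regions = list(SSU = c(1, 60), ITS2 = c(61, 90)),
                         introns = list(c(10, 30)))
  ssu <- extractRegion(s, "SSU")
  expect_equal(length(ssu), 60L)
  expect_equal(residues(ssu), substr(res, 1, 60))
  expect_equal(IRanges::start(introns(ssu)), 10L)
  its2 <- extractRegion(s, "ITS2")
  expect_equal(length(its2), 30L)
  expect_length(introns(its2), 0)
  expect_error(extractRegion(s, "ITS9"), "lookup error")
})

test_that("global alignment is deterministic, gap-correct and rejects empty input", {
  a <- annotatedSequence("a", "ACGU")
  ident <- alignGlobal(a, annotatedSequence("b", "ACGU"))
  expect_equal(rowA(ident), "ACGU")
  expect_equal(rowB(ident), "ACGU")

  # 4x3 instance checked by exhaustive inspection of the DP: deleting C is
  # the unique optimum (score 3*2 - 10.5 = -4.5; any substitution path
  # scores lower), so row B gets exactly one 1-column gap opposite C
  aln <- alignGlobal(a, annotatedSequence("b", "AGU"))
  expect_equal(rowA(aln), "ACGU")
  expect_equal(rowB(aln), "A-GU")
  aln2 <- alignGlobal(a, annotatedSequence("b", "AGU"))
  expect_identical(rowA(aln2), rowA(aln))

  expect_error(alignGlobal(annotatedSequence("a", "A"),
                           new("AnnotatedSequence", id = "b", residues = "")),
               "precondition error")
})

test_that("primer masks are carried onto alignment columns", {
  a <- annotatedSequence("a", "acgAACGGUU")   # mask positions 1-3
  b <- annotatedSequence("b", "ACGAACGGUU")
  aln <- alignGlobal(a, b)
  expect_equal(maskColumns(aln), 1:3)
})

test_that("intron excision reports maximal insertion blocks above threshold", {
  # identical rows: nothing to excise, query unchanged (idempotence)
  aln0 <- pairAlignment("ACGUACGU", "ACGUACGU", "q", "r")
  r0 <- exciseIntrons(aln0, minInsert = 2)
  expect_length(r0$introns, 0)
  expect_equal(residues(r0$query), "ACGUACGU")

  # single planted block of 6 against a gap run in the reference
  q <- "ACGUGGGGGGACGU"; r <- "ACGU------ACGU"
  r1 <- exciseIntrons(pairAlignment(q, r, "q", "r"), minInsert = 5)
  expect_length(r1$introns, 1)
  expect_equal(IRanges::start(r1$introns), 5L)
  expect_equal(IRanges::end(r1$introns), 10L)
  expect_equal(residues(r1$query), "ACGUACGU")

  # below threshold: block kept
  r2 <- exciseIntrons(pairAlignment(q, r, "q", "r"), minInsert = 7)
  expect_length(r2$introns, 0)
  expect_equal(residues(r2$query), q)

  expect_error(pairAlignment("ACGU", "ACG"), "unequal length")
})

test_that("reported introns reconstruct the original query exactly", {
  for (s in 1:5) {
    rd <- makeRdna(s, regionLengths = c(SSU = 400L, LSU = 120L),
                   intronSpec = list(SSU = c(80L, 60L)))
    ex <- exciseIntrons(alignGlobal(rd$query, rd$reference), minInsert = 50)
    rebuilt <- strsplit(residues(ex$query), "")[[1]]
    orig <- strsplit(residues(rd$query), "")[[1]]
    for (k in seq_along(ex$introns)) {
      at <- IRanges::start(ex$introns)[k]
      piece <- orig[at:IRanges::end(ex$introns)[k]]
      rebuilt <- append(rebuilt, piece, after = at - 1L)
    }
    expect_identical(paste(rebuilt, collapse = ""), residues(rd$query))
  }
})

test_that("Newick trees parse with addressable clades and reject duplicates", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", nwk)
  tr <- readTree(nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(ape::is.monophyletic(tr, c("B", "C")))
  writeLines("(A,(A,C));", nwk)
  expect_error(readTree(nwk), "duplicate tip names")
})

test_that("reports round-trip losslessly through TSV", {
  rep <- data.frame(column = c(3L, 9L), klass = c("CBC", "INDEL"),
                    stateA = c("G", "A"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeReport(rep, path, "tsv")
  expect_equal(readReport(path, "tsv"), rep)
})
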