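test_that("dot-bracket and CT dialects produce identical pair sets", {
  db <- tempfile(fileext = ".db")
  writeLines(c(">s", "GGAAACC", "((...))"), db)
  st <- parseStructure(db, "dotbracket")
  expect_equal(basePairs(st), matrix(c(1L, 2L, 7L, 6L), ncol = 2,
                                     dimnames = list(NULL, c("i", "j"))))

  ct <- tempfile(fileext = ".ct")
  writeStructure(st, ct, "ct", residues = "GGAAACC")
  st2 <- parseStructure(ct, "ct")
  expect_equal(basePairs(st2), basePairs(st))

  writeLines(c(">s", "(()"), db)
  expect_error(parseStructure(db, "dotbracket"), "unmatched")
})

test_that("crossing pairs are rejected as pseudoknots", {
  expect_error(secondaryStructure(rbind(c(1, 8), c(4, 12))), "pseudoknot")
  # CT file encoding the same crossing pairing
  ct <- tempfile(fileext = ".ct")
  partner <- integer(12); partner[c(1, 8)] <- c(8, 1); partner[c(4, 12)] <- c(12, 4)
  writeLines(c("12 s", sprintf("%d A %d %d %d %d", 1:12, 0:11,
                               c(2:12, 0), partner, 1:12)), ct)
  expect_error(parseStructure(ct, "ct"), "pseudoknot")
})

test_that("helix labels load from the sidecar and must sit on paired positions", {
  db <- tempfile(fileext = ".db")
  writeLines(c(">s", "((...))"), db)
  sc <- tempfile(fileext = ".tsv")
  writeLines(c("position\thelix", "1\tH1", "7\tH1"), sc)
  st <- parseStructure(db, "dotbracket", helixSidecar = sc)
  expect_equal(unname(helixLabels(st)[c("1", "7")]), c("H1", "H1"))
  writeLines(c("position\thelix", "3\tH1"), sc)  # position 3 is a loop base
  expect_error(parseStructure(db, "dotbracket", helixSidecar = sc), "paired")
})

test_that("complementarity covers Watson-Crick, wobble and ambiguity", {
  expect_true(isComplementary("A", "U"))
  expect_true(isComplementary("G", "U"))
  expect_true(isComplementary("C", "G"))
  expect_false(isComplementary("A", "G"))
  expect_false(isComplementary("U", "U"))
  expect_true(is.na(isComplementary("N", "U")))
  expect_true(is.na(isComplementary("R", "Y")))
})

test_that("structure mapping tracks alignment columns through gaps", {
  st <- secondaryStructure(rbind(c(1, 7), c(2, 6)), seqLength = 7)
  gapFree <- pairAlignment("GGAAACC", "GGAAACC")
  sa <- mapStructure(st, gapFree, "a")
  expect_equal(partnerColumns(sa)[1], 7L)
  expect_equal(partnerColumns(sa)[2], 6L)

  # a gap inserted before reference position 2 shifts its column by one
  shifted <- pairAlignment("G-GAAACC", "GUGAAACC")
  sa2 <- mapStructure(st, shifted, "a")
  expect_equal(partnerColumns(sa2)[1], 8L)
  expect_equal(partnerColumns(sa2)[3], 7L)
  expect_true(is.na(partnerColumns(sa2)[2]))

  big <- secondaryStructure(rbind(c(1, 20)), seqLength = 20)
  expect_error(mapStructure(big, gapFree, "a"), "consistency error")
})

test_that("structure transfer drops gapped pairs, flags broken ones, keeps labels", {
  st <- secondaryStructure(rbind(c(1, 7), c(2, 6)), seqId = "a",
                           helixLabels = c(`1` = "H1", `7` = "H1"),
                           seqLength = 7)
  # identity alignment: query structure equals template
  ident <- pairAlignment("GGAAACC", "GGAAACC")
  tr <- transferStructure(st, ident)
  expect_equal(basePairs(tr$structure), basePairs(st))
  expect_equal(nrow(tr$flags), 0L)
  expect_equal(unname(helixLabels(tr$structure)[c("1", "7")]), c("H1", "H1"))

  # query gap at one partner: pair dropped and reported
  gap <- pairAlignment("GGAAACC", "GGAAAC-")
  tr2 <- transferStructure(st, gap)
  expect_equal(nrow(basePairs(tr2$structure)), 1L)
  expect_equal(tr2$flags$reason, "gap")
  expect_equal(tr2$flags$templateI, 1L)

  # non-complementary query bases: pair kept but flagged
  brk <- pairAlignment("GGAAACC", "GGAAACA")
  tr3 <- transferStructure(st, brk)
  expect_equal(nrow(basePairs(tr3$structure)), 2L)
  expect_true("non_complementary" %in% tr3$flags$reason)
})

test_that("transferred structures are always nested and never pair a gap column", {
  for (s in 1:10) {
    tpl <- makeTemplate(s, nHelices = 4, helixLen = 6, loopLen = 4)
    res <- plantChanges(tpl$seq, tpl$structure,
                        c(UNCOUPLED = 2L, INDEL = 3L), seed = s + 100)
    tr <- transferStructure(tpl$structure, res$alignment)
    expect_true(validObject(tr$structure))  # validity enforces nestedness
    qlen <- nchar(residues(res$mutant))
    if (nrow(basePairs(tr$structure)))
      expect_true(all(basePairs(tr$structure) <= qlen))
  }
})
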