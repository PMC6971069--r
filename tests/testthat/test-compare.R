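test_that("variable sites respect the gap policy", {
  same <- pairAlignment("ACGU", "ACGU")
  expect_length(variableSites(same, gapPolicy("count")), 0)

  g <- pairAlignment("AC-U", "ACGU")
  expect_equal(variableSites(g, gapPolicy("count")), 3L)
  expect_length(variableSites(g, gapPolicy("exclude")), 0)

  s <- pairAlignment("ACGU", "ACGA")
  expect_equal(variableSites(s, gapPolicy("count")), 4L)
  expect_equal(variableSites(s, gapPolicy("exclude")), 4L)
})

test_that("masked and ambiguity columns never count", {
  aln <- pairAlignment("ACGUN", "GCGUA", maskColumns = 1L)
  expect_length(variableSites(aln, gapPolicy("count")), 0)  # col1 masked, col5 ambiguous
  noMask <- gapPolicy("count", maskPrimer = FALSE, maskAmbiguity = FALSE)
  expect_equal(variableSites(aln, noMask), c(1L, 5L))
})

test_that("paired-site changes classify by the CBC / hemi-CBC definitions", {
  expect_equal(classifyPairChange(c("G", "C"), c("A", "U")), "CBC")
  expect_equal(classifyPairChange(c("G", "C"), c("G", "U")), "HEMI_CBC")
  expect_equal(classifyPairChange(c("G", "C"), c("G", "A")), "UNCOUPLED")
  expect_equal(classifyPairChange(c("A", "U"), c("G", "U")), "HEMI_CBC")
  expect_equal(classifyPairChange(c("U", "A"), c("C", "G")), "CBC")
  # change out of an already non-complementary pair stays uncoupled
  expect_equal(classifyPairChange(c("A", "C"), c("G", "C")), "UNCOUPLED")
  expect_true(is.na(classifyPairChange(c("G", "C"), c("G", "C"))))
  expect_error(classifyPairChange(c("N", "C"), c("G", "C")), "ambiguity")
})

test_that("p-distance matches hand enumeration and the two-policy ordering", {
  # 10 columns, 2 substitutions, 1 gap column
  aln <- pairAlignment("ACGUACGUA-", "ACGAACGCAU")
  expect_equal(pDistance(aln, gapPolicy("count")), 0.30)
  expect_equal(pDistance(aln, gapPolicy("exclude")), 2 / 9)

  same <- pairAlignment("ACGU", "ACGU")
  expect_equal(pDistance(same, gapPolicy("count")), 0)
  expect_equal(pDistance(same, gapPolicy("exclude")), 0)

  allGap <- pairAlignment("AC", "--")
  expect_error(pDistance(allGap, gapPolicy("exclude")), "undefined-distance")
})

test_that("distances and counts are symmetric in the two rows", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      aln <- randomAlignment(60)
      swp <- pairAlignment(rowB(aln), rowA(aln))
      for (mode in c("count", "exclude")) {
        pol <- gapPolicy(mode)
        expect_equal(pDistance(aln, pol), pDistance(swp, pol))
        expect_equal(length(variableSites(aln, pol)),
                     length(variableSites(swp, pol)))
      }
    }
  })
})

test_that("counting gaps never gives a smaller distance than excluding them", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      aln <- randomAlignment(sample(20:120, 1))
      dW <- pDistance(aln, gapPolicy("count"))
      dN <- tryCatch(pDistance(aln, gapPolicy("exclude")), error = function(e) NA)
      if (!is.na(dN)) expect_gte(dW, dN)
    }
  })
})

test_that("structured comparison of identical rows is all-zero", {
  tpl <- makeTemplate(5, nHelices = 3)
  aln <- pairAlignment(residues(tpl$seq), residues(tpl$seq))
  rep <- compareStructured(mapStructure(tpl$structure, aln, "a"))
  expect_equal(rep@variableSitesWithGaps, 0L)
  expect_equal(sum(classCounts(rep)), 0L)
  expect_equal(rep@distanceWithGaps, 0)
})

test_that("structured comparison recovers planted change classes exactly", {
  tpl <- makeTemplate(2, nHelices = 8, helixLen = 7, loopLen = 6)
  counts <- c(CBC = 3L, HEMI_CBC = 2L, UNCOUPLED = 1L, LOOP_SUBSTITUTION = 4L)
  res <- plantChanges(tpl$seq, tpl$structure, counts, seed = 9)
  rep <- compareStructured(mapStructure(tpl$structure, res$alignment, "a"))
  expect_equal(classCounts(rep)[names(counts)], counts)
  expect_equal(classCounts(rep)[["INDEL"]], 0L)
})

test_that("class counts partition the variable sites (CBC spans two columns)", {
  for (s in 1:10) {
    tpl <- makeTemplate(s, nHelices = 10)
    res <- plantChanges(tpl$seq, tpl$structure,
                        c(CBC = 4L, HEMI_CBC = 3L, UNCOUPLED = 2L,
                          LOOP_SUBSTITUTION = 3L, INDEL = 2L), seed = s * 13)
    rep <- compareStructured(mapStructure(tpl$structure, res$alignment, "a"))
    cc <- classCounts(rep)
    expect_equal(2L * cc[["CBC"]] + cc[["HEMI_CBC"]] + cc[["UNCOUPLED"]] +
                 cc[["LOOP_SUBSTITUTION"]] + cc[["INDEL"]],
                 rep@variableSitesWithGaps)
  }
})

test_that("per-helix tallies attribute substitution columns to their helix", {
  tpl <- makeTemplate(4, nHelices = 2, helixLen = 6, loopLen = 5)
  res <- plantChanges(tpl$seq, tpl$structure, c(CBC = 2L), seed = 3)
  rep <- compareStructured(mapStructure(tpl$structure, res$alignment, "a"))
  expect_equal(sum(rep@perHelix), 4L)  # 2 CBCs x 2 columns, all in helices
})

test_that("primer-masked columns are excluded from structured comparisons", {
  s <- annotatedSequence("t", "acGGGGAAAACCCC")  # mask 1-2
  st <- secondaryStructure(cbind(3:6, 14:11), seqId = "t", seqLength = 14)
  mut <- annotatedSequence("m", "ugGGGGAAAACCCC")  # changes only in mask
  aln <- pairAlignment(residues(s), residues(mut), maskColumns = 1:2)
  rep <- compareStructured(mapStructure(st, aln, "a"))
  expect_equal(rep@variableSitesWithGaps, 0L)
  rep2 <- compareStructured(mapStructure(st, aln, "a"),
                            gapPolicy("count", maskPrimer = FALSE))
  expect_equal(rep2@variableSitesWithGaps, 2L)
})
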