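balanced4 <- ape::read.tree(text = "((A,B),(C,D));")

test_that("clade states are the shared state or POLYMORPHIC", {
  aln <- c(A = "GGC", B = "GUC", C = "AUC", D = "AUC")
  expect_equal(cladeState(aln, 1, c("A", "B")), "G")
  expect_equal(cladeState(aln, 2, c("A", "B")), "POLYMORPHIC")
  expect_error(cladeState(aln, 1, c("A", "Z")), "lookup error")
})

test_that("single-column calls follow the NHS / homoplasy definitions", {
  aln <- c(A = "G", B = "G", C = "U", D = "U")
  call <- classifySynapomorphy(aln, 1, c("A", "B"), balanced4)
  expect_equal(call$klass, "NHS")
  expect_equal(call$derivedState, "G")

  # derived state recurs outside the clade: homoplasious
  aln2 <- c(A = "G", B = "G", C = "U", D = "G")
  expect_equal(classifySynapomorphy(aln2, 1, c("A", "B"), balanced4)$klass,
               "HOMOPLASIOUS_SYNAPOMORPHY")

  # non-monophyletic tip set is a topology error
  expect_error(classifySynapomorphy(aln, 1, c("A", "B", "C"), balanced4),
               "topology error")

  # single-tip clade with a unique state is an autapomorphy
  aln3 <- c(A = "C", B = "G", C = "G", D = "G")
  expect_equal(classifySynapomorphy(aln3, 1, "A", balanced4)$klass,
               "AUTAPOMORPHY")

  # polymorphic clade is never synapomorphic
  aln4 <- c(A = "G", B = "C", C = "U", D = "U")
  expect_equal(classifySynapomorphy(aln4, 1, c("A", "B"), balanced4)$klass,
               "NOT_SYNAPOMORPHIC")
})

test_that("gap states can support a clade (indel synapomorphy, flagged)", {
  aln <- c(A = "-", B = "-", C = "G", D = "G")
  call <- classifySynapomorphy(aln, 1, c("A", "B"), balanced4)
  expect_equal(call$klass, "NHS")
  expect_true(call$isIndel)
})

test_that("paired-column calls classify CBC and hemi-CBC patterns as units", {
  # clade pair G:C -> A:U against an invariant outside: a CBC-type NHS
  aln <- c(A = "AxU", B = "AxU", C = "GxC", D = "GxC")
  aln <- gsub("x", "A", aln)
  call <- classifyPairedSynapomorphy(aln, c(1, 3), c("A", "B"), balanced4)
  expect_equal(call$klass, "NHS")
  expect_equal(call$pairedKlass, "CBC")
  expect_equal(call$derivedState, "A:U")

  # one side changes, complementarity conserved: hemi-CBC
  aln2 <- c(A = "CAG", B = "CAG", C = "UAG", D = "UAG")
  call2 <- classifyPairedSynapomorphy(aln2, c(1, 3), c("A", "B"), balanced4)
  expect_equal(call2$klass, "NHS")
  expect_equal(call2$pairedKlass, "HEMI_CBC")

  # clade pair equal to the outside pair: nothing to call
  aln3 <- c(A = "GAC", B = "GAC", C = "GAC", D = "GAC")
  expect_equal(classifyPairedSynapomorphy(aln3, c(1, 3), c("A", "B"),
                                          balanced4)$klass,
               "NOT_SYNAPOMORPHIC")
})

test_that("adjacent hemi-CBC couples reproduce the paired-NHS pattern", {
  # ten taxa; the derived clade changes U->C at one couple and C->U at the
  # next, each conserving complementarity with its own partner (U.G -> C.G
  # and C.G -> U.G): two hemi-CBC NHS calls
  tr <- ape::read.tree(text = "(((T1,T2),(T3,T4)),((T5,T6),((T7,T8),(T9,T10))));")
  outRow <- "UCAAAGG"   # cols: 1 pairs 7, 2 pairs 6
  inRow <- "CUAAAGG"
  aln <- stats::setNames(rep(outRow, 10), paste0("T", 1:10))
  aln[c("T1", "T2")] <- inRow
  c1 <- classifyPairedSynapomorphy(aln, c(1, 7), c("T1", "T2"), tr)
  c2 <- classifyPairedSynapomorphy(aln, c(2, 6), c("T1", "T2"), tr)
  expect_equal(c1$klass, "NHS"); expect_equal(c1$pairedKlass, "HEMI_CBC")
  expect_equal(c2$klass, "NHS"); expect_equal(c2$pairedKlass, "HEMI_CBC")
})

test_that("scanning recovers planted clade-diagnostic columns exactly", {
  tr <- ape::read.tree(text = "((A,B),((C,D),E));")
  gen <- makeCladeAlignment(tr, list(AB = 4L, CD = 2L),
                            list(AB = c("A", "B"), CD = c("C", "D")),
                            nNeutral = 40, seed = 17)
  calls <- scanSynapomorphies(gen$alignment, tr,
                              list(AB = c("A", "B"), CD = c("C", "D")))
  nhs <- calls[calls$klass == "NHS", ]
  expect_equal(sum(nhs$cladeName == "AB"), 4L)
  expect_equal(sum(nhs$cladeName == "CD"), 2L)
  planted <- gen$truth$planted
  expect_setequal(nhs$column[nhs$cladeName == "AB"],
                  planted$column[planted$clade == "AB"])
})

test_that("identical rows yield no calls; the full tip set has no outside", {
  aln <- c(A = "ACGU", B = "ACGU", C = "ACGU", D = "ACGU")
  expect_equal(nrow(scanSynapomorphies(aln, balanced4, list(AB = c("A", "B")))), 0L)
  aln2 <- c(A = "GCGU", B = "GCGU", C = "GCGU", D = "ACGU")
  all4 <- list(ALL = c("A", "B", "C", "D"))
  expect_equal(nrow(scanSynapomorphies(aln2, balanced4, all4)), 0L)
})

test_that("every NHS is a synapomorphy and calls survive tip reordering", {
  tr <- ape::read.tree(text = "((A,B),((C,D),E));")
  for (s in 1:8) {
    gen <- makeCladeAlignment(tr, list(AB = 3L), list(AB = c("A", "B")),
                              nNeutral = 25, seed = s)
    calls <- scanSynapomorphies(gen$alignment, tr, list(AB = c("A", "B")),
                                keepAll = TRUE)
    expect_true(all(calls$klass[calls$klass == "NHS"] %in%
                    c("NHS", "HOMOPLASIOUS_SYNAPOMORPHY")))
    perm <- scanSynapomorphies(gen$alignment[sample(names(gen$alignment))],
                               tr, list(AB = c("A", "B")))
    base <- scanSynapomorphies(gen$alignment, tr, list(AB = c("A", "B")))
    expect_equal(perm[order(perm$column), ], base[order(base$column), ])
  }
})
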