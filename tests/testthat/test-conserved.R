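# Homology matching, precursor excision and conserved miRNA calling.

test_that("mismatch counting: Hamming, offsets, overlap floor, symmetry", {
  # the two most similar published novel miRNAs differ at exactly 2 positions
  expect_equal(mismatchCount("UUCACUGCCACCAUCCGCCUGU",
                             "UUUACUGCCACCAUCCGCCUGC"), 2)
  expect_equal(mismatchCount("UGACAGAAGAGAGUGAGCAC",
                             "UGACAGAAGAGAGUGAGCAC"), 0)
  set.seed(51)
  a <- randRna(21)
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  for (i in c(3, 9, 17)) ch[i] <- setdiff(c("A","C","G","U"), ch[i])[1]
  expect_equal(mismatchCount(a, paste(ch, collapse = "")), 3)

  # unequal lengths: contained prefix costs only the length difference
  expect_equal(mismatchCount(a, substr(a, 1, 20)), 1)
  expect_equal(mismatchCount(substr(a, 2, 21), a), 1)
  # no qualifying overlap
  expect_equal(mismatchCount(substr(a, 1, 18), randRna(40)) >= 18, TRUE)
  expect_identical(mismatchCount("ACGUACGUACGUACGUA", a), Inf)  # 17 nt < floor

  # symmetry and T/U invariance
  b <- randRna(22)
  expect_equal(mismatchCount(a, b), mismatchCount(b, a))
  expect_equal(mismatchCount(chartr("U", "T", a), b), mismatchCount(a, b))
})

test_that("matchKnown reports budgeted hits with best-family tie-breaking", {
  set.seed(52)
  known <- knownMatureSet(
    c("osa-miR150a", "ath-miR200a", "zma-miR901a"),
    c("UGACAGAAGAGAGUGAGCACA", "UCGGACCAGGCUUCAUUCCCC",
      "UAGCCAAGGAUGACUUGCCUG"))
  hits <- matchKnown("UGACAGAAGAGAGUGAGCACA", known)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$family, "MIR150")

  # 3 mismatches from everything: silence
  expect_equal(nrow(matchKnown(.mutateAt("UGACAGAAGAGAGUGAGCACA", c(2, 8, 15)),
                               known)), 0L)
  # 2 mismatches: single hit at the threshold
  two <- .mutateAt("UAGCCAAGGAUGACUUGCCUG", c(4, 12))
  h2 <- matchKnown(two, known)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$mismatches, 2)

  # equidistant tag: best hit goes to the lower MIR number
  known2 <- knownMatureSet(c("osa-miR300a", "osa-miR250a"),
                           c("UGACAGAAGAGAGUGAGCACA",
                             "GGACAGAAGAGAGUGAGCACU"))
  tagEq <- "GGACAGAAGAGAGUGAGCACA"  # 1 mismatch from both
  he <- matchKnown(tagEq, known2)
  expect_equal(nrow(he), 2L)
  expect_equal(he$family[he$best], "MIR250")
})

test_that("excision emits the window schedule with correct mature anchoring", {
  set.seed(53)
  mature <- "UGACAGAAGAGAGUGAGCACA"
  pl <- plantHairpin(mature, leftFlank = 300, rightFlank = 300)
  tx <- c(T1 = pl$tx)
  cands <- locateAndExcise(mature, tx, flank = 250)
  expect_equal(length(cands), 3L)  # symmetric + two asymmetric windows
  for (cc in cands) {
    m <- matureInterval(cc)
    w <- cc@window
    expect_equal(substr(pl$tx, w[1] + m[1] - 1L, w[1] + m[2] - 1L), mature)
  }

  # a tag at the transcript end folds a clipped window
  edge <- c(T2 = paste0(randRna(40), mature))
  ce <- locateAndExcise(mature, edge, flank = 250)
  expect_gte(length(ce), 1L)
  expect_true(all(vapply(ce, function(cc) cc@window[2] <= 61L, logical(1))))

  # duplicated tag: two loci, two candidate sets
  dup <- c(T3 = paste0(randRna(80), mature, randRna(120), mature, randRna(80)))
  cd <- locateAndExcise(mature, dup, flank = 40)
  starts <- unique(vapply(cd, function(cc) cc@window[1] + cc@mature[1] - 1L,
                          integer(1)))
  expect_equal(length(starts), 2L)

  expect_equal(length(locateAndExcise(mature, c(T4 = randRna(200)))), 0L)
})

test_that("conserved calls carry the right family; hairpin-free homology is logged", {
  set.seed(54)
  mature <- paste0("U", randRna(20))
  pl <- plantHairpin(mature, leftFlank = 80, rightFlank = 80)
  known <- knownMatureSet("osa-miR171a", .mutateAt(mature, c(5, 13)))
  # a second tag matching the known set but planted without a hairpin
  freeTag <- .mutateAt(known$sequence, 2)
  tx <- c(HP = pl$tx,
          FLAT = paste0(strrep("AC", 40), freeTag, strrep("CA", 40)))
  lib <- collapseTags(c(rep(mature, 6), rep(freeTag, 4)), "flower")
  res <- callConserved(list(flower = lib), known, tx, flank = 100)
  seqs <- vapply(res$calls, matureSequence, character(1))
  expect_true(mature %in% seqs)
  expect_false(freeTag %in% seqs)
  cl <- res$calls[[match(mature, seqs)]]
  expect_equal(familyOf(cl), "MIR171")
  expect_equal(unname(callCounts(cl)["flower"]), 6)
  expect_true(freeTag %in% res$log$tag)
  expect_equal(res$log$reason[res$log$tag == freeTag][1],
               "no_validated_stemloop")
  # the retained precursor re-validates independently
  expect_true(validateStemloop(precursorOf(cl))$accept)
})

test_that("star support is detected from sequenced star tags", {
  set.seed(55)
  mature <- paste0("U", randRna(20))
  pl <- plantHairpin(mature, leftFlank = 80, rightFlank = 80)
  known <- knownMatureSet("osa-miR172a", mature)
  starSeq <- substr(pl$tx, pl$starTx[1], pl$starTx[2])
  tx <- c(HP = pl$tx)
  libNoStar <- collapseTags(rep(mature, 5), "x")
  libStar <- collapseTags(c(rep(mature, 5), rep(starSeq, 2)), "x")
  resNo <- callConserved(list(x = libNoStar), known, tx, flank = 100)
  resYes <- callConserved(list(x = libStar), known, tx, flank = 100)
  expect_false(starSupported(resNo$calls[[1]]))
  expect_true(starSupported(resYes$calls[[1]]))
})

test_that("family summaries count families and 5' U composition", {
  empty <- summarizeFamilies(list())
  expect_equal(nrow(empty$families), 0L)
  expect_true(is.nan(empty$fivePrimeUFraction))

  df <- data.frame(family = c("MIR1", "MIR1", "MIR2"),
                   sequence = c("UAAAAAAAAAAAAAAAAAAAA",
                                "UCCCCCCCCCCCCCCCCCCCC",
                                "GAAAAAAAAAAAAAAAAAAAA"))
  s <- summarizeFamilies(df)
  expect_equal(nrow(s$families), 2L)
  expect_equal(s$families$members[s$families$family == "MIR1"], 2L)
  expect_equal(s$fivePrimeUFraction, 2 / 3)
})
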