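# Locus finding and rule-based novel miRNA calling.

test_that("loci respect the count threshold and the 30-nt merge rule", {
  set.seed(61)
  mature <- paste0("U", randRna(20))
  other <- paste0("U", randRna(20))
  tx <- c(T1 = paste0(randRna(50), mature, randRna(19), other, randRna(50)))
  # starts 51 and 91: 40 nt apart -> two loci
  lib <- collapseTags(c(rep(mature, 10), rep(other, 4)), "x")
  loci <- candidateLoci(list(lib), tx, minCount = 3)
  expect_equal(length(loci), 2L)
  expect_equal(loci[[1]]$dominant, mature)
  expect_equal(loci[[1]]$total, 10)

  # below threshold: no locus
  lib2 <- collapseTags(rep(mature, 2), "x")
  expect_equal(length(candidateLoci(list(lib2), tx, minCount = 3)), 0L)

  # within 30 nt: merged into one locus
  tx2 <- c(T2 = paste0(randRna(50), mature, randRna(4), other, randRna(50)))
  loci2 <- candidateLoci(list(lib), tx2, minCount = 3)
  expect_equal(length(loci2), 1L)
  expect_equal(nrow(loci2[[1]]$members), 2L)
})

test_that("clean read stacks on hairpins are called; scattered stacks are not", {
  set.seed(62)
  mature <- paste0("U", randRna(20))
  pl <- plantHairpin(mature, leftFlank = 80, rightFlank = 80)
  starSeq <- substr(pl$tx, pl$starTx[1], pl$starTx[2])
  tx <- c(HP = pl$tx)
  lib <- collapseTags(c(rep(mature, 8), rep(starSeq, 2)), "flower")
  loci <- candidateLoci(list(lib), tx, minCount = 3)
  res <- callNovel(loci, tx, list(flower = lib))
  seqs <- vapply(res$calls, matureSequence, character(1))
  expect_true(mature %in% seqs)
  cl <- res$calls[[match(mature, seqs)]]
  expect_true(starSupported(cl))
  expect_equal(callKind(cl), "novel")
  expect_lt(mfe(precursorOf(cl)), 0)
  expect_false(is.na(mfei(precursorOf(cl))))

  # scatter: reads all over the merge window dilute consistency below 0.75
  scatter1 <- substr(pl$tx, pl$offset - 28L, pl$offset - 8L)
  scatter2 <- substr(pl$tx, pl$offset + 25L, pl$offset + 45L)
  libS <- collapseTags(c(rep(mature, 4), rep(scatter1, 3), rep(scatter2, 3)),
                       "flower")
  lociS <- candidateLoci(list(libS), tx, minCount = 3)
  resS <- callNovel(lociS, tx, list(flower = libS), readConsistency = 0.75)
  expect_false(mature %in% vapply(resS$calls, matureSequence, character(1)))
  expect_true("read_stack_inconsistent" %in% resS$log$reason)
})

test_that("identical matures at two loci collapse to one call with extra precursors", {
  set.seed(63)
  mature <- paste0("U", randRna(20))
  pl1 <- plantHairpin(mature, leftFlank = 70, rightFlank = 70)
  pl2 <- plantHairpin(mature, leftFlank = 90, rightFlank = 50)
  tx <- c(A = pl1$tx, B = pl2$tx)
  lib <- collapseTags(rep(mature, 6), "x")
  loci <- candidateLoci(list(lib), tx, minCount = 3)
  expect_equal(length(loci), 2L)
  res <- callNovel(loci, tx, list(x = lib))
  expect_equal(length(res$calls), 1L)
  expect_equal(length(res$calls[[1]]@extraPrecursors), 1L)
  resDup <- callNovel(loci, tx, list(x = lib), keepDuplicates = TRUE)
  expect_equal(length(resDup$calls), 2L)
})

test_that("matures within the homology budget of the known set are excluded", {
  set.seed(64)
  mature <- paste0("U", randRna(20))
  pl <- plantHairpin(mature, leftFlank = 80, rightFlank = 80)
  tx <- c(HP = pl$tx)
  lib <- collapseTags(rep(mature, 6), "x")
  loci <- candidateLoci(list(lib), tx, minCount = 3)
  known <- knownMatureSet("osa-miR399a", .mutateAt(mature, c(3, 11)))
  res <- callNovel(loci, tx, list(x = lib), known = known)
  expect_equal(length(res$calls), 0L)
  expect_true("matches_known_set" %in% res$log$reason)
})

test_that("composition statistics summarise matures", {
  cs <- compositionStats(c("UAGUAAGUUUGCAGAGCAGAG", "AAGGUAUAGAGUCAGACACU"))
  expect_equal(cs$fivePrimeUFraction, 0.5)
  expect_equal(cs$lengthMin, 20L)
  expect_equal(cs$lengthMax, 21L)
  cs0 <- compositionStats(character(0))
  expect_true(is.nan(cs0$fivePrimeUFraction))
  expect_true(is.na(cs0$lengthMin))
})
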