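# The dynamic-programming folder against hand-worked cases, the independent
# energy evaluator, and the exhaustive enumeration oracle.

test_that("hand-worked folds are reproduced exactly", {
  f <- foldMfe("GGGGAAAACCCC")
  expect_equal(dotBracket(f), "((((....))))")
  # three GC stacks (-9.0) + hairpin loop of 4 (+4.5)
  expect_equal(mfe(f), -4.5)

  # no legal pairs at all
  f2 <- foldMfe("AAAAAAAAAA")
  expect_equal(dotBracket(f2), "..........")
  expect_equal(mfe(f2), 0)

  # G/C present but every pairing would close a hairpin loop < 3
  f3 <- foldMfe("GGCCAAAAAA")
  expect_equal(mfe(f3), 0)
  expect_equal(dotBracket(f3), "..........")

  expect_error(foldMfe("ACGUACGU"), "too short")
  expect_error(foldMfe("ACGUXACGUA"), "invalid residue")
})

test_that("structureEnergy evaluates the declared model terms", {
  # open chain
  expect_equal(structureEnergy("ACGUACGUAC", ".........."), 0)
  # isolated GC pair closing a 4-nt hairpin: +4.5 loop - 1.5 half-pair
  expect_equal(structureEnergy("GAAAAC", "(....)"), 3.0)
  # the hand-worked stack case
  expect_equal(structureEnergy("GGGGAAAACCCC", "((((....))))"), -4.5)
  # errors: unbalanced, illegal pair, undersized hairpin loop
  expect_error(structureEnergy("ACGUACGUAC", "(........."), "unbalanced")
  expect_error(structureEnergy("AAGAAAAAAG", "(........)"), "not Watson-Crick")
  expect_error(structureEnergy("GGCC", "(())"), "fewer than 3")
})

test_that("every fold's mfe equals its structure energy (consistency oracle)", {
  set.seed(21)
  for (n in c(12, 30, 60, 120, 250)) {
    s <- randRna(n)
    f <- foldMfe(s)
    expect_equal(structureEnergy(s, dotBracket(f)), mfe(f))
  }
})

test_that("fold minimum matches exhaustive enumeration on short sequences", {
  # spot check; the full 200-sequence comparison runs in the acceptance suite
  set.seed(33)
  for (r in 1:25) {
    s <- randRna(sample(10:24, 1))
    expect_equal(mfe(foldMfe(s)), oracleMinEnergy(s), info = s)
  }
})

test_that("every enumerated structure of a 20-mer scores at or above the fold minimum", {
  set.seed(8)
  s <- randRna(20)
  structs <- enumAllStructures(s)
  energies <- vapply(structs, function(db) structureEnergy(s, db), numeric(1))
  f <- mfe(foldMfe(s))
  expect_true(all(energies >= f - 1e-9))
  expect_equal(min(c(0, energies)), f)
})

test_that("appending unpairable tails never raises the minimum energy", {
  set.seed(13)
  for (r in 1:10) {
    s <- randRna(sample(15:40, 1))
    e0 <- mfe(foldMfe(s))
    e1 <- mfe(foldMfe(paste0(s, strrep("A", 12))))
    expect_lte(e1, e0 + 1e-9)
  }
})

test_that("amfe is invariant under tandem duplication of an independent hairpin", {
  u <- "GGGGAAAACCCCAAAAA"          # one hairpin + unpairable spacer
  f1 <- foldMfe(u)
  f2 <- foldMfe(paste0(u, u))
  expect_equal(mfe(f2), 2 * mfe(f1))
  expect_equal(amfeMfei(f2)$amfe, amfeMfei(f1)$amfe)
})

test_that("folding is deterministic", {
  set.seed(77)
  s <- randRna(80)
  f1 <- foldMfe(s); f2 <- foldMfe(s)
  expect_identical(dotBracket(f1), dotBracket(f2))
  expect_identical(mfe(f1), mfe(f2))
})

test_that("AMFE/MFEI follow their defining arithmetic", {
  set.seed(4)
  s <- randRna(100)
  f <- foldMfe(s)
  st <- amfeMfei(f)
  expect_equal(st$amfe, mfe(f) / 100 * 100)
  expect_equal(st$mfei, st$amfe / st$gcPercent)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_equal(st$gcPercent, gc)  # n = 100, so GC% equals the GC count

  # unfoldable but GC-containing: amfe 0, mfei 0
  f0 <- foldMfe("GCAAAAAAAAAA")
  st0 <- amfeMfei(f0)
  expect_equal(st0$amfe, 0)
  expect_equal(st0$mfei, 0)

  # GC = 0: mfei undefined, not an error
  stA <- amfeMfei(foldMfe("AUAUAUAUAUAUAU"))
  expect_true(is.na(stA$mfei) || is.finite(stA$mfei))
  stAA <- amfeMfei(foldMfe("AAAAAAAAAAAA"))
  expect_true(is.na(stAA$mfei))
})
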