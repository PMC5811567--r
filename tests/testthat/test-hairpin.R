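# Star derivation and stem-loop acceptance on constructed hairpins.

test_that("star interval of a clean duplex carries the 2-nt 3' overhang", {
  set.seed(101)
  hp <- makeHairpin("UGACAGAAGAGAGUGAGCACA", loopLen = 8, starMismatches = 0)
  f <- foldMfe(hp$sequence)
  expect_equal(starOf(f, hp$mature), hp$star)
  # star has the mature's length and sits 2 nt past the partner block
  expect_equal(diff(hp$star), diff(hp$mature))
})

test_that("star is absent for loop-straddling or unpaired matures", {
  set.seed(102)
  hp <- makeHairpin("UGACAGAAGAGAGUGAGCACA", loopLen = 8)
  f <- foldMfe(hp$sequence)
  m <- nchar("UGACAGAAGAGAGUGAGCACA")
  # interval centred on the terminal loop pairs back into itself
  loopCentred <- c(m - 6L, m + 14L)
  expect_length(starOf(f, loopCentred), 0)
  # an all-dot stretch: fold a sequence with an unpaired 3' tail
  s <- paste0(hp$sequence, strrep("A", 24))
  f2 <- foldMfe(s)
  tail <- c(nchar(s) - 20L, nchar(s))
  expect_length(starOf(f2, tail), 0)
})

test_that("validateStemloop accepts canonical hairpins and reports failing clauses", {
  set.seed(103)
  mature <- "UGACAGAAGAGAGUGAGCACA"
  hp <- makeHairpin(mature, loopLen = 8, starMismatches = 0)
  f <- foldMfe(hp$sequence)
  st <- amfeMfei(f)
  cand <- new("PrecursorCandidate", sourceId = "t",
              window = c(1L, nchar(hp$sequence)), fold = f,
              mature = as.integer(hp$mature), star = starOf(f, hp$mature),
              amfe = st$amfe, mfei = st$mfei, gcPercent = st$gcPercent)
  v <- validateStemloop(cand)
  expect_true(v$accept)
  expect_length(v$reasons, 0)

  # mature centred on the loop: straddle clause fires
  m <- nchar(mature)
  loopCand <- new("PrecursorCandidate", sourceId = "t",
                  window = c(1L, nchar(hp$sequence)), fold = f,
                  mature = c(m - 6L, m + 14L), star = integer(0),
                  amfe = st$amfe, mfei = st$mfei, gcPercent = st$gcPercent)
  vl <- validateStemloop(loopCand)
  expect_false(vl$accept)
  expect_true("mature_straddles_loop" %in% vl$reasons)

  # unpaired budget boundary: mismatched star positions unpair the mature
  set.seed(104)
  hp3 <- makeHairpin(mature, loopLen = 8, starMismatches = 3)
  f3 <- foldMfe(hp3$sequence)
  st3 <- amfeMfei(f3)
  cand3 <- new("PrecursorCandidate", sourceId = "t",
               window = c(1L, nchar(hp3$sequence)), fold = f3,
               mature = as.integer(hp3$mature), star = integer(0),
               amfe = st3$amfe, mfei = st3$mfei, gcPercent = st3$gcPercent)
  unpaired <- sum(pairTable(dotBracket(f3))[hp3$mature[1]:hp3$mature[2]] == 0)
  vTight <- validateStemloop(cand3, maxMatureUnpaired = unpaired - 1L)
  expect_false(vTight$accept)
  expect_true("mature_unpaired_exceeds_threshold" %in% vTight$reasons)
  vLoose <- validateStemloop(cand3, maxMatureUnpaired = unpaired)
  expect_false("mature_unpaired_exceeds_threshold" %in% vLoose$reasons)
})

test_that("makeHairpin enforces its preconditions and flags weak constructs", {
  expect_error(makeHairpin("UGACAGAAGAGAGUGAGCACA", loopLen = 3),
               "loop length")
  expect_error(makeHairpin("ACGU"), "20-24")
  set.seed(105)
  weak <- makeHairpin("UGACAGAAGAGAGUGAGCACA", starMismatches = 8)
  expect_true(weak$mayNotValidate)
})

test_that("planted hairpins validate for any star mismatch count up to 3", {
  set.seed(106)
  for (sm in 0:3) {
    mature <- paste0("U", randRna(20))
    hp <- makeHairpin(mature, loopLen = 8, starMismatches = sm)
    f <- foldMfe(hp$sequence)
    st <- amfeMfei(f)
    cand <- new("PrecursorCandidate", sourceId = "t",
                window = c(1L, nchar(hp$sequence)), fold = f,
                mature = as.integer(hp$mature), star = starOf(f, hp$mature),
                amfe = st$amfe, mfei = st$mfei, gcPercent = st$gcPercent)
    expect_true(validateStemloop(cand)$accept, info = paste("mismatches", sm))
  }
})
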