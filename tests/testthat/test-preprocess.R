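# Adapter trimming, length filtering, tag collapsing, ncRNA removal,
# length distributions.

ADAPTER <- "UGGAAUUCUCGGGUGCCAAGG"

test_that("trimming inverts read construction and applies length bounds", {
  insert <- "UGACAGAAGAGAGUGAGCAC"  # 20 nt
  res <- trimAndFilter(paste0(insert, ADAPTER), ADAPTER)
  expect_equal(unname(res$reads), insert)
  expect_equal(unname(res$tallies["kept"]), 1L)

  # partial adapter at the read end: >= 8 nt prefix accepted, 7 nt is not
  res8 <- trimAndFilter(paste0(insert, substr(ADAPTER, 1, 8)), ADAPTER)
  expect_equal(unname(res8$reads), insert)
  res7 <- trimAndFilter(paste0(insert, substr(ADAPTER, 1, 7)), ADAPTER)
  expect_equal(length(res7$reads), 0L)
  expect_equal(unname(res7$tallies["no_adapter"]), 1L)

  # boundary insert lengths: 17 out, 18/30 in, 31 out
  set.seed(42)
  mk <- function(n) paste0(randRna(n), ADAPTER)
  res <- trimAndFilter(c(mk(17), mk(18), mk(30), mk(31)), ADAPTER)
  expect_equal(sort(nchar(res$reads)), c(18L, 30L))
  expect_equal(unname(res$tallies["too_short"]), 1L)
  expect_equal(unname(res$tallies["too_long"]), 1L)

  # T input is normalised to U before trimming
  resT <- trimAndFilter(chartr("U", "T", paste0(insert, ADAPTER)), ADAPTER)
  expect_equal(unname(resT$reads), insert)
})

test_that("ambiguous residues are rejected and tallied; empty input is legal", {
  res <- trimAndFilter(paste0("UGACNGAAGAGAGUGAGCAC", ADAPTER), ADAPTER)
  expect_equal(length(res$reads), 0L)
  expect_equal(unname(res$tallies["invalid_residue"]), 1L)

  res0 <- trimAndFilter(character(0), ADAPTER)
  expect_equal(length(res0$reads), 0L)
  expect_true(all(res0$tallies == 0L))
})

test_that("read conservation holds across random inputs", {
  set.seed(11)
  for (rep in 1:5) {
    reads <- vapply(1:40, function(i) {
      body <- randRna(sample(10:35, 1))
      paste0(body, if (runif(1) < 0.8) ADAPTER else "")
    }, character(1))
    res <- trimAndFilter(reads, ADAPTER)
    expect_equal(sum(res$tallies), length(reads))
    expect_equal(unname(res$tallies["kept"]), length(res$reads))
  }
})

test_that("collapsing is the inverse of expansion on multisets", {
  lib <- collapseTags(c(rep("ACGUACGUACGUACGUAC", 3),
                        rep("UGACAGAAGAGAGUGAGCAC", 2)), "flower")
  expect_s4_class(lib, "TagLibrary")
  expect_equal(length(lib), 2L)
  expect_equal(sort(unname(tagCounts(lib))), c(2L, 3L))
  expect_equal(totalReads(lib), 5L)

  # round trip: expanding tags by their counts recovers the read multiset
  set.seed(3)
  reads <- sample(vapply(1:6, function(i) randRna(21), character(1)),
                  50, replace = TRUE)
  lib2 <- collapseTags(reads, "x")
  expanded <- rep(tagSequences(lib2), tagCounts(lib2))
  expect_equal(sort(expanded), sort(reads))

  lib0 <- collapseTags(character(0), "empty")
  expect_equal(length(lib0), 0L)
  expect_equal(totalReads(lib0), 0L)
})

test_that("annotated ncRNA removal is exact and class-tallied", {
  set.seed(5)
  rrna <- randRna(120)
  trna <- randRna(90)
  ann <- annotationSet(c("r1", "t1"), c("rRNA", "tRNA"), c(rrna, trna))
  inR <- substr(rrna, 11, 31)       # exact 21-nt substring of the rRNA
  inT <- substr(trna, 40, 60)
  ch <- strsplit(inT, "", fixed = TRUE)[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "U"), ch[10])[1]
  nearT <- paste(ch, collapse = "") # 1 mismatch from the tRNA
  free <- randRna(21)

  lib <- collapseTags(c(inR, inT, nearT, free), "x")
  res0 <- filterAnnotated(lib, ann, maxMismatch = 0L)
  expect_setequal(tagSequences(res0$tags), c(nearT, free))
  expect_equal(res0$tally$reads_removed[res0$tally$class == "rRNA"], 1L)
  expect_equal(res0$tally$reads_removed[res0$tally$class == "tRNA"], 1L)

  res1 <- filterAnnotated(lib, ann, maxMismatch = 1L)
  expect_setequal(tagSequences(res1$tags), free)
})

test_that("the simulator's planted contaminants are removed completely and exclusively", {
  sim <- simulateStudy(seed = 31, nConserved = 4L, nNovel = 3L, nDecoys = 2L,
                       jitterRate = 0, noiseReads = 5L)
  ts <- sim$tissues[1]
  tf <- trimAndFilter(sim$libraries[[ts]], sim$adapter)
  lib <- collapseTags(tf$reads, ts)
  res <- filterAnnotated(lib, sim$annotation, maxMismatch = 0L)
  contam <- unique(sim$manifest@contaminants$sequence[
    sim$manifest@contaminants$tissue == ts])
  contam <- contam[nchar(contam) >= 18 & nchar(contam) <= 30]
  expect_true(all(!contam %in% tagSequences(res$tags)))
  expect_true(all(contam %in% tagSequences(lib)))
  # nothing else was removed
  expect_setequal(setdiff(tagSequences(lib), tagSequences(res$tags)), contam)
})

test_that("length distribution sums to the library totals", {
  set.seed(9)
  reads <- c(rep(randRna(21), 10), rep(randRna(21), 5), randRna(24))
  lib <- collapseTags(reads, "x")
  ld <- lengthDistribution(lib)
  expect_equal(ld$clean_reads[ld$length == 21], 15)
  expect_equal(ld$unique_reads[ld$length == 21], 2L)
  expect_equal(ld$clean_reads[ld$length == 24], 1)
  expect_equal(sum(ld$clean_reads), totalReads(lib))
  expect_equal(sum(ld$unique_reads), length(lib))

  ld0 <- lengthDistribution(collapseTags(character(0), "e"))
  expect_true(all(ld0$clean_reads == 0))
  expect_true(all(ld0$unique_reads == 0))
})
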