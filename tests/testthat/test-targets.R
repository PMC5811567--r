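# Position-weighted duplex scoring and the seeded target scanner.

test_that("duplex penalties follow the declared weights", {
  set.seed(71)
  m <- paste0("G", randRna(20))        # G at position 1 for the wobble case
  site <- rnaRevComp(m)                # perfect complement
  expect_equal(scoreDuplex(m, site)$penalty, 0)
  expect_equal(scoreDuplex(m, site)$pairing, strrep("|", 21))

  # G:U at miRNA position 1 (weight 1): complement C -> U
  L <- nchar(m)
  s1 <- .setAt(site, L, "U")           # site position facing miRNA pos 1
  expect_equal(scoreDuplex(m, s1)$penalty, 0.5)

  # the same wobble inside the doubled 2-13 core costs 1.0
  m5 <- .setAt(m, 5, "G")
  site5 <- rnaRevComp(m5)
  w5 <- .setAt(site5, L - 4L, "U")
  expect_equal(scoreDuplex(m5, w5)$penalty, 1.0)

  # additivity: mismatch at 15 (1.0) + wobble at 3 (1.0)
  m3 <- .setAt(m, 3, "G")
  siteA <- rnaRevComp(m3)
  siteA <- .setAt(siteA, L - 2L, "U")           # wobble at position 3
  mm15 <- chartr("ACGU", "CAUG", substr(m3, 15, 15))  # same base as target
  siteA <- .setAt(siteA, L - 14L, chartr("ACGU", "UGCA", mm15))
  expect_equal(scoreDuplex(m3, siteA)$penalty, 2.0)

  expect_error(scoreDuplex("UGA-CAGAA", "UUCUG-UCA"), "gap in both strands")
})

test_that("gap columns carry the position weight of the next miRNA base", {
  set.seed(72)
  m <- randRna(21)
  # miRNA gap between positions 14 and 15 (outside the doubled core):
  # the extra target base faces the gap, penalty 2.0 at weight 1
  mGap <- paste0(substr(m, 1, 14), "-", substr(m, 15, 21))
  site <- paste0(rnaRevComp(substr(m, 15, 21)), "A",
                 rnaRevComp(substr(m, 1, 14)))
  expect_equal(scoreDuplex(mGap, site)$penalty, 2.0)
  # the same gap between positions 9 and 10 falls in the core: 4.0
  mGap9 <- paste0(substr(m, 1, 9), "-", substr(m, 10, 21))
  site9 <- paste0(rnaRevComp(substr(m, 10, 21)), "A",
                  rnaRevComp(substr(m, 1, 9)))
  expect_equal(scoreDuplex(mGap9, site9)$penalty, 4.0)
})

test_that("the scanner finds planted sites and honours the cutoff", {
  set.seed(73)
  m <- paste0("U", randRna(20))
  L <- nchar(m)
  perfect <- rnaRevComp(m)
  tx <- c(T1 = paste0(randRna(60), perfect, randRna(60)))
  hits <- scanTargets(c(mir = m), tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$penalty, 0)
  expect_equal(hits$start, 61L)
  expect_equal(hits$end, 60L + L)
  expect_equal(hits$cut, 60L + L - 9L)  # paired to miRNA position 10

  # two core-region mismatches outside the seed: penalty 4.0, still reported
  site2 <- .setAt(perfect, L - 9L, .nextBase(substr(perfect, L - 9L, L - 9L)))
  site2 <- .setAt(site2, L - 11L, .nextBase(substr(site2, L - 11L, L - 11L)))
  tx2 <- c(T2 = paste0(randRna(40), site2, randRna(40)))
  h2 <- scanTargets(c(mir = m), tx2, maxPenalty = 4.0)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$penalty, 4.0)

  # three such mismatches (6.0): absent at the 4.0 cutoff
  site3 <- .setAt(site2, L - 13L, .nextBase(substr(site2, L - 13L, L - 13L)))
  tx3 <- c(T3 = paste0(randRna(40), site3, randRna(40)))
  expect_equal(nrow(scanTargets(c(mir = m), tx3, maxPenalty = 4.0)), 0L)

  # no complementarity anywhere
  expect_equal(nrow(scanTargets(c(mir = m),
                                c(T4 = strrep("A", 300)))), 0L)
})

test_that("the seeded scanner equals exhaustive all-offsets scoring", {
  set.seed(74)
  for (r in 1:6) {
    m <- paste0("U", randRna(20))
    tx <- randRna(300)
    # plant one perturbed site so non-trivial hits exist in most repeats
    site <- .mutateAt(rnaRevComp(m), sample(9:12, 1))
    pos <- sample(50:250, 1)
    tx <- paste0(substr(tx, 1, pos - 1), site,
                 substr(tx, pos + nchar(site), 300))
    got <- scanTargets(c(mir = m), c(T = tx), maxPenalty = 4.0)
    want <- oracleTargetSites(m, tx, maxPenalty = 4.0)
    if (nrow(want) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      # the scanner merges overlapping frames to the best one; every
      # reported site must be optimal among oracle frames it overlaps,
      # and the oracle's global best must be reported
      expect_true(all(got$penalty <= 4.0))
      expect_equal(min(got$penalty), min(want$penalty))
      for (i in seq_len(nrow(got))) {
        ov <- want[want$start <= got$end[i] & want$end >= got$start[i], ]
        expect_equal(got$penalty[i], min(ov$penalty))
      }
    }
  }
})

test_that("penalty is invariant under joint reverse-complementation (GU-free duplexes)", {
  set.seed(75)
  for (r in 1:10) {
    m <- randRna(21)
    site <- rnaRevComp(m)
    k <- sample(1:21, sample(0:2, 1))
    for (i in k) site <- .setAt(site, i, .nextBase(substr(site, i, i)))
    a <- scoreDuplex(m, site)
    b <- scoreDuplex(rnaRevComp(site), rnaRevComp(m))
    if (!grepl("o", a$pairing) && !grepl("o", b$pairing))
      expect_equal(a$penalty, b$penalty)
  }
})

test_that("adding a mismatch never lowers a site's penalty", {
  set.seed(76)
  m <- paste0("U", randRna(20))
  L <- nchar(m)
  site <- rnaRevComp(m)
  base <- scoreDuplex(m, site)$penalty
  for (i in c(1, 5, 10, 15, 21)) {
    worse <- .setAt(site, L - i + 1L, .nextBase(substr(site, L - i + 1L,
                                                       L - i + 1L)))
    expect_gte(scoreDuplex(m, worse)$penalty, base)
  }
})
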