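# Independent brute-force oracles used across the suite.

randRna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                             collapse = "")

# --- folding oracle --------------------------------------------------------
# Exhaustive depth-first enumeration of every non-crossing structure (legal
# Watson-Crick/G:U pairs, hairpin loops >= 3), with each closing pair's
# energy term computed from the declared model the moment its interior is
# complete, and a safe admissible bound (-1.5 per still-unassigned
# nucleotide, -3.0 per still-open pair) used only to skip subtrees that
# cannot beat the incumbent minimum. Entirely separate from the package's
# dynamic-programming folder.
oracleMinEnergy <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ci <- match(ch, c("A", "C", "G", "U"))
  PBi <- matrix(0L, 4, 4)
  PBi[1, 4] <- 2L; PBi[4, 1] <- 2L  # AU
  PBi[2, 3] <- 1L; PBi[3, 2] <- 1L  # CG
  PBi[3, 4] <- 3L; PBi[4, 3] <- 3L  # GU
  STK <- c(-3.0, -2.0, -1.0)
  pt <- integer(n)
  best <- 0; acc <- 0; rem <- n; nOpen <- 0L
  pairTerm <- function(i, k) {
    cls <- PBi[ci[i], ci[k]]
    u <- 0L; nchild <- 0L
    x <- i + 1L
    while (x < k) {
      if (pt[x] > x) { nchild <- nchild + 1L; x <- pt[x] + 1L }
      else { u <- u + 1L; x <- x + 1L }
    }
    e <- if (nchild == 0L) 4.0 + 0.5 * max(0L, u - 3L)
    else if (nchild == 1L && u == 0L) STK[cls]
    else 2.0 + 0.3 * u
    if (!(pt[i + 1L] == k - 1L) &&
        !((i > 1L) && (k < n) && (pt[i - 1L] == k + 1L)))
      e <- e + STK[cls] / 2
    e
  }
  rec <- function(i, j, cont) {
    if (acc - 1.5 * rem - 3 * nOpen >= best) return(invisible())
    if (i > j) { cont(); return(invisible()) }
    if (i + 4L <= j) for (k in j:(i + 4L)) {
      if (PBi[ci[i], ci[k]] == 0L) next
      pt[i] <<- k; pt[k] <<- i
      rem <<- rem - 2L; nOpen <<- nOpen + 1L
      rec(i + 1L, k - 1L, function() {
        term <- pairTerm(i, k)
        acc <<- acc + term
        nOpen <<- nOpen - 1L
        rec(k + 1L, j, cont)
        nOpen <<- nOpen + 1L
        acc <<- acc - term
      })
      rem <<- rem + 2L; nOpen <<- nOpen - 1L
      pt[i] <<- 0L; pt[k] <<- 0L
    }
    rem <<- rem - 1L
    rec(i + 1L, j, cont)
    rem <<- rem + 1L
    invisible()
  }
  rec(1L, n, function() { if (acc < best) best <<- acc })
  best
}

# All dot-bracket structures of a short sequence (no pruning), for
# "every enumerated structure scores >= the fold minimum" checks.
enumAllStructures <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairable <- function(a, b)
    paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  db <- rep(".", n)
  out <- character(0)
  rec <- function(i, j, cont) {
    if (i > j) { cont(); return(invisible()) }
    rec(i + 1L, j, cont)
    if (i + 4L <= j) for (k in (i + 4L):j) {
      if (!pairable(ch[i], ch[k])) next
      db[i] <<- "("; db[k] <<- ")"
      rec(i + 1L, k - 1L, function() rec(k + 1L, j, cont))
      db[i] <<- "."; db[k] <<- "."
    }
  }
  rec(1L, n, function() out[[length(out) + 1L]] <<- paste(db, collapse = ""))
  out
}

# --- target-scan oracle ----------------------------------------------------
# Exhaustive all-offsets scoring: every alignment frame of the miRNA against
# the transcript, ungapped and with every single-gap placement outside the
# seed, keeping frames whose positions 2-8 are exact Watson-Crick complements
# and whose penalty is within the cutoff. Independent of the package's
# seeded scanner.
oracleTargetSites <- function(mirna, tx, maxPenalty = 4.0) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  L <- length(m)
  txc <- strsplit(tx, "", fixed = TRUE)[[1]]
  n <- length(txc)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rows <- list()
  # a frame is the target coordinate paired to miRNA position 8 (seed 3' end)
  for (s in seq_len(n)) {
    seedPos <- s + 8L - (8:2)  # = s..s+6, facing miRNA positions 8..2
    if (max(seedPos) > n) next
    if (!all(txc[seedPos] == comp[m[8:2]])) next
    variants <- list(list(type = "none", g = NA))
    for (g in unique(c(1L, if (L >= 9L) 9:L)))
      variants[[length(variants) + 1L]] <- list(type = "tgap", g = g)
    for (g in unique(c(1L, if (L >= 9L) 8:(L - 1L))))
      variants[[length(variants) + 1L]] <- list(type = "mgap", g = g)
    for (v in variants) {
      if (v$type == "none") {
        mC <- m; tpos <- s + 8L - seq_len(L)
      } else if (v$type == "tgap") {
        mC <- m
        ks <- seq_len(L)
        tpos <- ifelse(ks < v$g, s + 8L - ks, s + 9L - ks)
        tpos[v$g] <- NA_integer_
        if (v$g == 1L) tpos[-1L] <- s + 8L - ks[-1L]
      } else {
        mC <- append(m, "-", after = v$g)
        T0 <- if (v$g == 1L) s + 8L else s + 7L
        tpos <- T0 - seq_len(L + 1L) + 1L
      }
      if (min(tpos, na.rm = TRUE) < 1L || max(tpos, na.rm = TRUE) > n) next
      rt <- ifelse(is.na(tpos), "-", txc[ifelse(is.na(tpos), 1L, tpos)])
      # independent penalty computation
      pen <- 0
      pos <- 0L
      for (cix in seq_along(mC)) {
        if (mC[cix] != "-") pos <- pos + 1L
        p <- if (mC[cix] == "-") pos + 1L else pos
        w <- if (p >= 2L && p <= 13L) 2 else 1
        if (mC[cix] == "-" || rt[cix] == "-") pen <- pen + w * 2.0
        else if (rt[cix] == comp[mC[cix]]) pen <- pen
        else if (paste0(mC[cix], rt[cix]) %in% c("GU", "UG")) pen <- pen + w * 0.5
        else pen <- pen + w * 1.0
      }
      if (pen <= maxPenalty)
        rows[[length(rows) + 1L]] <- data.frame(
          start = min(tpos, na.rm = TRUE), end = max(tpos, na.rm = TRUE),
          penalty = pen)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       penalty = numeric(0)))
  unique(do.call(rbind, rows))
}

# --- shared tiny fixtures --------------------------------------------------
# a transcript with one planted hairpin, returned with its geometry
plantHairpin <- function(mature, leftFlank = 60L, rightFlank = 60L,
                         loopLen = 8L, starMismatches = 0L) {
  hp <- makeHairpin(mature, loopLen = loopLen,
                    starMismatches = starMismatches)
  tx <- paste0(randRna(leftFlank), hp$sequence, randRna(rightFlank))
  list(tx = tx, hp = hp, offset = leftFlank + 1L,
       matureTx = c(leftFlank + 1L, leftFlank + nchar(mature)),
       starTx = hp$star + leftFlank)
}

# deterministic substitutions at given positions (A->C->G->U->A)
.mutateAt <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  nxt <- c(A = "C", C = "G", G = "U", U = "A")
  ch[pos] <- nxt[ch[pos]]
  paste(ch, collapse = "")
}

# replace one position of a sequence string
.setAt <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# deterministic different base (A->C->G->U->A)
.nextBase <- function(b) c(A = "C", C = "G", G = "U", U = "A")[[b]]
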