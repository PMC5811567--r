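# Plant miRNA target scoring: position-weighted penalty scheme (Allen-style)
# with an exact-complement seed requirement over miRNA positions 2-8, then
# banded extension allowing at most one gap.

.PEN_GU <- 0.5
.PEN_MISMATCH <- 1.0
.PEN_GAP <- 2.0
.CORE_FROM <- 2L  # positions whose penalty is doubled
.CORE_TO <- 13L

# column-wise scorer: m and rt are parallel character vectors, rt being the
# target site reversed so column i faces miRNA position i; both may hold "-"
.scoreColumns <- function(m, rt) {
  stopifnot(length(m) == length(rt))
  pen <- 0
  pairing <- character(length(m))
  pos <- 0L
  for (i in seq_along(m)) {
    if (m[i] != "-") pos <- pos + 1L
    # a gap column sits at the position of the next miRNA base
    p <- if (m[i] == "-") pos + 1L else pos
    w <- if (p >= .CORE_FROM && p <= .CORE_TO) 2 else 1
    if (m[i] == "-" && rt[i] == "-")
      stop("gap in both strands at the same column")
    if (m[i] == "-" || rt[i] == "-") {
      pen <- pen + w * .PEN_GAP
      pairing[i] <- "-"
    } else {
      cls <- pairClass1(m[i], rt[i])
      if (cls == 0L) { pen <- pen + w * .PEN_MISMATCH; pairing[i] <- "x" }
      else if (cls == 3L) { pen <- pen + w * .PEN_GU; pairing[i] <- "o" }
      else pairing[i] <- "|"
    }
  }
  list(penalty = pen, pairing = paste(pairing, collapse = ""))
}

#' Score a miRNA/target-site duplex
#'
#' Position-weighted penalties counted from the miRNA 5' end: match 0,
#' G:U wobble 0.5, mismatch 1.0, gap 2.0, with positions 2-13 doubled.
#' `targetSite` is given 5'-3' on the transcript and is reversed internally so
#' the duplex is read antiparallel; both strings may carry `-` gaps and must
#' have equal length after gap placement.
#'
#' @param mirna miRNA sequence 5'-3', optionally gapped.
#' @param targetSite target site sequence 5'-3', optionally gapped.
#' @return list with `penalty` and `pairing` (one symbol per column, miRNA
#'   5'-3': `|` match, `o` G:U, `x` mismatch, `-` gap).
#' @export
#' @examples
#' scoreDuplex("UGACAGAAGAGAGUGAGCAC", rnaRevComp("UGACAGAAGAGAGUGAGCAC"))
scoreDuplex <- function(mirna, targetSite) {
  m <- strsplit(normalizeRna(mirna), "", fixed = TRUE)[[1]]
  t5 <- strsplit(normalizeRna(targetSite), "", fixed = TRUE)[[1]]
  assertThat(length(m) == length(t5),
             "aligned strings must have equal length after gap placement")
  .scoreColumns(m, rev(t5))
}

# enumerate candidate alignments for one seed hit; returns rows of the site
# table or NULL. s = 1-based start of the revcomp(seed) occurrence.
.alignmentsAtSeed <- function(m, tx, txName, s, maxPenalty) {
  L <- length(m)
  n <- nchar(tx)
  txc <- strsplit(tx, "", fixed = TRUE)[[1]]
  out <- list()
  emit <- function(mCols, tpos) {
    # tpos: target coordinate per column (NA = target gap)
    if (min(tpos, na.rm = TRUE) < 1L || max(tpos, na.rm = TRUE) > n) return()
    rt <- ifelse(is.na(tpos), "-", txc[ifelse(is.na(tpos), 1L, tpos)])
    sc <- .scoreColumns(mCols, rt)
    if (sc$penalty > maxPenalty) return()
    p10 <- which(cumsum(mCols != "-") == 10L & mCols != "-")[1]
    out[[length(out) + 1L]] <<- data.frame(
      mirna = NA_character_, transcript = txName,
      start = min(tpos, na.rm = TRUE), end = max(tpos, na.rm = TRUE),
      cut = if (!is.na(p10)) tpos[p10] else NA_integer_,
      penalty = sc$penalty, pairing = sc$pairing,
      stringsAsFactors = FALSE)
  }
  # ungapped: miRNA position k faces target s + 8 - k
  emit(m, s + 8L - seq_len(L))
  # one target gap at miRNA position g (outside the seed)
  for (g in unique(c(1L, if (L >= 9L) 9:L))) {
    tpos <- integer(L)
    ks <- seq_len(L)
    tpos <- ifelse(ks < g, s + 8L - ks, s + 9L - ks)
    tpos[g] <- NA_integer_
    if (g == 1L) tpos[-1L] <- s + 8L - ks[-1L]
    emit(m, tpos)
  }
  # one miRNA gap between positions g and g+1
  for (g in unique(c(1L, if (L >= 9L) 8:(L - 1L)))) {
    mCols <- append(m, "-", after = g)
    T0 <- if (g == 1L) s + 8L else s + 7L
    emit(mCols, T0 - seq_len(L + 1L) + 1L)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Scan transcripts for miRNA target sites
#'
#' Sites require an exact-complement 7-mer seed over miRNA positions 2-8;
#' around each seed hit, the ungapped alignment and all single-gap variants
#' (gap outside the seed, on either strand) are scored with the
#' [scoreDuplex()] weights, and sites at penalty <= `maxPenalty` are
#' reported. Overlapping sites of one miRNA on one transcript are merged to
#' the best-scoring (ties to the leftmost); output is sorted by penalty, then
#' coordinate. Coordinates are 1-based inclusive; `cut` is the target
#' position paired to miRNA position 10 (the canonical cleavage site).
#'
#' @param mirnas named character vector of mature sequences, or a list of
#'   [MiRNACall-class].
#' @param transcripts named character vector.
#' @param maxPenalty penalty cutoff (default 4.0; raise toward ~5 to emulate
#'   looser expectation cutoffs).
#' @return `data.frame`: mirna, transcript, start, end, cut, penalty,
#'   pairing.
#' @export
scanTargets <- function(mirnas, transcripts, maxPenalty = 4.0) {
  if (is.list(mirnas) && !is.data.frame(mirnas)) {
    nm <- vapply(seq_along(mirnas), function(i) {
      cl <- mirnas[[i]]
      if (!is.na(cl@family)) sprintf("%s_%d", cl@family, i) else
        sprintf("novel_%d", i)
    }, character(1))
    mirnas <- stats::setNames(
      vapply(mirnas, matureSequence, character(1)), nm)
  }
  mirnas <- stats::setNames(normalizeRna(mirnas), names(mirnas))
  if (is.null(names(mirnas)))
    names(mirnas) <- paste0("mir", seq_along(mirnas))
  transcripts <- normalizeRna(transcripts)

  rows <- list()
  for (mn in names(mirnas)) {
    m <- strsplit(mirnas[[mn]], "", fixed = TRUE)[[1]]
    if (length(m) < 10L) next
    seedRC <- rnaRevComp(paste(m[2:8], collapse = ""))
    for (tx in names(transcripts)) {
      hits <- gregexpr(seedRC, transcripts[[tx]], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (s in as.integer(hits)) {
        r <- .alignmentsAtSeed(m, transcripts[[tx]], tx, s, maxPenalty)
        if (!is.null(r)) { r$mirna <- mn; rows[[length(rows) + 1L]] <- r }
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0), cut = integer(0),
                      penalty = numeric(0), pairing = character(0)))
  df <- do.call(rbind, rows)
  # merge overlapping sites per (mirna, transcript): keep best penalty,
  # ties to the leftmost
  df <- df[order(df$mirna, df$transcript, df$penalty, df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (key in unique(paste(df$mirna, df$transcript))) {
    idx <- which(paste(df$mirna, df$transcript) == key)
    taken <- matrix(numeric(0), ncol = 2)
    for (i in idx) {
      if (!nrow(taken) ||
          all(df$start[i] > taken[, 2] | df$end[i] < taken[, 1])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(df$start[i], df$end[i]))
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$penalty, df$transcript, df$start, df$mirna), , drop = FALSE]
  rownames(df) <- NULL
  df
}
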