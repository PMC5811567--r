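# Novel miRNA calling from unannotated, non-conserved tags: exact-match loci
# on transcripts, Dicer-consistent read stacks, stem-loop validation.

#' Find candidate loci of unannotated tags on transcripts
#'
#' Every exact forward tag occurrence contributes to a locus; occurrences on
#' the same transcript whose 5' starts lie within `mergeGap` nt are merged.
#' A locus is kept when the summed read count of its members reaches
#' `minCount`, and records its dominant (highest-count) tag.
#'
#' @param tagLibraries list of [TagLibrary-class]: the post-filter,
#'   non-conserved pool (counts are pooled across libraries).
#' @param transcripts named character vector.
#' @param minCount minimum total locus read count (default 3).
#' @param mergeGap merge distance between member 5' starts in nt (default 30).
#' @return list of loci; each locus is a list with `transcript`, `start`,
#'   `end` (footprint), `members` (`data.frame`: tag, start, end, count),
#'   `total`, `dominant`, `dominantStart`.
#' @export
candidateLoci <- function(tagLibraries, transcripts, minCount = 3L,
                          mergeGap = 30L) {
  if (is(tagLibraries, "TagLibrary")) tagLibraries <- list(tagLibraries)
  pooled <- Reduce(function(acc, lib) {
    cnt <- tagCounts(lib)
    for (s in names(cnt)) acc[s] <- (if (s %in% names(acc)) acc[s] else 0) + cnt[s]
    acc
  }, tagLibraries, init = stats::setNames(numeric(0), character(0)))
  transcripts <- normalizeRna(transcripts)

  occ <- list()
  for (tg in names(pooled)) {
    for (tx in names(transcripts)) {
      hits <- gregexpr(tg, transcripts[[tx]], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (s in as.integer(hits))
        occ[[length(occ) + 1L]] <- data.frame(
          transcript = tx, tag = tg, start = s, end = s + nchar(tg) - 1L,
          count = unname(pooled[tg]), stringsAsFactors = FALSE)
    }
  }
  if (!length(occ)) return(list())
  occ <- do.call(rbind, occ)
  occ <- occ[order(occ$transcript, occ$start, occ$tag), , drop = FALSE]

  loci <- list()
  for (tx in unique(occ$transcript)) {
    sub <- occ[occ$transcript == tx, , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$start) > mergeGap))
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      rownames(mem) <- NULL
      total <- sum(mem$count)
      if (total < minCount) next
      dom <- mem[order(-mem$count, mem$tag), , drop = FALSE][1, ]
      loci[[length(loci) + 1L]] <- list(
        transcript = tx, start = min(mem$start), end = max(mem$end),
        members = mem, total = total, dominant = dom$tag,
        dominantStart = dom$start)
    }
  }
  loci
}

# fraction of locus reads consistent with Dicer processing of the chosen
# precursor: 5' ends within +/- tol of the dominant 5' end, or member
# footprint within the star/loop span of the candidate (transcript coords)
.readConsistency <- function(locus, candidate, tol = 2L) {
  mem <- locus$members
  near <- abs(mem$start - locus$dominantStart) <= tol
  ok <- near
  if (length(candidate@star) == 2L) {
    w0 <- candidate@window[1] - 1L
    m <- candidate@mature + w0
    st <- sort(candidate@star + w0)
    lo <- min(m[1], st[1]); hi <- max(m[2], st[2])  # mature..loop..star span
    ok <- ok | (mem$start >= lo - tol & mem$end <= hi + tol)
  }
  sum(mem$count[ok]) / sum(mem$count)
}

#' Call novel miRNAs from candidate loci
#'
#' For each locus, windows are excised around the dominant tag (same schedule
#' as conserved identification), folded and validated with
#' [validateStemloop()]; the locus must additionally show a Dicer-consistent
#' read stack: the fraction of locus reads whose 5' ends fall within 2 nt of
#' the dominant 5' end, or within the star/loop span, must reach
#' `readConsistency`. Calls with an identical mature sequence across loci are
#' deduplicated, keeping the lowest-MFEI precursor and recording the other
#' loci as additional precursors (set `keepDuplicates = TRUE` to mirror
#' per-locus accounting instead). Matures matching the known set within
#' `maxKnownMismatch` are excluded (they belong to the conserved caller).
#'
#' @param loci from [candidateLoci()].
#' @param transcripts named character vector.
#' @param tagLibraries list of [TagLibrary-class] for per-library counts and
#'   star support.
#' @param known optional known-mature `data.frame`; enforces disjointness.
#' @param readConsistency required consistent-read fraction (default 0.75).
#' @param flank excision flank (default 250).
#' @param maxKnownMismatch homology radius excluded as conserved (default 2).
#' @param maxMatureUnpaired,requireOneArm forwarded to [validateStemloop()].
#' @param keepDuplicates emit one call per locus even for identical matures.
#' @return list with `calls` (list of [MiRNACall-class]) and `log`
#'   (`data.frame` of rejected loci with reasons).
#' @export
callNovel <- function(loci, transcripts, tagLibraries, known = NULL,
                      readConsistency = 0.75, flank = 250L,
                      maxKnownMismatch = 2L, maxMatureUnpaired = 8L,
                      requireOneArm = TRUE, keepDuplicates = FALSE) {
  if (is(tagLibraries, "TagLibrary")) tagLibraries <- list(tagLibraries)
  if (is.null(names(tagLibraries)))
    names(tagLibraries) <- vapply(tagLibraries, libraryName, character(1))
  transcripts <- normalizeRna(transcripts)
  pooled <- unique(unlist(lapply(tagLibraries, tagSequences), use.names = FALSE))

  calls <- list()
  log <- list()
  reject <- function(locus, reason) {
    log[[length(log) + 1L]] <<- data.frame(
      transcript = locus$transcript, start = locus$start,
      dominant = locus$dominant, reason = reason, stringsAsFactors = FALSE)
  }
  for (locus in loci) {
    dom <- locus$dominant
    if (!is.null(known) && nrow(known)) {
      mm <- min(vapply(known$sequence, function(k) mismatchCount(dom, k),
                       numeric(1)))
      if (mm <= maxKnownMismatch) { reject(locus, "matches_known_set"); next }
    }
    cands <- locateAndExcise(dom, transcripts[locus$transcript], flank = flank)
    # keep windows anchored at this locus (the dominant tag may multi-map)
    cands <- Filter(function(cc) {
      cc@window[1] + cc@mature[1] - 1L == locus$dominantStart
    }, cands)
    ok <- vapply(cands, function(cc)
      validateStemloop(cc, maxMatureUnpaired = maxMatureUnpaired,
                       requireOneArm = requireOneArm)$accept, logical(1))
    if (!length(cands) || !any(ok)) { reject(locus, "no_validated_stemloop"); next }
    acc <- cands[ok]
    best <- acc[[order(vapply(acc, function(cc)
      ifelse(is.na(cc@mfei), 0, cc@mfei), numeric(1)))[1]]]
    cons <- .readConsistency(locus, best)
    if (cons < readConsistency) { reject(locus, "read_stack_inconsistent"); next }
    calls[[length(calls) + 1L]] <- new("MiRNACall",
      mature = dom, kind = "novel", family = NA_character_,
      precursor = best, counts = .libraryCounts(dom, tagLibraries),
      starSupported = .starSupport(best, transcripts, pooled),
      extraPrecursors = character(0))
  }

  if (!keepDuplicates && length(calls) > 1L) {
    matures <- vapply(calls, function(cl) cl@mature, character(1))
    keep <- list()
    for (m in unique(matures)) {
      idx <- which(matures == m)
      if (length(idx) == 1L) { keep[[length(keep) + 1L]] <- calls[[idx]]; next }
      mfeis <- vapply(idx, function(i) {
        v <- calls[[i]]@precursor@mfei
        if (is.na(v)) 0 else v
      }, numeric(1))
      b <- idx[order(mfeis)[1]]
      cl <- calls[[b]]
      cl@extraPrecursors <- vapply(setdiff(idx, b), function(i)
        calls[[i]]@precursor@sourceId, character(1))
      keep[[length(keep) + 1L]] <- cl
    }
    calls <- keep
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(transcript = character(0), start = integer(0),
               dominant = character(0), reason = character(0))
  list(calls = calls, log = log)
}

#' Composition statistics of mature miRNA sequences
#'
#' @param x list of [MiRNACall-class] or character vector of matures.
#' @return list with `fivePrimeUFraction` (`NaN` when empty), `lengthMin`,
#'   `lengthMax` (`NA` when empty) and `lengthHistogram` (named integer).
#' @export
#' @examples
#' compositionStats(llNovelMirnas()$sequence)
compositionStats <- function(x) {
  seqs <- if (is.list(x)) vapply(x, matureSequence, character(1)) else
    normalizeRna(x)
  if (!length(seqs))
    return(list(fivePrimeUFraction = NaN, lengthMin = NA_integer_,
                lengthMax = NA_integer_,
                lengthHistogram = stats::setNames(integer(0), character(0))))
  lens <- nchar(seqs)
  list(fivePrimeUFraction = mean(substr(seqs, 1L, 1L) == "U"),
       lengthMin = min(lens), lengthMax = max(lens),
       lengthHistogram = table(lens))
}
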