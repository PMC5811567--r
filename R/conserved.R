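# Conserved miRNA identification: mismatch-bounded homology to known matures,
# transcript anchoring, precursor excision/validation, family assignment.

#' Mismatch count between two small-RNA sequences
#'
#' Equal lengths: Hamming distance. Unequal lengths: minimum over ungapped
#' offsets of (mismatches on the overlap + the length difference), requiring
#' an overlap of at least `minOverlap` nt; `Inf` when no offset qualifies.
#' Symmetric, and invariant to the T/U input convention.
#'
#' @param a,b sequences (T normalised to U).
#' @param minOverlap minimum ungapped overlap for unequal lengths (default 18).
#' @return integer-valued mismatch count (possibly `Inf`).
#' @export
#' @examples
#' mismatchCount("UUCACUGCCACCAUCCGCCUGU", "UUUACUGCCACCAUCCGCCUGC")  # 2
mismatchCount <- function(a, b, minOverlap = 18L) {
  a <- strsplit(normalizeRna(a), "", fixed = TRUE)[[1]]
  b <- strsplit(normalizeRna(b), "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b)
  if (la == lb) return(sum(a != b))
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  best <- Inf
  for (off in seq(-(la - minOverlap), lb - minOverlap)) {
    sa <- max(1L, 1L - off); ea <- min(la, lb - off)
    ov <- ea - sa + 1L
    if (ov < minOverlap) next
    mm <- sum(a[sa:ea] != b[(sa + off):(ea + off)]) + (lb - la)
    if (mm < best) best <- mm
  }
  best
}

#' Match tags against a known mature miRNA set
#'
#' Reports every (tag, known entry) pair within the mismatch budget, together
#' with the tag's best-hit family (minimum mismatches; ties broken by the
#' lowest MIR family number, then name).
#'
#' @param tags a [TagLibrary-class] or character vector of tag sequences.
#' @param known a known-mature `data.frame` from [knownMatureSet()].
#' @param maxMismatch homology budget (default 2, the conserved-miRNA rule).
#' @return `data.frame` with columns `tag`, `name`, `family`, `familyNumber`,
#'   `mismatches`, `best` (logical: the tag's best hit).
#' @export
matchKnown <- function(tags, known, maxMismatch = 2L) {
  seqs <- if (is(tags, "TagLibrary")) tagSequences(tags) else
    normalizeRna(tags)
  assertThat(nrow(known) > 0L, "known mature set is empty")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    mm <- vapply(known$sequence, function(k) mismatchCount(seqs[i], k),
                 numeric(1), USE.NAMES = FALSE)
    hit <- which(mm <= maxMismatch)
    if (!length(hit)) next
    df <- data.frame(tag = seqs[i], name = known$name[hit],
                     family = known$family[hit],
                     familyNumber = known$familyNumber[hit],
                     mismatches = mm[hit], stringsAsFactors = FALSE)
    df <- df[order(df$mismatches, df$familyNumber, df$name), , drop = FALSE]
    df$best <- seq_len(nrow(df)) == 1L
    out[[i]] <- df
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tag = character(0), name = character(0),
                      family = character(0), familyNumber = integer(0),
                      mismatches = numeric(0), best = logical(0))
  rownames(out) <- NULL
  out
}

#' Locate a tag on transcripts and excise folded precursor windows
#'
#' For every exact forward occurrence of the tag, emits the symmetric
#' tag+/-flank window plus the two asymmetric windows (flank downstream only /
#' upstream only), clipped to transcript bounds, each folded and annotated
#' with the mature interval, AMFE, MFEI and the derived star interval.
#'
#' @param tagSeq the tag (mature candidate) sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param flank flanking length in nt excised on each side (default 250).
#' @param bothStrands also scan the reverse complement strand (default FALSE;
#'   assembled transcripts are taken as forward).
#' @return list of [PrecursorCandidate-class] (possibly empty).
#' @export
locateAndExcise <- function(tagSeq, transcripts, flank = 250L,
                            bothStrands = FALSE) {
  tagSeq <- normalizeRna(tagSeq)
  transcripts <- normalizeRna(transcripts)
  if (bothStrands)
    transcripts <- c(transcripts,
                     stats::setNames(rnaRevComp(transcripts),
                                     paste0(names(transcripts), "_rc")))
  out <- list()
  tl <- nchar(tagSeq)
  for (tx in names(transcripts)) {
    seq <- transcripts[[tx]]
    hits <- gregexpr(tagSeq, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    L <- nchar(seq)
    for (s in as.integer(hits)) {
      e <- s + tl - 1L
      wins <- unique(list(
        c(max(1L, s - flank), min(L, e + flank)),
        c(s, min(L, e + flank)),
        c(max(1L, s - flank), e)))
      for (w in wins) {
        if (w[2] - w[1] + 1L < 10L) next
        wseq <- substr(seq, w[1], w[2])
        fold <- foldMfe(wseq)
        stat <- amfeMfei(fold)
        mat <- c(s - w[1] + 1L, e - w[1] + 1L)
        star <- starOf(fold, mat)
        out[[length(out) + 1L]] <- new("PrecursorCandidate",
          sourceId = tx, window = as.integer(w), fold = fold,
          mature = as.integer(mat), star = star, amfe = stat$amfe,
          mfei = stat$mfei, gcPercent = stat$gcPercent)
      }
    }
  }
  out
}

# per-library exact-tag counts for a mature sequence
.libraryCounts <- function(matureSeq, tagLibraries) {
  vapply(tagLibraries, function(lib) {
    cnt <- lib@tags$count[lib@tags$sequence == matureSeq]
    if (length(cnt)) as.numeric(cnt[1]) else 0
  }, numeric(1))
}

# TRUE when any tag in the pooled libraries starts within +/- tol nt of the
# candidate's star interval
.starSupport <- function(candidate, transcripts, pooledTags, tol = 2L) {
  if (length(candidate@star) != 2L) return(FALSE)
  wseq <- candidate@fold@sequence
  starStart <- candidate@star[1]
  lo <- max(1L, starStart - tol)
  for (tg in pooledTags) {
    hits <- gregexpr(tg, wseq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    if (any(abs(as.integer(hits) - starStart) <= tol)) return(TRUE)
  }
  FALSE
}

#' Call conserved miRNAs
#'
#' A conserved call is emitted for every tag that (i) hits the known set
#' within the mismatch budget and (ii) has at least one excised window
#' accepted by [validateStemloop()]. Among accepted windows the lowest-MFEI
#' one is retained. The call carries the best-hit family, per-library counts
#' of the exact tag, and a star-support flag (a sequenced tag within 2 nt of
#' the computed star interval).
#'
#' @param tagLibraries list of [TagLibrary-class] (the filtered,
#'   "without annotation" pools), named by library.
#' @param known known-mature `data.frame` from [knownMatureSet()].
#' @param transcripts named character vector of transcripts.
#' @param maxMismatch homology budget (default 2).
#' @param flank excision flank (default 250).
#' @param maxMatureUnpaired,requireOneArm forwarded to [validateStemloop()].
#' @return list with `calls` (list of [MiRNACall-class]) and `log`
#'   (`data.frame` of tags with homology hits but no validated precursor).
#' @export
callConserved <- function(tagLibraries, known, transcripts, maxMismatch = 2L,
                          flank = 250L, maxMatureUnpaired = 8L,
                          requireOneArm = TRUE) {
  if (is(tagLibraries, "TagLibrary")) tagLibraries <- list(tagLibraries)
  if (is.null(names(tagLibraries)))
    names(tagLibraries) <- vapply(tagLibraries, libraryName, character(1))
  pooled <- unique(unlist(lapply(tagLibraries, tagSequences), use.names = FALSE))
  transcripts <- normalizeRna(transcripts)

  hits <- matchKnown(pooled, known, maxMismatch = maxMismatch)
  calls <- list()
  log <- list()
  for (tg in unique(hits$tag)) {
    fam <- hits[hits$tag == tg & hits$best, , drop = FALSE]
    cands <- locateAndExcise(tg, transcripts, flank = flank)
    ok <- vapply(cands, function(cc)
      validateStemloop(cc, maxMatureUnpaired = maxMatureUnpaired,
                       requireOneArm = requireOneArm)$accept, logical(1))
    if (!length(cands) || !any(ok)) {
      log[[length(log) + 1L]] <- data.frame(
        tag = tg, family = fam$family,
        reason = if (!length(cands)) "no_transcript_locus"
                 else "no_validated_stemloop")
      next
    }
    acc <- cands[ok]
    best <- acc[[order(vapply(acc, function(cc)
      ifelse(is.na(cc@mfei), 0, cc@mfei), numeric(1)))[1]]]
    calls[[length(calls) + 1L]] <- new("MiRNACall",
      mature = tg, kind = "conserved", family = fam$family,
      precursor = best, counts = .libraryCounts(tg, tagLibraries),
      starSupported = .starSupport(best, transcripts, pooled),
      extraPrecursors = character(0))
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(tag = character(0), family = character(0),
               reason = character(0))
  list(calls = calls, log = log)
}

#' Tabulate miRNA calls
#'
#' @param calls list of [MiRNACall-class].
#' @return `data.frame` with one row per call: kind, family, mature sequence,
#'   length, precursor id, MFE/AMFE/MFEI, star support and per-library counts.
#' @export
callTable <- function(calls) {
  if (!length(calls))
    return(data.frame(kind = character(0), family = character(0),
                      sequence = character(0), length = integer(0),
                      precursor = character(0), mfe = numeric(0),
                      amfe = numeric(0), mfei = numeric(0),
                      star_supported = logical(0)))
  base <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(kind = cl@kind, family = cl@family, sequence = cl@mature,
               length = nchar(cl@mature), precursor = cl@precursor@sourceId,
               mfe = cl@precursor@fold@mfe, amfe = cl@precursor@amfe,
               mfei = cl@precursor@mfei,
               star_supported = cl@starSupported, stringsAsFactors = FALSE)
  }))
  cnts <- do.call(rbind, lapply(calls, function(cl)
    as.data.frame(as.list(cl@counts))))
  if (!is.null(cnts) && ncol(cnts)) base <- cbind(base, cnts)
  rownames(base) <- NULL
  base
}

#' Summarise miRNA calls by family
#'
#' Accepts either a list of [MiRNACall-class] or a `data.frame` with columns
#' `family` and `sequence` (e.g. a published catalogue), and reports per
#' family the member and precursor counts and the 5'-nucleotide composition,
#' plus the overall fraction of mature sequences starting with U.
#'
#' @param x calls or `data.frame`.
#' @return list with `families` (`data.frame`: family, members, precursors,
#'   five_prime_u) and `fivePrimeUFraction` (overall, `NaN` when empty).
#' @export
#' @examples
#' summarizeFamilies(llConservedMirnas())$fivePrimeUFraction  # 0.84
summarizeFamilies <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    df <- callTable(x)
  } else {
    df <- x
    assertThat(all(c("family", "sequence") %in% names(df)),
               "need columns 'family' and 'sequence'")
    if (!"precursor" %in% names(df)) df$precursor <- NA_character_
  }
  df$sequence <- normalizeRna(df$sequence)
  if (!nrow(df))
    return(list(families = data.frame(family = character(0),
                                      members = integer(0),
                                      precursors = integer(0),
                                      five_prime_u = integer(0)),
                fivePrimeUFraction = NaN))
  five <- substr(df$sequence, 1L, 1L)
  fams <- sort(unique(df$family))
  tab <- data.frame(
    family = fams,
    members = vapply(fams, function(f)
      length(unique(df$sequence[df$family == f])), integer(1)),
    precursors = vapply(fams, function(f)
      length(unique(stats::na.omit(df$precursor[df$family == f]))),
      integer(1)),
    five_prime_u = vapply(fams, function(f)
      sum(five[df$family == f] == "U"), integer(1)),
    row.names = NULL)
  list(families = tab, fivePrimeUFraction = mean(five == "U"))
}
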