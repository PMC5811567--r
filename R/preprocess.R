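# Read preprocessing: 3' adapter trimming, 18-30 nt length filtering,
# collapsing to unique tags, ncRNA contaminant removal, length distributions.

#' Trim 3' adapters and length-filter small-RNA reads
#'
#' Each read is cut at the leftmost full occurrence of the 3' adapter; reads
#' whose adapter is only partially sequenced are trimmed when a prefix of the
#' adapter of at least `minAdapterOverlap` nt terminates the read. Reads with
#' no adapter evidence, with ambiguous residues, or whose trimmed insert falls
#' outside `[minLen, maxLen]` are discarded and tallied per reason. T is
#' normalised to U on input.
#'
#' @param reads character vector of reads (optionally named), or any
#'   `XStringSet`.
#' @param adapter3 the 3' adapter sequence (non-empty).
#' @param minLen,maxLen inclusive insert length bounds (defaults 18 and 30 nt,
#'   the small-RNA clean-read window).
#' @param minAdapterOverlap minimum adapter prefix length accepted at the read
#'   end (default 8).
#' @return list with `reads` (named character vector of trimmed inserts) and
#'   `tallies` (named integer: kept, no_adapter, too_short, too_long,
#'   invalid_residue; these always sum to the input read count).
#' @export
#' @examples
#' trimAndFilter(paste0("UGACAGAAGAGAGUGAGCAC", "UGGAAUUCUCGGGUGCCAAGG"),
#'               adapter3 = "UGGAAUUCUCGGGUGCCAAGG")
trimAndFilter <- function(reads, adapter3, minLen = 18L, maxLen = 30L,
                          minAdapterOverlap = 8L) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  assertThat(length(adapter3) == 1L && nzchar(adapter3),
             "adapter3 must be a non-empty sequence")
  assertThat(minLen <= maxLen, "minLen must be <= maxLen")
  tallies <- c(kept = 0L, no_adapter = 0L, too_short = 0L, too_long = 0L,
               invalid_residue = 0L)
  if (!length(reads)) return(list(reads = character(0), tallies = tallies))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))

  reads <- normalizeRna(reads)
  adapter3 <- normalizeRna(adapter3)
  bad <- hasInvalidResidues(reads)
  tallies["invalid_residue"] <- sum(bad)
  reads <- reads[!bad]

  # leftmost full adapter occurrence, else longest adapter prefix (>= overlap)
  # terminating the read
  hit <- regexpr(adapter3, reads, fixed = TRUE)
  insert <- ifelse(hit > 0L, substr(reads, 1L, hit - 1L), NA_character_)
  noFull <- which(hit < 0L)
  maxPartial <- min(nchar(adapter3) - 1L, max(nchar(reads), 0L))
  for (i in noFull) {
    r <- reads[i]
    nr <- nchar(r)
    for (k in seq(min(maxPartial, nr), minAdapterOverlap)) {
      if (k < minAdapterOverlap) break
      if (substr(r, nr - k + 1L, nr) == substr(adapter3, 1L, k)) {
        insert[i] <- substr(r, 1L, nr - k)
        break
      }
    }
  }
  found <- !is.na(insert)
  tallies["no_adapter"] <- sum(!found)
  insert <- insert[found]
  len <- nchar(insert)
  tallies["too_short"] <- sum(len < minLen)
  tallies["too_long"] <- sum(len > maxLen)
  keep <- len >= minLen & len <= maxLen
  tallies["kept"] <- sum(keep)
  list(reads = insert[keep], tallies = tallies)
}

#' Collapse reads into a unique-tag library
#'
#' One entry per distinct sequence with its multiplicity; the sum of counts
#' equals the number of input reads. Tags are ordered by decreasing count,
#' then sequence, which fixes the `tag{serial}` numbering used on output.
#'
#' @param reads character vector of trimmed, filtered reads.
#' @param libraryName library (tissue) label.
#' @param minLen,maxLen the length bounds the reads were filtered to;
#'   recorded in the library.
#' @return a [TagLibrary-class].
#' @export
collapseTags <- function(reads, libraryName, minLen = 18L, maxLen = 30L) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- normalizeRna(unname(reads))
  if (length(reads)) {
    tab <- table(reads)
    df <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$sequence), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(sequence = character(0), count = integer(0))
  }
  new("TagLibrary", libraryName = libraryName, tags = df,
      bounds = as.integer(c(minLen, maxLen)))
}

#' Remove tags matching annotated ncRNA classes
#'
#' A tag is removed when it aligns ungapped as a substring of any annotation
#' record with at most `maxMismatch` mismatches. Removed read counts are
#' tallied per class; ties across classes are broken by the fixed order
#' rRNA > tRNA > snRNA > snoRNA. Survivors form the "without annotation" pool.
#'
#' @param tags a [TagLibrary-class].
#' @param annotation an [AnnotationSet-class] (non-empty).
#' @param maxMismatch mismatch budget for the ungapped containment match
#'   (default 0).
#' @return list with `tags` (the filtered [TagLibrary-class]) and `tally`
#'   (`data.frame` per class: tags_removed, reads_removed).
#' @export
filterAnnotated <- function(tags, annotation, maxMismatch = 0L) {
  stopifnot(is(tags, "TagLibrary"), is(annotation, "AnnotationSet"))
  rec <- annotation@records
  assertThat(nrow(rec) > 0L, "annotation set is empty")
  rec$sequence <- normalizeRna(rec$sequence)
  classes <- NCRNA_CLASSES
  subjects <- lapply(classes, function(cl) {
    Biostrings::RNAStringSet(rec$sequence[rec$class == cl])
  })
  names(subjects) <- classes

  seqs <- tags@tags$sequence
  assigned <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    pat <- Biostrings::RNAString(seqs[i])
    for (cl in classes) {
      if (!length(subjects[[cl]])) next
      nhit <- sum(Biostrings::vcountPattern(pat, subjects[[cl]],
                                            max.mismatch = maxMismatch))
      if (nhit > 0L) { assigned[i] <- cl; break }
    }
  }
  removed <- !is.na(assigned)
  tally <- data.frame(
    class = classes,
    tags_removed = vapply(classes, function(cl)
      sum(assigned == cl, na.rm = TRUE), integer(1)),
    reads_removed = vapply(classes, function(cl)
      sum(tags@tags$count[which(assigned == cl)]), integer(1)),
    row.names = NULL)
  kept <- tags@tags[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(tags = new("TagLibrary", libraryName = tags@libraryName, tags = kept,
                  bounds = tags@bounds),
       tally = tally)
}

#' Length distribution of a tag library
#'
#' @param tags a [TagLibrary-class].
#' @return `data.frame` with one row per length within the library bounds:
#'   `length`, `clean_reads` (sum of counts), `unique_reads` (number of
#'   tags). Column sums equal the library totals.
#' @export
lengthDistribution <- function(tags) {
  stopifnot(is(tags, "TagLibrary"))
  lens <- tags@bounds[1]:tags@bounds[2]
  tl <- nchar(tags@tags$sequence)
  data.frame(
    length = lens,
    clean_reads = vapply(lens, function(L)
      sum(tags@tags$count[tl == L]), numeric(1)),
    unique_reads = vapply(lens, function(L) sum(tl == L), integer(1)))
}
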