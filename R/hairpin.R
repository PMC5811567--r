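# Duplex geometry on a folded precursor: star derivation and stem-loop
# acceptance. Intervals are 1-based closed, in the coordinates of the folded
# sequence.

#' Derive the miRNA* interval from a fold and a mature interval
#'
#' The star is the region pairing with the mature, shifted by 2 nt toward the
#' mature's 5' side partner so that each duplex strand carries the canonical
#' 2-nt 3' overhang. Absent (`integer(0)`) when fewer than 60% of mature
#' positions are paired, when pairing partners fall inside the mature or on
#' both of its sides (the mature straddles the terminal loop), or when the
#' shifted star would overlap the mature.
#'
#' @param fold a [HairpinFold-class].
#' @param mature integer(2), 1-based closed interval within the fold.
#' @param minPairedFraction minimum fraction of paired mature positions
#'   (default 0.6).
#' @return integer(2) star interval, or `integer(0)` when absent.
#' @export
starOf <- function(fold, mature, minPairedFraction = 0.6) {
  stopifnot(is(fold, "HairpinFold"), length(mature) == 2L)
  n <- nchar(fold@sequence)
  mature <- as.integer(mature)
  assertThat(mature[1] >= 1L && mature[2] <= n && mature[1] <= mature[2],
             "mature interval outside the fold")
  pt <- pairTable(fold@structure)
  pos <- mature[1]:mature[2]
  partners <- pt[pos]
  paired <- partners > 0L
  if (mean(paired) < minPairedFraction) return(integer(0))
  prt <- partners[paired]
  if (any(prt >= mature[1] & prt <= mature[2])) return(integer(0))
  left <- any(prt < mature[1]); right <- any(prt > mature[2])
  if (left && right) return(integer(0))
  shift <- if (right) 2L else -2L
  star <- c(min(prt), max(prt)) + shift
  star <- c(max(1L, star[1]), min(n, star[2]))
  if (star[1] <= mature[2] && mature[1] <= star[2]) return(integer(0))
  as.integer(star)
}

#' Decide stem-loop validity of a precursor candidate
#'
#' A candidate is accepted when (a) the mature lies entirely on one arm (its
#' pairing partners all fall on the same side, none inside the mature), (b) at
#' most `maxMatureUnpaired` mature positions are unpaired, (c) every paired
#' position within the partner block pairs back into the mature (the star
#' block is a contiguous opposite-arm block, bulges allowed), and (d) the fold
#' energy is negative. Rejections report every violated clause.
#'
#' @param candidate a [PrecursorCandidate-class].
#' @param maxMatureUnpaired maximum unpaired nucleotides tolerated within the
#'   mature (default 8).
#' @param requireOneArm when `TRUE` (default) clause (a) is enforced.
#' @return list with `accept` (logical) and `reasons` (character vector of
#'   violated clauses, empty on acceptance).
#' @export
validateStemloop <- function(candidate, maxMatureUnpaired = 8L,
                             requireOneArm = TRUE) {
  stopifnot(is(candidate, "PrecursorCandidate"))
  fold <- candidate@fold
  mature <- candidate@mature
  pt <- pairTable(fold@structure)
  pos <- mature[1]:mature[2]
  partners <- pt[pos]
  prt <- partners[partners > 0L]
  reasons <- character(0)

  inMature <- any(prt >= mature[1] & prt <= mature[2])
  left <- any(prt < mature[1]); right <- any(prt > mature[2])
  if (requireOneArm && (inMature || (left && right)))
    reasons <- c(reasons, "mature_straddles_loop")

  if (sum(partners == 0L) > maxMatureUnpaired)
    reasons <- c(reasons, "mature_unpaired_exceeds_threshold")

  if (length(prt) && !(left && right) && !inMature) {
    block <- min(prt):max(prt)
    foreign <- pt[block] > 0L & !(pt[block] >= mature[1] & pt[block] <= mature[2])
    if (any(foreign))
      reasons <- c(reasons, "star_block_not_contiguous")
  } else if (!length(prt)) {
    reasons <- c(reasons, "star_block_not_contiguous")
  }

  if (!(fold@mfe < 0))
    reasons <- c(reasons, "mfe_not_negative")

  list(accept = length(reasons) == 0L, reasons = reasons)
}
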