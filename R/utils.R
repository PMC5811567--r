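# Small shared helpers. All internal sequences are RNA alphabet (A/C/G/U);
# T is accepted on input and normalised to U.

RNA_BASES <- c("A", "C", "G", "U")
NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Normalise a character vector of sequences to the RNA alphabet
#'
#' Uppercases and converts T to U. Does not validate residues; see
#' [hasInvalidResidues()].
#' @param x character vector of sequences.
#' @return character vector over the RNA alphabet.
#' @keywords internal
#' @noRd
normalizeRna <- function(x) {
  chartr("t", "u", chartr("T", "U", toupper(x)))
}

#' @noRd
hasInvalidResidues <- function(x) {
  grepl("[^ACGU]", x)
}

#' Reverse complement of RNA sequences
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' rnaRevComp("UGACAGAAGAGAGUGAGCAC")
rnaRevComp <- function(x) {
  x <- normalizeRna(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Watson-Crick or G:U wobble pairing class of two single bases:
# 0 none, 1 GC/CG, 2 AU/UA, 3 GU/UG
pairClass1 <- function(a, b) {
  ab <- paste0(a, b)
  if (ab %in% c("GC", "CG")) return(1L)
  if (ab %in% c("AU", "UA")) return(2L)
  if (ab %in% c("GU", "UG")) return(3L)
  0L
}

#' @noRd
gcPercentOf <- function(seq) {
  ch <- strsplit(normalizeRna(seq), "", fixed = TRUE)[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# stopifnot with a custom message
assertThat <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
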