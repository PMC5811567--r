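# RNA folding surface: the dynamic-programming folder lives in src/fold.cpp;
# structureEnergy() is an independent R evaluator of the same declared model
# and doubles as the consistency oracle for every fold the pipeline produces.
#
# Model (units ~ kcal/mol-equivalents, all terms multiples of 0.1):
#   stacked pair (outer pair type)  GC/CG -3.0, AU/UA -2.0, GU/UG -1.0
#   isolated pair (no stacking neighbour)          half the pair energy
#   hairpin loop   +4.0 initiation, +0.5 per unpaired nt beyond 3 (min 3)
#   internal/bulge +2.0 initiation, +0.3 per unpaired nt (search cap 30 nt)
#   multibranch    +2.0 initiation, +0.3 per unpaired loop nt

.STACK <- c("1" = -3.0, "2" = -2.0, "3" = -1.0)  # by pairClass1()

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (characters `(`, `)`, `.`).
#' @return integer vector `pt` with `pt[i] = j` when i pairs j, 0 when
#'   unpaired. Errors on unbalanced brackets.
#' @export
#' @examples
#' pairTable("((...))")
pairTable <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (length(ch) && any(!ch %in% c("(", ")", ".")))
    stop("structure may only contain '(', ')' and '.'")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '('")
  pt
}

#' Energy of a given structure under the declared model
#'
#' Evaluates the loop decomposition of `structure` on `sequence`: stacking
#' terms for helix-internal pairs, loop initiation and per-nucleotide terms
#' for hairpin, internal/bulge and multibranch loops, and half pair energy for
#' isolated (unstacked) pairs. By construction
#' `structureEnergy(s, dotBracket(foldMfe(s))) == mfe(foldMfe(s))`.
#'
#' @param sequence RNA sequence (T accepted, normalised to U).
#' @param structure dot-bracket string of the same length.
#' @return the energy (0 for an all-dot structure).
#' @export
#' @examples
#' structureEnergy("GGGGAAAACCCC", "((((....))))")
structureEnergy <- function(sequence, structure) {
  sequence <- normalizeRna(sequence)
  assertThat(!hasInvalidResidues(sequence), "invalid residue in sequence")
  assertThat(nchar(sequence) == nchar(structure),
             "sequence and structure lengths differ")
  pt <- pairTable(structure)
  n <- length(pt)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  e <- 0
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next  # unpaired or closing half
    cls <- pairClass1(ch[i], ch[j])
    if (cls == 0L)
      stop(sprintf("pair %s-%s at (%d,%d) is not Watson-Crick or G:U",
                   ch[i], ch[j], i, j))
    # loop closed by (i, j)
    inner <- .innerChildren(pt, i, j)
    u <- (j - i - 1L) - sum(inner$ends - inner$starts + 1L)
    if (nrow(inner) == 0L) {
      if (u < 3L) stop("hairpin loop with fewer than 3 unpaired nucleotides")
      e <- e + 4.0 + 0.5 * max(0L, u - 3L)
    } else if (nrow(inner) == 1L && u == 0L) {
      e <- e + .STACK[[as.character(cls)]]  # stack on (i+1, j-1)
    } else if (nrow(inner) == 1L) {
      e <- e + 2.0 + 0.3 * u                # internal or bulge loop
    } else {
      e <- e + 2.0 + 0.3 * u                # multibranch loop
    }
    # isolated pair: no stacking neighbour inward or outward
    stackedIn <- (j - i >= 2L) && pt[i + 1L] == j - 1L
    stackedOut <- (i > 1L) && (j < n) && pt[i - 1L] == j + 1L
    if (!stackedIn && !stackedOut)
      e <- e + .STACK[[as.character(cls)]] / 2
  }
  round(e, 10)
}

# maximal pairs directly inside (i, j): data.frame(starts, ends)
.innerChildren <- function(pt, i, j) {
  starts <- integer(0); ends <- integer(0)
  k <- i + 1L
  while (k < j) {
    if (pt[k] > k) {
      starts <- c(starts, k); ends <- c(ends, pt[k])
      k <- pt[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  data.frame(starts = starts, ends = ends)
}

#' Fold a sequence to its minimum-energy nested structure
#'
#' Dynamic-programming minimisation over all non-crossing structures under the
#' package's model (see [structureEnergy()]). Deterministic: ties are broken
#' toward the structure with more pairs, then by a fixed traceback order, so
#' repeated calls are bit-identical.
#'
#' @param sequence RNA sequence, 10 to 2000 nt (T normalised to U).
#' @return a [HairpinFold-class].
#' @export
#' @examples
#' foldMfe("GGGGAAAACCCCAA")
foldMfe <- function(sequence) {
  sequence <- normalizeRna(sequence)
  assertThat(!hasInvalidResidues(sequence),
             "invalid residue (expected A/C/G/U, or T on input)")
  n <- nchar(sequence)
  if (n < 10L) stop("too short to fold")
  if (n > 2000L) stop("sequence longer than 2000 nt")
  res <- .fold_mfe_cpp(sequence)
  new("HairpinFold", sequence = sequence, structure = res$structure,
      mfe = res$mfe_deci / 10)
}

#' AMFE and MFEI precursor statistics
#'
#' AMFE is the energy normalised to 100 nt, `(mfe / length) * 100`; the
#' minimal folding energy index is `MFEI = AMFE / (G+C)%` with GC expressed on
#' the 0-100 scale, the convention under which typical plant pre-miRNAs score
#' around -0.5 to -1.5. MFEI is `NA` when the sequence has no G or C.
#'
#' @param fold a [HairpinFold-class].
#' @return list with elements `amfe`, `mfei`, `gcPercent`.
#' @export
#' @examples
#' amfeMfei(foldMfe("GGGGAAAACCCCAA"))
amfeMfei <- function(fold) {
  stopifnot(is(fold, "HairpinFold"))
  n <- nchar(fold@sequence)
  gc <- gcPercentOf(fold@sequence)
  a <- fold@mfe / n * 100
  list(amfe = a, mfei = if (gc > 0) a / gc else NA_real_, gcPercent = gc)
}

#' Format a fold as dot-bracket text
#'
#' Sequence line, structure line and `(mfe)` suffix, the layout common RNA
#' structure viewers accept.
#'
#' @param fold a [HairpinFold-class].
#' @param id optional header line written as `>id`.
#' @return character vector of lines.
#' @export
formatDotBracket <- function(fold, id = NULL) {
  c(if (!is.null(id)) paste0(">", id),
    fold@sequence,
    sprintf("%s (%.1f)", fold@structure, fold@mfe))
}
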