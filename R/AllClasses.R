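#' @import methods
NULL

# ---------------------------------------------------------------------------
# TagLibrary: collapsed unique small-RNA tags with per-library counts
# ---------------------------------------------------------------------------

#' TagLibrary: collapsed unique small-RNA tags
#'
#' The unit flowing through preprocessing and miRNA discovery: one entry per
#' distinct read sequence with its multiplicity in a library (tissue), plus
#' the length bounds the library was filtered to.
#'
#' @slot libraryName single character, e.g. `"flower"`.
#' @slot tags `data.frame` with columns `sequence` (RNA alphabet) and
#'   `count` (integer >= 1); no duplicated sequences.
#' @slot bounds integer(2), minimum and maximum tag length in nucleotides.
#'
#' @seealso [collapseTags()], [filterAnnotated()], [lengthDistribution()]
#' @export
setClass("TagLibrary",
  representation(libraryName = "character", tags = "data.frame",
                 bounds = "integer"))

setValidity("TagLibrary", function(object) {
  t <- object@tags
  msgs <- character()
  if (length(object@libraryName) != 1L)
    msgs <- c(msgs, "libraryName must be a single string")
  if (!all(c("sequence", "count") %in% names(t)))
    msgs <- c(msgs, "tags must have columns 'sequence' and 'count'")
  else {
    if (anyDuplicated(t$sequence))
      msgs <- c(msgs, "duplicate tag sequences")
    if (nrow(t) && any(t$count < 1))
      msgs <- c(msgs, "all counts must be >= 1")
    if (nrow(t) && any(hasInvalidResidues(t$sequence)))
      msgs <- c(msgs, "tag sequences must be over A/C/G/U")
    len <- nchar(t$sequence)
    if (nrow(t) && (any(len < object@bounds[1]) || any(len > object@bounds[2])))
      msgs <- c(msgs, "tag length outside bounds")
  }
  if (length(object@bounds) != 2L || object@bounds[1] > object@bounds[2])
    msgs <- c(msgs, "bounds must be integer(2) with min <= max")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# AnnotationSet: labelled ncRNA records used for contaminant removal
# ---------------------------------------------------------------------------

#' AnnotationSet: class-labelled ncRNA sequences
#'
#' Sequences labelled with one of the closed class set rRNA, tRNA, snRNA,
#' snoRNA, used to remove annotated non-miRNA small RNAs.
#'
#' @slot records `data.frame` with columns `id`, `class`, `sequence`.
#' @export
setClass("AnnotationSet", representation(records = "data.frame"))

setValidity("AnnotationSet", function(object) {
  r <- object@records
  if (!all(c("id", "class", "sequence") %in% names(r)))
    return("records must have columns id, class, sequence")
  if (nrow(r) && !all(r$class %in% NCRNA_CLASSES))
    return(sprintf("class labels must be one of: %s",
                   paste(NCRNA_CLASSES, collapse = ", ")))
  if (nrow(r) && any(hasInvalidResidues(normalizeRna(r$sequence))))
    return("annotation sequences must normalise to A/C/G/U")
  TRUE
})

# ---------------------------------------------------------------------------
# HairpinFold: a sequence with its predicted structure and energy
# ---------------------------------------------------------------------------

#' HairpinFold: an RNA sequence with folded structure and energy
#'
#' Holds a dot-bracket secondary structure and its energy under the package's
#' simplified loop-based model. Validity enforces the structural contract:
#' balanced non-crossing brackets, Watson-Crick or G:U pairs only, hairpin
#' loops of at least 3 unpaired nucleotides, and energy consistency
#' (`mfe == structureEnergy(sequence, structure)`).
#'
#' @slot sequence RNA sequence (A/C/G/U).
#' @slot structure dot-bracket string of the same length.
#' @slot mfe energy of the structure (model units, <= 0 for returned folds).
#'
#' @seealso [foldMfe()], [structureEnergy()]
#' @export
setClass("HairpinFold",
  representation(sequence = "character", structure = "character",
                 mfe = "numeric"))

setValidity("HairpinFold", function(object) {
  s <- object@sequence
  db <- object@structure
  if (length(s) != 1L || length(db) != 1L || length(object@mfe) != 1L)
    return("sequence, structure and mfe must be scalars")
  if (nchar(s) != nchar(db))
    return("structure length must equal sequence length")
  pt <- tryCatch(pairTable(db), error = function(e) conditionMessage(e))
  if (is.character(pt)) return(pt)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in which(pt > seq_along(pt))) {
    j <- pt[i]
    if (pairClass1(ch[i], ch[j]) == 0L)
      return(sprintf("illegal pair %s-%s at (%d,%d)", ch[i], ch[j], i, j))
    inner <- if (j - i >= 2L) pt[(i + 1L):(j - 1L)] else integer(0)
    if (!any(inner > 0L) && (j - i - 1L) < 3L)
      return("hairpin loop with fewer than 3 unpaired nucleotides")
  }
  e <- structureEnergy(s, db)
  if (abs(e - object@mfe) > 1e-9)
    return(sprintf("mfe (%g) inconsistent with structure energy (%g)",
                   object@mfe, e))
  TRUE
})

# ---------------------------------------------------------------------------
# PrecursorCandidate: an excised transcript window with fold and statistics
# ---------------------------------------------------------------------------

#' PrecursorCandidate: an excised, folded precursor window
#'
#' A window excised around a candidate mature miRNA on a transcript, folded,
#' with the mature (and, when derivable, star) interval in window coordinates
#' and the AMFE/MFEI statistics. All intervals are 1-based closed.
#'
#' @slot sourceId transcript identifier.
#' @slot window integer(2): start and end of the window on the transcript.
#' @slot fold [HairpinFold-class] of the window sequence.
#' @slot mature integer(2): mature interval within the window.
#' @slot star integer(2) or integer(0) when absent.
#' @slot amfe energy per 100 nt: `(mfe / window length) * 100`.
#' @slot mfei `amfe / gcPercent` with GC on the 0-100 scale (NA when GC = 0).
#' @slot gcPercent GC percentage of the window (0-100).
#' @export
setClass("PrecursorCandidate",
  representation(sourceId = "character", window = "integer",
                 fold = "HairpinFold", mature = "integer", star = "integer",
                 amfe = "numeric", mfei = "numeric", gcPercent = "numeric"))

setValidity("PrecursorCandidate", function(object) {
  n <- nchar(object@fold@sequence)
  w <- object@window
  m <- object@mature
  msgs <- character()
  if (length(w) != 2L || w[2] - w[1] + 1L != n)
    msgs <- c(msgs, "window must be integer(2) spanning the folded sequence")
  if (length(m) != 2L || m[1] < 1L || m[2] > n || m[1] > m[2])
    msgs <- c(msgs, "mature interval must lie within the window")
  st <- object@star
  if (length(st) == 2L && length(m) == 2L &&
      st[1] <= m[2] && m[1] <= st[2])
    msgs <- c(msgs, "star must be disjoint from mature")
  if (abs(object@amfe - object@fold@mfe / n * 100) > 1e-6)
    msgs <- c(msgs, "amfe must equal (mfe / window length) * 100")
  gc <- object@gcPercent
  if (gc > 0 && !is.na(object@mfei) &&
      abs(object@mfei - object@amfe / gc) > 1e-6)
    msgs <- c(msgs, "mfei must equal amfe / gcPercent")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# MiRNACall: an accepted conserved or novel miRNA
# ---------------------------------------------------------------------------

#' MiRNACall: an accepted conserved or novel miRNA
#'
#' @slot mature mature sequence (equal to the precursor's mature-interval
#'   subsequence).
#' @slot kind `"conserved"` or `"novel"`.
#' @slot family family label (e.g. `"MIR156"`); `NA` for novel calls.
#' @slot precursor the retained (lowest-MFEI) [PrecursorCandidate-class].
#' @slot counts named numeric of per-library read counts of the exact tag.
#' @slot starSupported `TRUE` when a sequenced tag sits within 2 nt of the
#'   computed star interval.
#' @slot extraPrecursors transcript ids of additional loci carrying an
#'   identical mature sequence.
#' @export
setClass("MiRNACall",
  representation(mature = "character", kind = "character", family = "character",
                 precursor = "PrecursorCandidate", counts = "numeric",
                 starSupported = "logical", extraPrecursors = "character"))

setValidity("MiRNACall", function(object) {
  msgs <- character()
  if (!object@kind %in% c("conserved", "novel"))
    msgs <- c(msgs, "kind must be 'conserved' or 'novel'")
  if (object@kind == "conserved" &&
      (length(object@family) != 1L || is.na(object@family) ||
       !nzchar(object@family)))
    msgs <- c(msgs, "conserved calls must carry a family")
  m <- object@precursor@mature
  sub <- substr(object@precursor@fold@sequence, m[1], m[2])
  if (!identical(sub, object@mature))
    msgs <- c(msgs, "mature must equal the precursor's mature subsequence")
  if (length(object@counts) && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by library")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# DegradomeProfile: per-transcript 5'-end counts
# ---------------------------------------------------------------------------

#' DegradomeProfile: per-transcript degradome 5'-end counts
#'
#' Sparse per-position counts of degradome tag 5' ends on one transcript.
#' Positions are 1-based; fractional counts arise from equal splitting of
#' multi-mapping tags.
#'
#' @slot transcriptId transcript identifier.
#' @slot positions integer vector of 1-based positions (sorted, unique).
#' @slot counts numeric vector of positive counts, parallel to `positions`.
#' @export
setClass("DegradomeProfile",
  representation(transcriptId = "character", positions = "integer",
                 counts = "numeric"))

setValidity("DegradomeProfile", function(object) {
  if (length(object@positions) != length(object@counts))
    return("positions and counts must be parallel")
  if (length(object@positions)) {
    if (is.unsorted(object@positions, strictly = TRUE))
      return("positions must be sorted and unique")
    if (any(object@counts <= 0))
      return("stored counts must be positive")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# GroundTruthManifest: record of everything the simulator planted
# ---------------------------------------------------------------------------

#' GroundTruthManifest: the synthetic generator's ground truth
#'
#' Records every planted hairpin (with its mature/star geometry and intended
#' per-tissue counts), contaminant, decoy and degradome cleavage scenario, so
#' recovery can be scored exactly.
#'
#' @slot mirnas `data.frame`: one row per planted miRNA (or decoy) with
#'   columns `name`, `kind` (`conserved`/`novel`/`decoy`), `family`, `mature`,
#'   `transcript`, `start`, `end`, `star_start`, `star_end` and per-tissue
#'   count columns.
#' @slot contaminants `data.frame`: planted ncRNA fragments (`sequence`,
#'   `class`, per-tissue counts).
#' @slot targets `data.frame`: planted target sites (`mirna`, `transcript`,
#'   `start`, `end`, `cut`, `intended_category`, `site_count`).
#' @slot seed the integer seed the study was generated from.
#' @export
setClass("GroundTruthManifest",
  representation(mirnas = "data.frame", contaminants = "data.frame",
                 targets = "data.frame", seed = "integer"))

setValidity("GroundTruthManifest", function(object) {
  if (nrow(object@targets) &&
      !all(object@targets$intended_category %in% 0:4))
    return("intended_category must be in 0..4")
  TRUE
})
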