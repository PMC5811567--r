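# Generics, accessors and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @describeIn TagLibrary-class number of unique tags
#' @param x,object a `TagLibrary`
#' @export
setMethod("length", "TagLibrary", function(x) nrow(x@tags))

#' Accessors for TagLibrary
#'
#' @param x a [TagLibrary-class].
#' @return `tagSequences()` the unique tag sequences; `tagCounts()` their
#'   counts (named by sequence); `libraryName()` the library label;
#'   `totalReads()` the sum of counts (the library's clean-read total);
#'   `tagBounds()` the length bounds.
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))
#' @rdname tagSequences
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))
#' @rdname tagSequences
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))
#' @rdname tagSequences
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname tagSequences
#' @export
setGeneric("tagBounds", function(x) standardGeneric("tagBounds"))

#' @rdname tagSequences
#' @export
setMethod("tagSequences", "TagLibrary", function(x) x@tags$sequence)
#' @rdname tagSequences
#' @export
setMethod("tagCounts", "TagLibrary", function(x) {
  stats::setNames(x@tags$count, x@tags$sequence)
})
#' @rdname tagSequences
#' @export
setMethod("libraryName", "TagLibrary", function(x) x@libraryName)
#' @rdname tagSequences
#' @export
setMethod("totalReads", "TagLibrary", function(x) sum(x@tags$count))
#' @rdname tagSequences
#' @export
setMethod("tagBounds", "TagLibrary", function(x) x@bounds)

setMethod("show", "TagLibrary", function(object) {
  cat(sprintf("TagLibrary '%s': %d unique tags, %s reads, %d-%d nt\n",
              object@libraryName, nrow(object@tags),
              format(sum(object@tags$count), big.mark = ","),
              object@bounds[1], object@bounds[2]))
})

#' Accessors for folds and precursor candidates
#'
#' @param x a [HairpinFold-class] or [PrecursorCandidate-class].
#' @return `mfe()` the structure energy; `dotBracket()` the structure string;
#'   `foldSequence()` the folded sequence; `amfe()`, `mfei()`, `gcPercent()`
#'   the precursor statistics; `matureInterval()` / `starInterval()` the
#'   1-based closed intervals in window coordinates (star may be `integer(0)`).
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))
#' @rdname mfe
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname mfe
#' @export
setGeneric("foldSequence", function(x) standardGeneric("foldSequence"))
#' @rdname mfe
#' @export
setGeneric("amfe", function(x) standardGeneric("amfe"))
#' @rdname mfe
#' @export
setGeneric("mfei", function(x) standardGeneric("mfei"))
#' @rdname mfe
#' @export
setGeneric("gcPercent", function(x) standardGeneric("gcPercent"))
#' @rdname mfe
#' @export
setGeneric("matureInterval", function(x) standardGeneric("matureInterval"))
#' @rdname mfe
#' @export
setGeneric("starInterval", function(x) standardGeneric("starInterval"))

#' @rdname mfe
#' @export
setMethod("mfe", "HairpinFold", function(x) x@mfe)
#' @rdname mfe
#' @export
setMethod("dotBracket", "HairpinFold", function(x) x@structure)
#' @rdname mfe
#' @export
setMethod("foldSequence", "HairpinFold", function(x) x@sequence)

#' @rdname mfe
#' @export
setMethod("mfe", "PrecursorCandidate", function(x) x@fold@mfe)
#' @rdname mfe
#' @export
setMethod("dotBracket", "PrecursorCandidate", function(x) x@fold@structure)
#' @rdname mfe
#' @export
setMethod("foldSequence", "PrecursorCandidate", function(x) x@fold@sequence)
#' @rdname mfe
#' @export
setMethod("amfe", "PrecursorCandidate", function(x) x@amfe)
#' @rdname mfe
#' @export
setMethod("mfei", "PrecursorCandidate", function(x) x@mfei)
#' @rdname mfe
#' @export
setMethod("gcPercent", "PrecursorCandidate", function(x) x@gcPercent)
#' @rdname mfe
#' @export
setMethod("matureInterval", "PrecursorCandidate", function(x) x@mature)
#' @rdname mfe
#' @export
setMethod("starInterval", "PrecursorCandidate", function(x) x@star)

setMethod("show", "HairpinFold", function(object) {
  cat(object@sequence, "\n", object@structure,
      sprintf(" (%.1f)\n", object@mfe), sep = "")
})

setMethod("show", "PrecursorCandidate", function(object) {
  cat(sprintf("PrecursorCandidate on %s [%d-%d], mature [%d-%d]%s\n",
              object@sourceId, object@window[1], object@window[2],
              object@mature[1], object@mature[2],
              if (length(object@star) == 2L)
                sprintf(", star [%d-%d]", object@star[1], object@star[2])
              else ", star absent"))
  cat(sprintf("  MFE %.1f, AMFE %.2f, MFEI %s, GC %.1f%%\n", object@fold@mfe,
              object@amfe,
              if (is.na(object@mfei)) "NA" else sprintf("%.3f", object@mfei),
              object@gcPercent))
})

#' Accessors for miRNA calls
#'
#' @param x a [MiRNACall-class].
#' @return `matureSequence()` the mature sequence; `callKind()` conserved or
#'   novel; `familyOf()` the family label (`NA` for novel calls);
#'   `callCounts()` per-library read counts; `precursorOf()` the retained
#'   precursor candidate; `starSupported()` the star-evidence flag.
#' @export
setGeneric("matureSequence", function(x) standardGeneric("matureSequence"))
#' @rdname matureSequence
#' @export
setGeneric("callKind", function(x) standardGeneric("callKind"))
#' @rdname matureSequence
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))
#' @rdname matureSequence
#' @export
setGeneric("callCounts", function(x) standardGeneric("callCounts"))
#' @rdname matureSequence
#' @export
setGeneric("precursorOf", function(x) standardGeneric("precursorOf"))
#' @rdname matureSequence
#' @export
setGeneric("starSupported", function(x) standardGeneric("starSupported"))

#' @rdname matureSequence
#' @export
setMethod("matureSequence", "MiRNACall", function(x) x@mature)
#' @rdname matureSequence
#' @export
setMethod("callKind", "MiRNACall", function(x) x@kind)
#' @rdname matureSequence
#' @export
setMethod("familyOf", "MiRNACall", function(x) x@family)
#' @rdname matureSequence
#' @export
setMethod("callCounts", "MiRNACall", function(x) x@counts)
#' @rdname matureSequence
#' @export
setMethod("precursorOf", "MiRNACall", function(x) x@precursor)
#' @rdname matureSequence
#' @export
setMethod("starSupported", "MiRNACall", function(x) x@starSupported)

setMethod("show", "MiRNACall", function(object) {
  cat(sprintf("MiRNACall (%s%s): %s (%d nt) on %s%s\n", object@kind,
              if (!is.na(object@family)) paste0(", ", object@family) else "",
              object@mature, nchar(object@mature),
              object@precursor@sourceId,
              if (isTRUE(object@starSupported)) ", star-supported" else ""))
})

#' @rdname DegradomeProfile-class
#' @param x,object a `DegradomeProfile`
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname DegradomeProfile-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))
#' @rdname DegradomeProfile-class
#' @export
setMethod("profilePositions", "DegradomeProfile", function(x) x@positions)
#' @rdname DegradomeProfile-class
#' @export
setMethod("profileCounts", "DegradomeProfile", function(x) {
  stats::setNames(x@counts, x@positions)
})

setMethod("show", "DegradomeProfile", function(object) {
  cat(sprintf("DegradomeProfile %s: %d expressed positions, %.1f tags\n",
              object@transcriptId, length(object@positions),
              sum(object@counts)))
})

setMethod("show", "GroundTruthManifest", function(object) {
  k <- table(object@mirnas$kind)
  cat(sprintf(
    "GroundTruthManifest (seed %d): %s planted miRNAs (%s), %d contaminants, %d target sites\n",
    object@seed, nrow(object@mirnas),
    paste(sprintf("%d %s", as.integer(k), names(k)), collapse = ", "),
    nrow(object@contaminants), nrow(object@targets)))
})
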