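# File-format surface. FASTA/FASTQ parsing is delegated to Biostrings; these
# wrappers fix the conventions the pipeline expects (RNA alphabet, header
# layouts, tag FASTA naming).

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path file path; format is inferred from the extension unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"` (Phred+33; qualities are
#'   not used).
#' @return named character vector of reads (raw alphabet; normalisation to
#'   RNA happens in [trimAndFilter()]).
#' @export
readSmallRNA <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readBStringSet(path, format = format)
  stats::setNames(as.character(x), names(x))
}

#' Read a class-labelled ncRNA annotation FASTA
#'
#' Headers carry the class after the last `|`, e.g. `>rrna_1|rRNA`; classes
#' must be one of rRNA, tRNA, snRNA, snoRNA.
#'
#' @param path FASTA path.
#' @return an [AnnotationSet-class].
#' @export
readAnnotationFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  cls <- sub("^.*\\|", "", hdr)
  id <- sub("\\|[^|]*$", "", hdr)
  annotationSet(id, cls, as.character(x))
}

#' Construct an AnnotationSet from vectors
#'
#' @param id,class,sequence parallel vectors; `class` drawn from rRNA, tRNA,
#'   snRNA, snoRNA.
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(id, class, sequence) {
  new("AnnotationSet",
      records = data.frame(id = id, class = class,
                           sequence = normalizeRna(sequence),
                           stringsAsFactors = FALSE))
}

#' Read a known mature miRNA set (miRBase-style headers)
#'
#' Headers are parsed as `species-miR{family}{letter}` (e.g. `osa-miR156a`);
#' the family is the `MIR` number, the species the prefix before the first
#' dash.
#'
#' @param path FASTA path.
#' @return a known-mature `data.frame`; see [knownMatureSet()].
#' @export
readKnownMatures <- function(path) {
  x <- Biostrings::readBStringSet(path)
  knownMatureSet(names(x), as.character(x))
}

#' Construct a known mature miRNA set
#'
#' @param name entry names in the `species-miR{family}{letter}` convention;
#'   must be unique.
#' @param sequence mature sequences (T normalised to U).
#' @return `data.frame` with columns `name`, `species`, `family` (e.g.
#'   `"MIR156"`), `familyNumber` and `sequence`.
#' @export
#' @examples
#' knownMatureSet("osa-miR156a", "ugacagaagagagugagcac")
knownMatureSet <- function(name, sequence) {
  assertThat(!anyDuplicated(name), "known mature names must be unique")
  num <- regmatches(name, regexpr("(?i)mir[-]?([0-9]+)", name, perl = TRUE))
  assertThat(length(num) == length(name) && all(nzchar(num)),
             "cannot parse a MIR number from every name")
  fam <- as.integer(sub("(?i)mir[-]?", "", num, perl = TRUE))
  data.frame(name = name,
             species = sub("-.*$", "", name),
             family = paste0("MIR", fam),
             familyNumber = fam,
             sequence = normalizeRna(sequence),
             stringsAsFactors = FALSE)
}

#' Read a transcript reference FASTA
#'
#' @param path FASTA path.
#' @return named character vector of transcript sequences, normalised to the
#'   RNA alphabet.
#' @export
readTranscripts <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(normalizeRna(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a tag library as FASTA
#'
#' Headers follow the `tag{serial}_x{count}` convention.
#'
#' @param tags a [TagLibrary-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTagsFasta <- function(tags, path) {
  stopifnot(is(tags, "TagLibrary"))
  x <- Biostrings::RNAStringSet(tags@tags$sequence)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags@tags)), tags@tags$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads named character vector (RNA or DNA alphabet; written as-is).
#' @param path output path.
#' @param quality single quality character applied to every base (Phred+33).
#' @return the path, invisibly.
#' @export
writeFastq <- function(reads, path, quality = "I") {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      strrep(quality, n), character(1))), con)
  invisible(path)
}

#' Read a Ct table from TSV
#'
#' Expected columns: `assay`, `tissue`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return `data.frame` suitable for [relativeExpression()].
#' @export
readCtTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assertThat(all(c("assay", "tissue", "replicate", "ct") %in% names(df)),
             "Ct table needs columns assay, tissue, replicate, ct")
  df
}
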