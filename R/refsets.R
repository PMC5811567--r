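# Bundled reference catalogues: the conserved and novel mature miRNA sets
# reported for Lilium lancifolium (flower/leaf/bulblet/bulb libraries) and
# the published degradome cleavage-site category tallies, shipped as
# plain-text fixtures for worked examples and cross-checks.

#' Published L. lancifolium conserved miRNA catalogue
#'
#' The 25 distinct conserved mature sequences with their family labels
#' (17 families, e.g. MIR156-MIR2118).
#'
#' @return `data.frame`: family, name, sequence.
#' @export
#' @examples
#' nrow(llConservedMirnas())  # 25
llConservedMirnas <- function() {
  utils::read.delim(system.file("extdata", "ll_conserved_mirnas.tsv",
                                package = "bulbmiR", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published L. lancifolium novel miRNA catalogue
#'
#' The 44 novel mature sequences (LL-miR01..LL-miR44).
#'
#' @return `data.frame`: name, sequence.
#' @export
#' @examples
#' range(nchar(llNovelMirnas()$sequence))  # 20 24
llNovelMirnas <- function() {
  utils::read.delim(system.file("extdata", "ll_novel_mirnas.tsv",
                                package = "bulbmiR", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published degradome cleavage-site category tallies
#'
#' The number of cleavage sites reported per category 0-4 for the
#' L. lancifolium degradome library.
#'
#' @return `data.frame`: category, sites.
#' @export
#' @examples
#' sum(llDegradomeCategories()$sites)  # 53
llDegradomeCategories <- function() {
  utils::read.delim(system.file("extdata", "ll_degradome_categories.tsv",
                                package = "bulbmiR", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
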