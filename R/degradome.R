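# Degradome (PARE) analysis: per-transcript 5'-end profiles, cleavage-site
# calling opposite miRNA positions 10-11, five-category classification,
# T-plot tables.

#' Build degradome 5'-end profiles
#'
#' Each exact occurrence of a tag adds its count at the occurrence's 5'
#' position; tags matching multiple places have their counts split equally
#' over all occurrences (fractional counts allowed). Tags matching nowhere
#' are tallied as unmapped.
#'
#' @param tags a [TagLibrary-class] of degradome tags (~20 nt).
#' @param transcripts named character vector.
#' @return list with `profiles` (named list of [DegradomeProfile-class]) and
#'   `unmapped` (read count). Conservation: summed profile counts plus
#'   unmapped equal the input tag count total.
#' @export
buildProfile <- function(tags, transcripts) {
  stopifnot(is(tags, "TagLibrary"))
  transcripts <- normalizeRna(transcripts)
  acc <- lapply(transcripts, function(x) numeric(0))  # named vectors pos->count
  unmapped <- 0
  for (i in seq_len(length(tags))) {
    tg <- tags@tags$sequence[i]
    cnt <- tags@tags$count[i]
    occ <- list()
    for (tx in names(transcripts)) {
      hits <- gregexpr(tg, transcripts[[tx]], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (s in as.integer(hits)) occ[[length(occ) + 1L]] <- c(tx, s)
    }
    if (!length(occ)) { unmapped <- unmapped + cnt; next }
    share <- cnt / length(occ)
    for (o in occ) {
      tx <- o[1]; pos <- o[2]
      cur <- acc[[tx]]
      cur[pos] <- (if (pos %in% names(cur)) cur[[pos]] else 0) + share
      acc[[tx]] <- cur
    }
  }
  profiles <- list()
  for (tx in names(acc)) {
    if (!length(acc[[tx]])) next
    pos <- as.integer(names(acc[[tx]]))
    o <- order(pos)
    profiles[[tx]] <- new("DegradomeProfile", transcriptId = tx,
                          positions = pos[o],
                          counts = unname(acc[[tx]])[o])
  }
  list(profiles = profiles, unmapped = unmapped)
}

#' Classify a degradome position into categories 0-4
#'
#' With `c` the count at the position, `M` the transcript maximum and `med`
#' the median over expressed (count > 0) positions: category 4 when
#' `c <= 1`; else 0 when `c` equals a uniquely attained maximum; 1 when `c`
#' equals a maximum attained at more than one position; 2 when
#' `med < c < M`; 3 when `1 < c <= med`. Exactly one clause holds for every
#' expressed position.
#'
#' @param profile a [DegradomeProfile-class] with at least one expressed
#'   position.
#' @param position 1-based transcript coordinate; must have count > 0.
#' @return integer category 0-4.
#' @export
categorizeSite <- function(profile, position) {
  stopifnot(is(profile, "DegradomeProfile"))
  assertThat(length(profile@positions) > 0L, "profile has no expressed positions")
  idx <- match(position, profile@positions)
  if (is.na(idx) || profile@counts[idx] <= 0) stop("not a site")
  c0 <- profile@counts[idx]
  M <- max(profile@counts)
  med <- stats::median(profile@counts)
  if (c0 <= 1) return(4L)
  if (c0 == M) {
    if (sum(profile@counts == M) == 1L) return(0L)
    return(1L)
  }
  if (c0 > med) return(2L)  # med < c < M
  3L                        # 1 < c <= med
}

#' Call cleavage sites from target alignments and degradome profiles
#'
#' For each alignment the expected cleavage position is the target nucleotide
#' paired to miRNA position 10 (slicing between positions 10 and 11). A site
#' is called when the profile carries at least `minCount` tags within
#' `window` nt of the expected position; the maximal position in the window
#' is reported, with its category.
#'
#' @param alignments `data.frame` from [scanTargets()] (columns mirna,
#'   transcript, cut, penalty, ...).
#' @param profiles named list of [DegradomeProfile-class] from
#'   [buildProfile()].
#' @param minCount minimum site count (default 1; category 4 permitted).
#' @param window search half-width around the expected position (default 1).
#' @return `data.frame`: mirna, transcript, position, count, category,
#'   penalty. Alignments on transcripts without a profile are skipped.
#' @export
callCleavageSites <- function(alignments, profiles, minCount = 1, window = 1L) {
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    if (is.na(al$cut)) next
    prof <- profiles[[al$transcript]]
    if (is.null(prof)) next
    inWin <- which(abs(prof@positions - al$cut) <= window)
    if (!length(inWin)) next
    j <- inWin[which.max(prof@counts[inWin])]
    if (prof@counts[j] < minCount) next
    out[[length(out) + 1L]] <- data.frame(
      mirna = al$mirna, transcript = al$transcript,
      position = prof@positions[j], count = prof@counts[j],
      category = categorizeSite(prof, prof@positions[j]),
      penalty = al$penalty, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna = character(0), transcript = character(0),
                      position = integer(0), count = numeric(0),
                      category = integer(0), penalty = numeric(0)))
  df <- unique(do.call(rbind, out))
  rownames(df) <- NULL
  df
}

#' Per-position T-plot table for one transcript
#'
#' @param profile a [DegradomeProfile-class].
#' @param sites optional `data.frame` from [callCleavageSites()] (rows for
#'   other transcripts are ignored).
#' @return `data.frame`: position, count, is_site, category (NA when not a
#'   called site); one row per expressed position, ready for plotting.
#' @export
tplotTable <- function(profile, sites = NULL) {
  stopifnot(is(profile, "DegradomeProfile"))
  np <- length(profile@positions)
  df <- data.frame(position = profile@positions, count = profile@counts,
                   is_site = logical(np), category = rep(NA_integer_, np))
  if (!is.null(sites) && nrow(sites)) {
    sites <- sites[sites$transcript == profile@transcriptId, , drop = FALSE]
    hit <- match(sites$position, df$position)
    df$is_site[hit[!is.na(hit)]] <- TRUE
    df$category[hit[!is.na(hit)]] <- sites$category[!is.na(hit)]
  }
  df
}
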