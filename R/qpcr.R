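# Stem-loop qPCR relative quantification (2^-ddCt) and miRNA/target
# anti-correlation across tissues.

#' Relative expression by the 2^-ddCt method
#'
#' Per tissue, `dCt = mean Ct(assay) - mean Ct(reference)`; then
#' `ddCt = dCt(tissue) - dCt(calibrator)` and the relative level is
#' `2^-ddCt`, so the calibrator tissue maps to level 1 by construction.
#' Dispersion is propagated from the replicate standard deviations
#' (`sd_ddct = sqrt(sd_assay^2/n_a + sd_ref^2/n_r)`), reported as a fold
#' range `2^-(ddCt +/- sd)`.
#'
#' @param ct `data.frame` with columns `assay`, `tissue`, `replicate`, `ct`
#'   (cycles, > 0; at least one replicate per assay/tissue; the reference
#'   assay present in every tissue).
#' @param referenceAssay the normaliser assay (e.g. `"5.8S"`).
#' @param calibratorTissue the tissue whose level defines 1.
#' @return `data.frame`: assay, tissue, n, dct, ddct, level, level_low,
#'   level_high (reference assay rows omitted).
#' @export
#' @examples
#' ct <- data.frame(assay = rep(c("m1", "5.8S"), each = 2),
#'                  tissue = rep("flower", 4), replicate = c(1, 2, 1, 2),
#'                  ct = c(25.1, 24.9, 20.0, 20.2))
#' relativeExpression(ct, "5.8S", "flower")
relativeExpression <- function(ct, referenceAssay, calibratorTissue) {
  assertThat(all(c("assay", "tissue", "replicate", "ct") %in% names(ct)),
             "Ct table needs columns assay, tissue, replicate, ct")
  assertThat(all(ct$ct > 0), "all Ct values must be positive")
  tissues <- unique(ct$tissue)
  assertThat(calibratorTissue %in% tissues,
             sprintf("calibrator tissue '%s' not present", calibratorTissue))
  for (ts in tissues) {
    if (!any(ct$assay == referenceAssay & ct$tissue == ts))
      stop(sprintf("reference assay '%s' missing in tissue '%s'",
                   referenceAssay, ts))
  }
  agg <- function(assay, tissue) {
    v <- ct$ct[ct$assay == assay & ct$tissue == tissue]
    list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  assays <- setdiff(unique(ct$assay), referenceAssay)
  rows <- list()
  for (a in assays) {
    atis <- intersect(tissues, unique(ct$tissue[ct$assay == a]))
    if (!calibratorTissue %in% atis) next
    dct <- vapply(atis, function(ts) {
      agg(a, ts)$mean - agg(referenceAssay, ts)$mean
    }, numeric(1))
    sdd <- vapply(atis, function(ts) {
      x <- agg(a, ts); r <- agg(referenceAssay, ts)
      sqrt((ifelse(is.na(x$sd), 0, x$sd))^2 / x$n +
           (ifelse(is.na(r$sd), 0, r$sd))^2 / r$n)
    }, numeric(1))
    ddct <- dct - dct[[calibratorTissue]]
    rows[[length(rows) + 1L]] <- data.frame(
      assay = a, tissue = atis,
      n = vapply(atis, function(ts) agg(a, ts)$n, integer(1)),
      dct = unname(dct), ddct = unname(ddct), level = 2^-unname(ddct),
      level_low = 2^-(unname(ddct) + sdd),
      level_high = 2^-(unname(ddct) - sdd),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test for opposite miRNA/target expression patterns
#'
#' Spearman rank correlation of relative levels across shared tissues; the
#' pair is flagged "opposite" when the correlation is negative.
#'
#' @param mirnaLevels,targetLevels named numeric vectors of per-tissue levels
#'   (at least 3 shared tissues).
#' @return list with `rho` (NA for a constant vector) and `opposite`
#'   (logical; `NA` when the correlation is undefined).
#' @export
#' @examples
#' oppositePattern(c(f = 1, l = 2, b = 3, bb = 4),
#'                 c(f = 4, l = 3, b = 2, bb = 1))
oppositePattern <- function(mirnaLevels, targetLevels) {
  shared <- intersect(names(mirnaLevels), names(targetLevels))
  assertThat(length(shared) >= 3L, "need at least 3 shared tissues")
  x <- mirnaLevels[shared]; y <- targetLevels[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, opposite = NA))
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, opposite = rho < 0)
}
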