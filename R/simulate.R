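# Ground-truthed synthetic data: transcripts carrying planted hairpin
# precursors, tissue-specific read stacks with 3' adapters, ncRNA
# contaminants, and degradome tags with controlled cleavage-position
# abundance classes. Everything planted is recorded in a
# GroundTruthManifest so recovery can be scored exactly.

.randSeq <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                              collapse = "")

#' Build a synthetic hairpin precursor around a mature sequence
#'
#' The precursor is mature arm + loop + star arm (+ a 2-nt tail), the star
#' being the reverse complement of the mature with `starMismatches`
#' substitutions at duplex-internal positions, arranged so the duplex carries
#' the canonical 2-nt 3' overhangs. With `starMismatches <= 3` the construct
#' passes [validateStemloop()] under the default folder; larger values are
#' flagged as negative-control material.
#'
#' @param mature mature sequence, 20-24 nt.
#' @param loopLen terminal loop length, >= 4 nt.
#' @param starMismatches substitutions introduced into the star arm.
#' @return list: `sequence`, `mature` and `star` (1-based closed intervals in
#'   precursor coordinates), `loopLen`, `starMismatches`, `mayNotValidate`.
#' @export
makeHairpin <- function(mature, loopLen = 8L, starMismatches = 0L) {
  mature <- normalizeRna(mature)
  m <- nchar(mature)
  assertThat(m >= 20L && m <= 24L, "mature length must be 20-24 nt")
  assertThat(loopLen >= 4L, "loop length below folder minimum")
  mch <- strsplit(mature, "", fixed = TRUE)[[1]]
  star <- strsplit(rnaRevComp(mature), "", fixed = TRUE)[[1]]
  if (starMismatches > 0L) {
    k <- sample(3:(m - 2L), starMismatches)
    for (i in k) {
      partner <- mch[m + 1L - i]
      ok <- RNA_BASES[vapply(RNA_BASES, function(b)
        pairClass1(partner, b) == 0L, logical(1))]
      star[i] <- sample(ok, 1L)
    }
  }
  seq <- paste0(mature, .randSeq(loopLen), paste(star, collapse = ""),
                .randSeq(2L))
  list(sequence = seq, mature = c(1L, m),
       star = c(m + loopLen + 3L, 2L * m + loopLen + 2L),
       loopLen = as.integer(loopLen),
       starMismatches = as.integer(starMismatches),
       mayNotValidate = starMismatches > 3L)
}

# random mature: length nt, biased to a 5' U like real plant miRNAs
.randMature <- function(len, forceU = TRUE) {
  first <- if (forceU) "U" else sample(RNA_BASES, 1L)
  paste0(first, .randSeq(len - 1L))
}

# substitute exactly d positions
.mutate <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in sample(seq_along(ch), d))
    ch[i] <- sample(setdiff(RNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# low-structure spacer: A/C only, cannot pair internally
.acSpacer <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                               collapse = "")

#' The bundled miniature ncRNA contaminant set
#'
#' A small synthetic FASTA of rRNA/tRNA/snRNA/snoRNA-labelled records (not a
#' database extract) used as the contaminant reference in simulations and
#' examples.
#'
#' @return an [AnnotationSet-class].
#' @export
syntheticNcrnaSet <- function() {
  readAnnotationFasta(system.file("extdata", "synthetic_ncrna.fa",
                                  package = "bulbmiR", mustWork = TRUE))
}

#' Simulate a complete small-RNA study with ground truth
#'
#' Generates transcripts with planted conserved and novel miRNA hairpins,
#' decoy tags in hairpin-free (unstructured) contexts, a matching known
#' mature set (each planted conserved miRNA at 0-2 mismatches from exactly
#' one known family), per-tissue read libraries with 3' adapters, ncRNA
#' contaminant reads, no-adapter/ambiguous-residue rejects, planted target
#' sites, and degradome tags realising each cleavage-site category.
#'
#' Per-tissue miRNA abundances are log-normal (heavy-tailed, as observed
#' small-RNA counts are); planted novel miRNAs are guaranteed >= 5 total
#' reads so the novel-recovery contract is well-defined.
#'
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param nConserved,nNovel,nDecoys numbers of planted items.
#' @param tissues library names.
#' @param adapter 3' adapter appended to every sequenced read.
#' @param jitterRate fraction of reads trimmed by 1 nt at the 5' or 3' end.
#' @param noiseReads unmappable random reads added per tissue.
#' @param transcriptLength range of background transcript lengths.
#' @param loopLen hairpin terminal loop length.
#' @param countMeanLog,countSdLog log-normal abundance parameters.
#' @return list with `transcripts`, `knownSet`, `annotation`, `libraries`
#'   (named list of read vectors, adapters attached), `degradomeReads`,
#'   `manifest` (a [GroundTruthManifest-class]), `adapter`, `tissues`.
#' @export
simulateStudy <- function(seed, nConserved = 20L, nNovel = 15L, nDecoys = 6L,
                          tissues = c("flower", "leaf", "bulblet", "bulb"),
                          adapter = "UGGAAUUCUCGGGUGCCAAGG",
                          jitterRate = 0.1, noiseReads = 30L,
                          transcriptLength = c(400L, 700L), loopLen = 8L,
                          countMeanLog = log(15), countSdLog = 0.7) {
  seed <- as.integer(seed)
  set.seed(seed)
  adapter <- normalizeRna(adapter)
  annotation <- syntheticNcrnaSet()

  # --- planted matures and the known set -----------------------------------
  conserved <- character(nConserved)
  known <- character(nConserved)
  for (i in seq_len(nConserved)) {
    repeat {
      mt <- .randMature(21L)
      kn <- .mutate(mt, sample(0:2, 1L))
      ok <- TRUE
      if (i > 1L) {
        ok <- all(vapply(known[seq_len(i - 1L)], function(k)
          mismatchCount(mt, k) > 2, logical(1))) &&
          all(vapply(conserved[seq_len(i - 1L)], function(k)
            mismatchCount(kn, k) > 2, logical(1)))
      }
      if (ok) { conserved[i] <- mt; known[i] <- kn; break }
    }
  }
  knownSet <- knownMatureSet(sprintf("syn-miR%da", 100L + seq_len(nConserved)),
                             known)
  novel <- character(nNovel)
  for (i in seq_len(nNovel)) {
    repeat {
      mt <- .randMature(sample(20:24, 1L), forceU = stats::runif(1) < 0.8)
      if (all(vapply(knownSet$sequence, function(k)
        mismatchCount(mt, k) > 2, logical(1)))) { novel[i] <- mt; break }
    }
  }
  # decoys: near-known tags in hairpin-free context, and far-from-known noise
  nDecoyA <- ceiling(nDecoys / 2)
  decoys <- c(vapply(seq_len(nDecoyA), function(i)
    .mutate(knownSet$sequence[i], 1L), character(1)),
    vapply(seq_len(nDecoys - nDecoyA), function(i) {
      repeat {
        d <- .randMature(21L)
        if (all(vapply(knownSet$sequence, function(k)
          mismatchCount(d, k) > 2, logical(1)))) return(d)
      }
    }, character(1)))

  # --- transcriptome -------------------------------------------------------
  txLen <- function() sample(transcriptLength[1]:transcriptLength[2], 1L)
  transcripts <- character(0)
  mirRows <- list()
  planted <- c(conserved, novel)
  kinds <- c(rep("conserved", nConserved), rep("novel", nNovel))
  fams <- c(knownSet$family, rep(NA_character_, nNovel))
  hairpins <- vector("list", length(planted))
  for (i in seq_along(planted)) {
    hp <- makeHairpin(planted[i], loopLen = loopLen,
                      starMismatches = sample(0:1, 1L))
    hairpins[[i]] <- hp
    L <- txLen()
    off <- sample(20:(L - nchar(hp$sequence) - 20L), 1L)
    tx <- paste0(.randSeq(off - 1L), hp$sequence,
                 .randSeq(L - off + 1L - nchar(hp$sequence)))
    nm <- sprintf("tx_%s%02d", ifelse(kinds[i] == "conserved", "c", "n"),
                  i)
    transcripts[nm] <- tx
    mirRows[[i]] <- data.frame(
      name = sprintf("%s%02d", ifelse(kinds[i] == "conserved", "cons", "nov"),
                     i),
      kind = kinds[i], family = fams[i], mature = planted[i],
      transcript = nm, start = off, end = off + nchar(planted[i]) - 1L,
      star_start = off + hp$star[1] - 1L, star_end = off + hp$star[2] - 1L,
      stringsAsFactors = FALSE)
  }
  for (j in seq_along(decoys)) {
    # decoys are hairpin-free by construction: reject any context in which
    # an excised window around the tag would pass stem-loop validation
    repeat {
      L <- txLen()
      core <- paste0(.acSpacer(60L), decoys[j], .acSpacer(60L))
      off <- sample(20:(L - nchar(core) - 20L), 1L)
      tx <- paste0(.randSeq(off - 1L), core,
                   .randSeq(L - off + 1L - nchar(core)))
      cands <- locateAndExcise(decoys[j], c(tmp = tx), flank = 250L)
      if (!any(vapply(cands, function(cc) validateStemloop(cc)$accept,
                      logical(1)))) break
    }
    nm <- sprintf("tx_d%02d", j)
    transcripts[nm] <- tx
    mirRows[[length(mirRows) + 1L]] <- data.frame(
      name = sprintf("decoy%02d", j), kind = "decoy", family = NA_character_,
      mature = decoys[j], transcript = nm, start = off + 60L,
      end = off + 60L + nchar(decoys[j]) - 1L,
      star_start = NA_integer_, star_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  mirnas <- do.call(rbind, mirRows)

  # target-site transcripts: one per chosen miRNA, cycled over categories 0-4
  targetMirs <- c(utils::head(seq_len(nConserved), 5L),
                  nConserved + utils::head(seq_len(nNovel), 5L))
  tgRows <- list()
  for (k in seq_along(targetMirs)) {
    i <- targetMirs[k]
    site <- rnaRevComp(planted[i])
    L <- max(300L, txLen())
    off <- sample(60:(L - nchar(site) - 60L), 1L)
    tx <- paste0(.randSeq(off - 1L), site,
                 .randSeq(L - off + 1L - nchar(site)))
    nm <- sprintf("tx_t%02d", k)
    transcripts[nm] <- tx
    e <- off + nchar(site) - 1L
    tgRows[[k]] <- data.frame(
      mirna = mirnas$name[i], mature = planted[i], transcript = nm,
      start = off, end = e, cut = e - 9L,
      intended_category = (k - 1L) %% 5L, site_count = NA_real_,
      stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, tgRows)
  # a little featureless background
  for (b in 1:4) transcripts[sprintf("tx_bg%02d", b)] <- .randSeq(txLen())

  # reject accidental duplicate plantings of any mature elsewhere
  for (i in seq_along(planted)) {
    occ <- sum(vapply(transcripts, function(tx)
      length(gregexpr(planted[i], tx, fixed = TRUE)[[1]]) *
        (gregexpr(planted[i], tx, fixed = TRUE)[[1]][1] != -1L), integer(1)))
    assertThat(occ == 1L, "planted mature duplicated by background; reseed")
  }

  # --- per-tissue abundances and reads -------------------------------------
  drawCount <- function() max(1L, as.integer(round(
    stats::rlnorm(1, countMeanLog, countSdLog))))
  counts <- matrix(0L, nrow = nrow(mirnas), ncol = length(tissues),
                   dimnames = list(mirnas$name, tissues))
  starCounts <- counts
  for (i in seq_len(nrow(mirnas))) {
    expressed <- stats::runif(length(tissues)) < 0.75
    if (!any(expressed)) expressed[sample(length(tissues), 1L)] <- TRUE
    counts[i, expressed] <- vapply(which(expressed), function(j) drawCount(),
                                   integer(1))
    if (mirnas$kind[i] == "novel" && sum(counts[i, ]) < 5L)
      counts[i, which.max(counts[i, ])] <-
        counts[i, which.max(counts[i, ])] + 5L
    if (mirnas$kind[i] != "decoy" && stats::runif(1) < 0.6)
      starCounts[i, sample(length(tissues), 1L)] <- sample(1:4, 1L)
  }

  contam <- annotation@records
  contamRows <- list()
  libraries <- stats::setNames(vector("list", length(tissues)), tissues)
  for (ts in seq_along(tissues)) {
    reads <- character(0)
    for (i in seq_len(nrow(mirnas))) {
      n <- counts[i, ts]
      if (n > 0L) {
        tx <- transcripts[[mirnas$transcript[i]]]
        s <- mirnas$start[i]; e <- mirnas$end[i]
        full <- substr(tx, s, e)
        rds <- rep(full, n)
        jit <- stats::runif(n) < jitterRate
        if (any(jit)) {
          rds[jit] <- vapply(which(jit), function(r) {
            if (stats::runif(1) < 0.5) substr(tx, s + 1L, e)
            else substr(tx, s, e - 1L)
          }, character(1))
        }
        reads <- c(reads, rds)
      }
      ns <- starCounts[i, ts]
      if (ns > 0L && !is.na(mirnas$star_start[i])) {
        tx <- transcripts[[mirnas$transcript[i]]]
        reads <- c(reads, rep(substr(tx, mirnas$star_start[i],
                                     mirnas$star_end[i]), ns))
      }
    }
    # ncRNA contaminant fragments
    for (r in seq_len(nrow(contam))) {
      n <- max(0L, round(stats::rlnorm(1, log(8), 0.6)))
      if (n == 0L) next
      rl <- sample(18:28, 1L)
      rs <- sample(seq_len(nchar(contam$sequence[r]) - rl + 1L), 1L)
      frag <- substr(contam$sequence[r], rs, rs + rl - 1L)
      reads <- c(reads, rep(frag, n))
      contamRows[[length(contamRows) + 1L]] <- data.frame(
        sequence = frag, class = contam$class[r], tissue = tissues[ts],
        count = n, stringsAsFactors = FALSE)
    }
    # unmappable noise (kept by trimming, matching no transcript)
    reads <- c(reads, vapply(seq_len(noiseReads), function(x)
      .randSeq(sample(18:28, 1L)), character(1)))
    reads <- paste0(reads, adapter)
    # adapterless and ambiguous-residue rejects
    reads <- c(reads, vapply(1:5, function(x) .randSeq(30L), character(1)),
               paste0(.randSeq(10L), "N", .randSeq(10L), adapter))
    reads <- sample(reads)  # shuffle
    names(reads) <- sprintf("%s_read%05d", tissues[ts], seq_along(reads))
    libraries[[tissues[ts]]] <- reads
  }
  contaminants <- if (length(contamRows)) do.call(rbind, contamRows) else
    data.frame(sequence = character(0), class = character(0),
               tissue = character(0), count = integer(0))

  # --- degradome tags with controlled category scenarios -------------------
  scenario <- list(`0` = list(site = 8, bg = c(3, 2)),
                   `1` = list(site = 6, bg = c(6, 1)),
                   `2` = list(site = 4, bg = c(9, 1, 1)),
                   `3` = list(site = 2, bg = c(9, 3)),
                   `4` = list(site = 1, bg = c(5)))
  degReads <- character(0)
  for (k in seq_len(nrow(targets))) {
    tx <- transcripts[[targets$transcript[k]]]
    sc <- scenario[[as.character(targets$intended_category[k])]]
    P <- targets$cut[k]
    bgPos <- integer(0)
    while (length(bgPos) < length(sc$bg)) {
      p <- sample(21:(nchar(tx) - 21L), 1L)
      if (abs(p - P) >= 25L && (!length(bgPos) || min(abs(p - bgPos)) >= 3L))
        bgPos <- c(bgPos, p)
    }
    allPos <- c(P, bgPos)
    allCnt <- c(sc$site, sc$bg)
    for (q in seq_along(allPos))
      degReads <- c(degReads,
                    rep(substr(tx, allPos[q], allPos[q] + 19L), allCnt[q]))
    targets$site_count[k] <- sc$site
    # generator self-check: the planted profile must realise the intent
    prof <- new("DegradomeProfile", transcriptId = targets$transcript[k],
                positions = sort(allPos),
                counts = as.numeric(allCnt[order(allPos)]))
    assertThat(categorizeSite(prof, P) == targets$intended_category[k],
               "scenario failed to realise its intended category")
  }
  names(degReads) <- sprintf("deg_read%05d", seq_along(degReads))

  manifest <- new("GroundTruthManifest",
                  mirnas = cbind(mirnas, as.data.frame(counts)),
                  contaminants = contaminants, targets = targets,
                  seed = seed)
  list(transcripts = transcripts, knownSet = knownSet,
       annotation = annotation, libraries = libraries,
       degradomeReads = degReads, manifest = manifest, adapter = adapter,
       tissues = tissues)
}
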