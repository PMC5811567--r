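---
title: "bulbmiR: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bulbmiR: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulbmiR)
```

This vignette is the package's own account of the science it implements: the
models and rules at each pipeline stage, the tunable parameters and their
defaults, what the synthetic generator emulates (and does not), and the
choices made where the design was genuinely open.

## The discovery problem

For a species without a reference genome, miRNAs are discovered from
small-RNA libraries mapped against transcriptome assemblies. Reads are
trimmed and filtered to the 18–30 nt clean window, collapsed to unique tags,
and cleared of annotated structural ncRNAs. Conserved miRNAs are tags within
a small mismatch budget of known plant matures whose transcript context
folds into a valid stem-loop; novel miRNAs additionally need read-stack
evidence consistent with Dicer processing. Targets are scored by sequence
complementarity, and degradome (PARE) libraries — sequenced 5′ ends of
uncapped transcripts — provide physical evidence of miRNA-guided cleavage
opposite miRNA positions 10–11.

## Preprocessing rules

* Adapter: the leftmost full 3′-adapter occurrence is removed; a read whose
  adapter is only partially sequenced is trimmed when an adapter **prefix of
  at least 8 nt** terminates the read. Reads with no adapter evidence are
  discarded (the adapter is the proof that the full insert was sequenced).
  All discards are tallied by reason, and the tallies plus kept reads always
  sum to the input count.
* Length window: 18–30 nt by default (`minLen`, `maxLen`), the conventional
  clean-read definition for plant small RNAs.
* Ambiguous residues (N) discard the read; T is normalised to U so all
  internal sequences are RNA alphabet.
* ncRNA removal: a tag is removed when it aligns ungapped as a substring of
  any annotation record within a mismatch budget (default 0). Full-database
  screens use E-value cutoffs; at the miniature-reference scale bundled
  here, substring containment expresses the same contract — remove
  rRNA/tRNA/snRNA/snoRNA fragments — in an exactly testable form. Class
  ties break in the fixed order rRNA > tRNA > snRNA > snoRNA.

## The folding model

`foldMfe()` minimises a simplified loop-based energy over all nested
(pseudoknot-free) structures with Watson–Crick or G:U pairs and hairpin
loops of ≥ 3 nt:

| term | energy |
|---|---|
| stacked pair, by outer pair | GC/CG −3.0, AU/UA −2.0, GU/UG −1.0 |
| isolated pair (no stacking neighbour) | half the pair energy |
| hairpin loop | +4.0, +0.5 per unpaired nt beyond 3 |
| internal/bulge loop | +2.0, +0.3 per unpaired nt |
| multibranch loop | +2.0, +0.3 per unpaired loop nt |

The published thermodynamic folders (mfold/ViennaRNA) use full
nearest-neighbour tables; reproducing their numerical energies is explicitly
out of scope here, and quantities that depend on them (e.g. mean precursor
MFE in kcal/mol) are not comparable. What the model preserves is the
*ranking* behaviour the pipeline needs: stable stems beat open chains,
G:C-rich stems beat A:U stems, loops cost energy. Three design details are
worth stating:

* **Multibranch term.** The stack/hairpin/internal terms fix everything
  except multiloops; those are charged like internal loops (+2.0 and
  +0.3/nt), the simplest choice that keeps the decomposition additive.
* **Determinism.** All terms are multiples of 0.1, so the dynamic program
  runs in integer tenths and ties are exact. Ties are resolved toward the
  structure with more pairs, then by a fixed traceback order — outputs are
  bit-stable across platforms.
* **Search cap.** Internal/bulge loops are capped at 30 unpaired nt during
  the search (the standard Zuker-style cap). Sequences up to 28 nt cannot
  contain such loops, so the cap is invisible to the enumeration oracle the
  tests compare against.

`structureEnergy()` evaluates any given dot-bracket under the same model and
is the consistency oracle: every fold the pipeline produces satisfies
`mfe == structureEnergy(sequence, structure)`, enforced by the
`HairpinFold` class validity itself.

Precursor statistics follow the standard definitions: AMFE = (MFE/length) ×
100 and MFEI = AMFE/(G+C)% with GC on the 0–100 scale, the convention under
which plant pre-miRNAs typically score −0.5 to −1.5.

## Stem-loop validation and star geometry

`validateStemloop()` accepts a candidate when (a) the mature lies entirely
on one arm, (b) at most 8 mature nucleotides are unpaired
(`maxMatureUnpaired`), (c) the mature's pairing partners form a contiguous
opposite-arm block containing no foreign helix (bulges allowed), and (d) the
window folds below zero. Every violated clause is reported, so rejections
are auditable.

`starOf()` derives the star as the partner block shifted 2 nt toward the
mature's 5′-side partner — the canonical 2-nt 3′ overhang Dicer leaves on
each duplex strand; the overhang length is fixed at 2 because that geometry
is what defines a miRNA/miRNA* duplex. The star is absent when under 60% of
mature positions pair, or the partners fall inside the mature or on both
sides (a loop-straddling mature).

## Conserved and novel calling

Homology uses `mismatchCount()`: Hamming distance at equal lengths; for
unequal lengths the minimum over ungapped offsets of (overlap mismatches +
length difference), with at least 18 nt overlap. The budget is 2 mismatches.
Families come from the best hit (fewest mismatches, ties to the lower MIR
number): each known entry's family is parsed from its
`species-miR{number}{letter}` name.

Windows are excised at every exact transcript occurrence of a tag: the
symmetric tag ± 250 nt window plus the two asymmetric 250-nt windows
(downstream-only, upstream-only), so a hairpin is found whichever arm the
mature sits on; 250 nt comfortably covers plant precursors (up to several
hundred nt) while keeping folds fast. Among validated windows the
lowest-MFEI one is retained.

Novel calling is a rule-based stand-in for probabilistic tools: loci are
exact-match tag clusters (5′ starts within 30 nt merged) with total count ≥
3; the dominant tag must validate as a mature on an excised hairpin; and at
least 75% of locus reads must have 5′ ends within 2 nt of the dominant 5′
end or fall inside the star/loop span (`readConsistency`). Identical matures
across loci are deduplicated to the lowest-MFEI precursor, with the other
loci recorded (`keepDuplicates = TRUE` restores per-locus accounting, the
bookkeeping some published catalogues use). Novel calls are disjoint from
the conserved set by construction: a dominant tag within 2 mismatches of the
known set is rejected from the novel path.

## Target scoring

`scoreDuplex()` charges, per position from the miRNA 5′ end: match 0, G:U
wobble 0.5, mismatch 1.0, gap 2.0, doubled over positions 2–13 (the
5′/central region whose pairing cleavage requires); the default cutoff is
4.0. A reportable site must contain an exact Watson–Crick complement of
miRNA positions 2–8 (the 7-mer seed); around each seed hit the scanner
scores the ungapped frame and every single-gap variant outside the seed, and
merges overlapping frames to the best-scoring. The seed requirement is part
of the site definition, so the seeded scan provably equals exhaustive
all-offsets scoring — the test suite checks exactly that against an
independent brute-force scorer. Gap columns take the position weight of the
next miRNA base. Raising `maxPenalty` toward ~5 emulates looser
expectation-style cutoffs.

## Degradome categories

Tag 5′ ends are accumulated per transcript position; multi-mapping tags
split their counts equally (fractional counts allowed). For an alignment,
the expected cleavage position is the target nucleotide paired to miRNA
position 10; a site is called at the maximal profile position within ± 1 nt
(`window`) if it carries ≥ `minCount` (default 1) tags. With `c` the site
count, `M` the transcript maximum and `med` the median over expressed
positions:

* category 4: `c ≤ 1` — single-read evidence, also after fractional
  splitting;
* category 0: `c = M`, maximum attained at exactly one position;
* category 1: `c = M`, maximum attained at several positions;
* category 2: `med < c < M`;
* category 3: `1 < c ≤ med`.

The clause order makes the five categories a partition of all expressed
positions — verified exhaustively in the tests over every count multiset
0–10 up to six expressed positions. The median is taken over expressed
positions only, and `minCount = 1` deliberately admits category-4 sites,
mirroring how published degradome tables report them.

## Quantification

`relativeExpression()` implements 2^−ΔΔCT: per tissue, ΔCT = mean Ct(assay)
− mean Ct(reference); ΔΔCT subtracts the calibrator tissue's ΔCT, so the
calibrator maps to level 1 exactly. The reference assay is configurable
(5.8S/18S rRNA in typical stem-loop qPCR designs). Replicate dispersion is
propagated as sd(ΔΔCT) = sqrt(sd_a²/n_a + sd_r²/n_r) and reported as a fold
range; multiple-range testing across tissues is ordinary off-the-shelf
statistics and out of scope. `oppositePattern()` flags miRNA/target pairs
with negative Spearman correlation across ≥ 3 shared tissues; a constant
vector leaves the flag undefined rather than forcing a sign.

## The synthetic study

`simulateStudy()` generates the full study the tests and the acceptance
script run on: background transcripts of 400–700 nt; 20 conserved and 15
novel hairpins (mature + ≥4-nt loop + near-reverse-complement star with the
2-nt overhang geometry), each on its own transcript; a known mature set
placing every conserved mature at 0–2 substitutions from exactly one
synthetic family (and > 2 from all others, so family assignment has a unique
right answer); six decoys — near-known tags planted in unstructured
(A/C-only flanked) contexts and far-from-known noise tags — which must never
be called; four tissue libraries with log-normal tag abundances (median ~15,
heavy-tailed like real count tables), 10% 1-nt end jitter, star reads,
ncRNA contaminant fragments from the bundled synthetic annotation set,
unmappable noise reads, adapterless and ambiguous-residue rejects; ten
planted target sites; and degradome tags arranged so each intended category
0–4 is realised, verified by the generator against its own clause
definitions before emission. Everything is recorded in a
`GroundTruthManifest`, and regeneration from the same seed is
byte-identical.

What passing the round trip shows: the pipeline's rules recover what they
claim to recover under clean, known-truth conditions — counts conserved
through preprocessing, ≥ 90% conserved and ≥ 80% novel recovery with zero
family misassignments, zero decoy or unexplained calls, planted sites found
at penalty ≤ 4, and exact category agreement. What it does not show:
robustness to sequencing error, isomiR complexity, assembly fragmentation or
cross-mapping gene families — real-data features the generator deliberately
does not model. Target-site and category agreement are scored conditionally
on the upstream call having been made, so each metric isolates its own
stage.

## Problem sizes and numerical checks

The test suite compares the folder against exhaustive enumeration on 200
random sequences of 10–28 nt (an independent depth-first enumerator with an
admissible bound, evaluating the declared model term by term), checks the
category partition over all ~12,000 count multisets, and runs the synthetic
round trip once at the default study size (41 planted items on 55
transcripts). These sizes were chosen so the whole suite exercises every
contract at full strength while remaining a routine desk-scale run.

Degenerate inputs are defined rather than accidental: empty read sets
produce empty libraries with zeroed tallies; GC-free sequences report MFEI
as undefined; constant expression vectors leave the anti-correlation flag
absent; a profile position with zero count is an error ("not a site"), not
category 0.

## Known limitations

* The energy model is intentionally simple; absolute energies are not
  comparable to thermodynamic folders, and quantities derived from them
  (mean precursor MFE) are out of scope.
* Forward-strand scanning by default (assembled transcripts); reverse
  complement scanning is an option flag on excision.
* No isomiR aggregation: counts attribute to the exact tag only.
* The degradome noise model is the category scheme itself; no statistical
  background model beyond it.
* 1-based closed coordinates everywhere, the R/Bioconductor convention.
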