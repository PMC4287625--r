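---
title: "Detecting and curating plastid RNA editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and curating plastid RNA editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The problem

Plant plastid transcripts are post-transcriptionally edited: specific
cytidines are converted to uridines (C-to-U) and, in some lineages,
uridines back to cytidines (U-to-C). Against a plastid genome
sequenced from the same plant, an edit site appears in RNA-seq read
alignments as a DNA:RNA mismatch — C:T on the sense strand or G:A on
the antisense strand for C-to-U, T:C or A:G for U-to-C. The eight
remaining ref:alt pairs cannot be produced by editing and are always
errors of some kind; their abundance in raw mismatch calls is the
yardstick for how many editing-shaped calls are probably errors too.

`editscan` implements this comparison as an explicit, fully automated
pipeline: pileup construction under several read-end trim treatments,
mismatch typing and threshold-based calling, rule-based
classification of four false-positive classes that were historically
separated by visual inspection, reference correction with a second
calling pass, codon-level and cross-species annotation, and a seeded
simulator that makes the whole chain testable without any external
data.

## The calling rule

A candidate site is a (position, alternative base) pair in the RNA
pileup satisfying

* read depth ≥ `min_depth` (default 3), and
* supporting reads ≥ max(⌈`min_frequency` · depth⌉, `min_support_reads`)
  (defaults 5% and 3 reads — "whichever is greater").

The frequency comparison is inclusive (a 6/118 site at 5.08% passes),
and the ceiling means a fractional read count never satisfies the
rule. Because editing can be very inefficient, these defaults are
deliberately permissive: the design accepts extra false positives at
the calling stage and removes them with the artifact classifiers,
rather than tightening thresholds and losing inefficiently edited
sites. `sweep_thresholds()` reproduces the parameter-sweep tables that
motivate this choice: per-category counts are monotone non-increasing
in every threshold, but editing-shaped categories fall much faster
than error categories as thresholds rise.

Each of three trim treatments (0, 6 and 12 bp masked from both read
ends) is called independently and the union is retained, keyed on
(position, alt base). Union rather than intersection is used because
the treatments disagree mainly at inefficiently edited sites near the
5% boundary, where intersection would manufacture false negatives.
Reported depth, support and frequency for a unioned call come from the
untrimmed pileup, which uses the maximal data. Trimming is implemented
as masking read ends during pileup — alignments are consumed, not
recomputed — and end distances are always measured on the untrimmed
read.

## The four artifact classes

Each classifier turns a visual-inspection criterion into an explicit
rule with configurable thresholds (`filter_thresholds()`); any flag
rejects a call, and no flagged call is ever rescued.

**Heteroplasmy.** Plastids carry many genome copies; real sequence
polymorphism among them propagates into transcripts and mimics
partial editing. A call is flagged when the DNA read pool itself shows
the alternative base at ≥ 5% with ≥ 3 reads (mirroring the RNA calling
thresholds), but below the 90% consensus bar that would instead
indicate a reference error. Positions with fewer than 3 DNA reads
cannot be cleared; they are retained and annotated as DNA-uncovered
rather than rejected.

**Read-end bias.** Imperfect random-hexamer binding during cDNA
synthesis concentrates errors in read ends. A call is flagged when
*every* supporting read carries the mismatch within 6 bp (inclusive)
of one of its untrimmed ends. A single mid-read supporting read
defeats the flag.

**Exon/intron junction mismapping.** A spliced read aligned
contiguously across an exon/intron boundary of the unspliced genome
deposits next-exon bases onto intron positions. A call is flagged
when it lies in an intron within a read length of a boundary and, for
every supporting read: the read is contiguous across that boundary;
re-interpreting the alignment as spliced (relocating the past-boundary
segment to the far side of the intron) removes the mismatch at the
call position; and the relocation strictly reduces the segment's total
mismatch count. The segment-level condition is the package's own
refinement: with only the single-base test, a genuine intron edit
whose relocated base matches by coincidence (a 1-in-4 event per
boundary) would be mis-flagged, whereas for a truly mismapped read the
whole overhang matches the next exon and the reduction is decisive.

**Reference error.** When the DNA consensus (≥ 90%) and the RNA
majority base agree with each other but not with the published
reference, the published sequence is wrong. The mismatch is rejected,
the genome is corrected at that position, and the entire
call-and-filter pass is re-run once against the corrected genome —
exactly one correction pass, no iteration to a fixpoint. First-pass
reference-error rejections are kept in the final rejected table, since
the corrected positions no longer produce mismatches on the second
pass.

The detectors are independent and order-free; a call may carry several
flags. The heteroplasmy and reference-error numeric cutoffs are the
package's own operational definitions — visual inspection has no
numeric criterion to inherit — and are therefore exposed as
parameters.

## Annotation

Curated editing-consistent calls are located in the annotation
(priority CDS > tRNA > rRNA > intron; everything else is a single
UTR-or-intergenic class, since no distance rule separates UTRs from
spacers). Coding sites get spliced, strand-oriented CDS coordinates,
reconstructed reference/edited codons, and amino acids under the
standard genetic code. Start-codon creation (e.g. ACG → ATG) is
detected structurally — codon 1 becoming ATG — not by translating ACG
as methionine; frames come from the annotation, with no ORF
re-prediction. Intron sites are labelled gene + "i" + the CDS position
of the last exonic base before the intron (clpPi71 style).

Editing efficiency is the fraction of reads carrying the edited base,
`support / depth` from the untrimmed pileup. Percentages render at one
decimal, rounding half away from zero (6/118 → "5.1%").

The functional effect of a coding edit is scored against a per-gene
protein alignment: *silent* if the amino acid is unchanged;
*conservative* if the edited residue matches strictly more of the
other species' residues at the homologous column than the reference
residue does; *non-conservative* otherwise — a tie is not an
improvement, and premature stops are always non-conservative. Sites
are compared across species through the same alignments: two sites are
homologous only when gene, alignment column, codon offset *and* edit
type all agree, since edits at different offsets of one codon, or a
C-to-U and a U-to-C at one column, are distinct events.

## The simulator

`simulate_dataset(sim_config(seed))` emulates the study design this
pipeline targets: a 20 kb circular plastid-like genome; six genes on
both strands (two with group-II-style introns) plus a tRNA and
intergenic spacers; 75 bp single-end reads; RNA depth 60 over
transcribed regions and DNA depth 40 genome-wide (deep enough for
stable binomial behaviour at desk scale while keeping runtimes in
seconds); per-base error 0.001, elevated to 0.02 in the terminal 6 bp
to mimic hexamer mispriming; 40 edit sites whose efficiencies evenly
span 0.05–1.0, shuffled over coding, intron, tRNA and UTR locations
with a small U-to-C contingent; and all four artifact classes:
heteroplasmic positions at fractions 0.2–0.5 present in both DNA and
RNA pools, deliberate reference errors, end-bias positions, and
junction mismapping.

Reads are emitted pre-aligned — their generation coordinates are their
alignments — deliberately bypassing any aligner so the pipeline is
tested in isolation from mapping variability. Mismapping is injected
mechanistically: spliced reads whose junction overhang is at most 8 bp
are always emitted contiguously (an aligner cannot split a read on an
anchor that short), plus 5% of longer-overhang reads. A 30% precursor
(unspliced pre-mRNA) read pool gives introns genuine coverage, which
is what makes intron edit sites observable at all. Transcripts extend
100 bp beyond gene bounds so UTR edits are simulable.

Two deliberate simplifications: random sequencing errors are
suppressed at injected-artifact positions, so each artifact has a
single unambiguous cause and the truth table stays exact; and base
qualities are constant (the pipeline never reads them). The simulator
also does not model indel errors, PCR duplicates, coverage
heterogeneity beyond transcript-end edge effects, or origin-spanning
reads (which the loaders reject). Passing tests on this synthetic data
therefore demonstrate the pipeline's logic — typing, thresholds,
artifact separation, strand handling, coordinate arithmetic — not
robustness to every failure mode of real libraries.

## Numerical choices and degenerate inputs

* `ceil(min_frequency · depth)` is computed with a 1e-9 slack so that
  products like 0.05 × 60, exactly 3 in real arithmetic, do not round
  up through binary floating point.
* Coordinates are 1-based closed everywhere; the SAM boundary is the
  only conversion point. Multi-allelic positions yield one call per
  alternative base. Insertions and deletions are never candidates.
* Deterministic throughout: identical inputs give identical outputs,
  and the simulator is byte-reproducible from its seed. All
  randomness lives in `sim_config$seed`.
* Empty inputs (no reads, no calls, no sites) flow through every stage
  as empty tables; a class with one site reports an undefined standard
  error as NA rather than 0.
* With no DNA reads the DNA-based detectors disable with a warning and
  the remaining pipeline completes — transcript-only evidence is
  reported, not silently dropped.

## Problem sizes used in the tests

The packaged checks run the full pipeline on the default 20 kb fixture
(seed 42), unit-test every rule on constructed micro-fixtures, verify
pileup construction against a naive per-read CIGAR re-walk, check
threshold monotonicity on a 7 kb fixture, and calibrate the efficiency
estimator on 50 seeded replicates of a single-gene fixture at depth
110, pooling all sites with realized depth ≥ 100. At these sizes the
estimator's mean signed error is well inside ±0.02, the binomial
expectation.

## Known limitations

Origin-wrapping alignments on the circular genome are rejected rather
than handled. The inverted repeat receives no special treatment —
duplicated features simply appear twice. Base qualities are ignored at
the pileup stage, and artifact classification is rule-based, not
likelihood-based. The UTR class is not separated from generic
intergenic sequence. tRNA and intron secondary-structure consequences
of editing are out of scope, as is running or wrapping any aligner.
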