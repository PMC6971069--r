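---
title: "Structure-aware rDNA comparison: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware rDNA comparison: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcscope)
```

## The problem

Coccoid green algae offer few morphological characters, so genus- and
species-level decisions in groups like the Scenedesmaceae lean on the
ribosomal operon: how many sites separate two taxa, how many of those
sites are compensatory base changes (CBCs) or hemi-CBCs in conserved
helices of the SSU rRNA, whether clades carry non-homoplasious
synapomorphies (NHS), and how divergent the internal transcribed spacers
are once gaps are handled explicitly. `cbcscope` turns each of those
steps into a typed, testable operation. This vignette records the models
and conventions behind them, the parameters a user may want to move, and
what the validation does and does not establish.

## Pairing model

A secondary structure is a set of base pairs `(i, j)`, `i < j`, on the
ungapped sequence, with three structural commitments:

* **Nested only.** Crossing pairs (pseudoknots) are rejected at
  construction, not silently dropped: the eukaryotic SSU rRNA consensus
  models this package targets are nested, and a silently dropped pair
  would distort every downstream count.
* **G·U counts as complementary.** Complementarity is A·U, G·C and the
  G·U wobble. Wobble pairs are structurally conserved in rRNA stems;
  scoring them as broken would flood conserved helices with spurious
  "uncoupled" calls and inflate hemi-CBC→uncoupled misclassifications.
* **Labels are carried, not computed.** Helix names ("49", "E23_4", …)
  are free text supplied via a sidecar TSV and simply travel with their
  positions through alignments and transfers. The package does not
  hard-code any helix-numbering table; per-helix tallies are only as
  good as the curation in the sidecar.

Ambiguity codes (N, R, Y, …) are retained verbatim, never expanded, and
make complementarity *indeterminate* (`NA`) rather than true or false.

## Structure transfer

`transferStructure()` pushes a template structure through a pairwise
alignment onto a query. A template pair survives iff the query holds
residues at both partner columns; pairs lost to query gaps are reported
in a flag table, and transferred pairs whose query bases are
non-complementary are **kept but flagged**. Keeping them is deliberate:
the downstream classifier needs the site to exist to call it an
uncoupled substitution — dropping it would silently delete the most
taxonomically interesting sites.

## Site classification and gap policies

For two aligned rows in structural context, every variable column gets
exactly one record:

| situation | class |
|---|---|
| both sides of a pair change, both pairs complementary | CBC (one record, two columns) |
| one side changes, both pairs complementary | hemi-CBC |
| any change, at least one pair non-complementary | uncoupled |
| substitution at an unpaired column | loop substitution |
| gap in the column's own states, or at its pairing partner | indel |

Conventions worth stating explicitly:

* A CBC is counted **once per base pair** but spans two columns, so the
  bookkeeping identity `2·CBC + hemiCBC + uncoupled + loop + indel =
  variable sites (gaps counted)` holds on every comparison and is
  asserted property-style in the tests.
* Each gap column counts as one differing site by default (a 3-column
  indel is 3 sites); `gapPolicy(indelAsEvent = TRUE)` collapses a
  maximal gap run into a single reported record for users who prefer
  event counting. Gap-vs-gap columns never count anywhere.
* A paired column whose *partner* carries a gap is classified as an
  indel: the pair no longer exists as a comparable unit, and assigning
  it to any substitution class would double-count the disruption.
* Columns where either row has an ambiguity code are excluded from all
  counts by default (`maskAmbiguity`), as are primer-masked columns
  (`maskPrimer`) — the lower-case 5′ primer-binding convention on input
  FASTA populates the mask automatically. A paired column whose partner
  is masked is excluded with it, keeping the partition identity intact.

The two distances are `(m + g)/L` with gaps counted and `m/(L − g)`
with gaps excluded (`m` substitution columns, `g` single-gap columns,
`L` usable columns). The first always dominates the second —
`(m+g)/L ≥ m/(L−g)` algebraically — and the suite checks this on 1,000
random alignments.

## Intron excision

Group I introns in algal rDNA are hundreds of nucleotides long. Against
an intron-free reference they appear as long insertion blocks, so
excision is defined directly on the alignment: every maximal run of at
least `minInsert` consecutive columns where the reference has gaps and
the query has residues is removed and reported as one intron. The
default `minInsert = 50` nt sits far below real group I intron lengths
and far above ordinary alignment slop; it is a parameter, not a claim.
Alignment defaults (match +2, mismatch −1, gap open −10, gap extend
−0.5) are fixed so that counts are reproducible run-to-run; the
alignment engine is standard Needleman–Wunsch with affine gaps.

## Synapomorphy calls

"Derived" is decided by direct comparison with the clade's **sister
group**, not by ancestral-state reconstruction: a clade-fixed state is
synapomorphic when at least one sister representative differs, an NHS
when it additionally occurs in no tip outside the clade, an autapomorphy
when the clade is a single tip. This mirrors how such characters are
read off comparative structure diagrams; Fitch parsimony is explicitly
out of scope. Consequences of that choice: gaps act as a fifth state
(indel synapomorphies are reported, flagged); a clade equal to the whole
tip set has no outside and is defined as not-synapomorphic rather than
an error. Paired-column couples are classified as units — the clade's
pair versus the sister consensus pair — so a conserved-pairing change
can be annotated CBC or hemi-CBC at clade level, and the NHS criterion
applies to the pair state as a whole.

## ITS2 motifs

Helices are numbered I–IV by the 5′ order of their outermost pair, on
the assumption of the standard eukaryotic four-helix ITS2 layout. The
four checks: a 1×1 internal loop in helix II whose facing bases are both
pyrimidines; an A-rich window between helices II and III (window ≥ 4 nt,
A-fraction ≥ 0.75 — invented defaults, exposed as `aWindow`/`aFrac`,
since no numeric criterion is published for "A-rich"); the literal
`GGU` on the 5′ strand of helix III before its apex; and a branched
(y-shaped) helix I, detected as any multiloop within the helix I domain
carrying ≥ 2 child stems. ITS2 folding itself is accepted from input
files: the package's `foldMaxPairing()` is a maximum-pairing
(Nussinov-style) folder intended for synthetic tests only, where its
optimum is verified against exhaustive enumeration; it is not an energy
model and should not be used to predict real structures.

## What the generators emulate — and what they do not

The synthetic module is first-class, tested code. Each generator takes
one integer seed, runs on a private RNG stream (no global state), and is
byte-deterministic. `makeTemplate()` builds concatenated stem-loops with
strict Watson–Crick stems, so every planted wobble is attributable;
`plantChanges()` plants non-overlapping changes of each class away from
primer-masked positions; `makeRdna()` plants intron blocks inside named
regions; `makeCladeAlignment()` plants clade-diagnostic columns on an
otherwise invariant alignment; `makeIts2()` builds a four-helix molecule
with all motifs present and can knock out exactly one.

Two generator details exist purely to keep planted truth unambiguous,
and are worth knowing about:

* intron blocks are **pinned**: their first and last bases are chosen to
  differ from the flanking reference bases, because otherwise the
  optimal alignment can slide the gap by one column and the "true"
  coordinates are not unique;
* insertion points within one region are kept ≥ 20 nt apart, because
  two nearly adjacent blocks can be absorbed into a single gap that
  out-scores two gap-opens, merging two planted introns into one.

What passing these round-trips shows: the detectors invert the
generators exactly under the stated conventions. What it does not show:
robustness to real-data phenomena the generators deliberately omit —
substitution-model evolution along branches, rate heterogeneity,
empirically distributed indel lengths, alignment error between distant
taxa, or structures that deviate from the supplied template. Real
comparisons remain sensitive to alignment parameters and structure
curation, which is why accession-based counts are only expected to
reproduce to within a few sites when the alignment is re-estimated.

## Problem sizes and degenerate inputs

The validation suite uses an SSU-scale template of 65 stem-loops
(1,695 nt, 520 pairs) for the headline comparison; 100-seed loops for
planted-change, NHS and intron recovery (the intron loop uses a 850-nt
molecule with three blocks so that 100 alignments stay quick); 500
random sequences of length ≤ 12 for the fold-versus-enumeration
property; and 1,000 random alignments for the distance ordering. The
acceptance script re-runs the same conditions end to end.

Degenerate inputs are errors, not silent results: empty FASTA records,
non-IUPAC characters (reported with their position), unequal alignment
rows, unknown region names, pseudoknotted structure files, structures
longer than their reference row, non-monophyletic clade queries,
all-gap denominators in distances, and over-capacity planting requests
all raise typed messages. The one soft case is `checkMotifs()` with
fewer than three helices, which warns and reports all motifs `FALSE` —
a structure that degenerate is an answer, not a crash.
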