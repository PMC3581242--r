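---
title: "Methods: unique peptide segments and heparin-binding region screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unique peptide segments and heparin-binding region screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbrscout)
```

## The problem

Closely related protein families — the motivating case is the thirteen human
ribonuclease A (RNaseA) superfamily members, where RNase3 is the eosinophil
cationic protein — share a conserved fold and much of their sequence, yet
individual members carry functions the others lack. A useful first in-silico
step is to ask: *which stretches of one member's sequence occur in no other
member?* Such member-unique segments are candidate carriers of
member-specific function. Among RNase3's unique segments, the ones rich in
positively charged residues (arginine/lysine) are candidate heparin-binding
regions (HBRs), because heparin and heparan-sulfate binding is
electrostatically driven by clustered basic side chains.

hbrscout implements that pipeline end to end: unique-segment extraction,
cationic-window screening, and the identity bookkeeping used to compare the
10-residue heparin-binding motif (mature RNase3 residues 32–41, NYRWRCKNQN)
across species and family members.

## Unique-segment model

Fix a *primary pattern length* `L` (default 3 residues — short patterns for
closely related sequences, longer for divergent families) and a *uniqueness
level* `m` (default 1). For every length-`L` substring in the family the
**carrier set** is the set of members containing it at least once;
multiplicity within one member is irrelevant, because uniqueness is defined
against *other* sequences. Start position `i` of a member is flagged when its
pattern's carrier count is at most `m`. Maximal runs of consecutive flagged
starts are merged bottom-up: a run over starts `[i..j]` yields the segment
`[i, j + L - 1]`. The segment's `level` is the largest carrier count among
its constituent patterns.

Two numerical consequences of this rule are worth stating explicitly:

* Two runs separated by a single unflagged start produce *distinct* segments
  that share up to `L - 2` boundary residues (one residue at `L = 3`). The
  published RNase3 motif list behaves exactly this way (HISLNPPR at 15–22 and
  RCTIAMRA at 22–29 share Arg22), which is why merging is keyed on
  consecutive flagged starts rather than on any residue overlap between
  patterns: an overlap-based rule (start distance ≤ `L - 1`) would fuse those
  printed pairs into single segments.
* Flagged positions are monotone in `m`, and monotone in `L` on the shared
  coordinate range (a unique `L`-window makes its containing
  `(L+1)`-window unique). Both are property-tested.

Exact matching is the whole contract; the hash index used here is one of
several equivalent backends (classic string-search algorithms such as
Boyer–Moore give the same answer and differ only in constant factors).
`X` (unknown residue) is treated as a literal: an X-containing pattern
matches only another literal X.

## HBR screening rule

No screening rule is published with the motif list; the three published
windows (^34^RWRCK^38^, ^73^RSRFR^77^, ^101^RPGRR^105^) and the eight
non-HBR unique motifs were used to reverse-engineer the minimal rule that
reproduces exactly that outcome. The defaults are:

| knob | default | meaning |
|---|---|---|
| `window` | 5 | scanned window width (residues) |
| `min_basic` | 3 | minimum basic residues per window |
| `basic` | R, K | residues counted as basic |
| `flank` | 2 | extension of the unique segment before scanning |
| `min_overlap` | 3 | required overlap with the unextended segment |

The flank is load-bearing: Lys38 of the first window lies one residue
outside the unique segment NYRWRC (32–37), so an unextended scan misses it.
Histidine is excluded by default — it is only partially protonated at
physiological pH and including it does not change the RNase3 outcome — but it
is one `screen_config(basic = c("R","K","H"))` away. Per segment, only the
window with the maximal basic count is reported (ties broken leftmost) so a
single cationic cluster is not double-reported; `all_windows = TRUE`
disables the collapse.

## Identity computations

**Motif identity** over the printed 10-mers is plain positional (Hamming)
identity: identical non-gap residues over all 10 columns, gaps always
mismatching and never removed from the denominator. This is deliberately not
a re-run of an alignment service: the printed 10-mers are already
column-aligned, and this definition reproduces the printed percentages
(validated cell-by-cell in the tests; see the fixture notes below for the
two kinds of cells that do not reproduce). The corresponding-region claim —
that four family members are 60% identical to the first HBR window — is the
same computation on motif positions 3–7 versus RWRCK.

**Whole-protein identity** is a full Needleman–Wunsch global alignment under
an affine gap model (Gotoh), BLOSUM62, gap open 10, gap extend 0.2 (the
classic ClustalW protein defaults; a gap of length *k* costs
`10 + 0.2 k`). Traceback ties break deterministically: diagonal, then up,
then left. Percent identity is identical pairs over alignment columns,
excluding columns inside a terminal gap run of either sequence (leading and
trailing overhangs are not evidence about either protein). Because percent
identity of an *optimal-but-not-unique* alignment is engine-dependent, the
whole-protein identity column is treated as a soft quantity everywhere; the
alignment *score* is the hard quantity, checked against a brute-force
alignment enumerator at tiny lengths and against an independent
dynamic-programming engine (`Biostrings::pairwiseAlignment`) up to longer
lengths.

## Fixture tables and their two curated cells

The packaged tables carry, per row, both `motif_printed` (the published cell,
whitespace stripped) and `motif` (the motif actually used in computations),
plus a `note` wherever they differ or a cell is irreproducible:

* The cross-species table prints the RNase2 motif as NYQRQCKNQN in five rows
  (human and four primates) alongside an 80% identity figure. That motif
  computes to 70%; the within-family table prints the human RNase2 motif as
  NYQRRCKNQN, which computes to 80% and matches UniProt P10153. The curated
  `motif` column therefore uses NYQRRCKNQN for those five rows and keeps the
  printed variant side by side. The same-table Pongo pygmaeus RNase2 row
  (NFQRRCKNQN, 70%) reproduces as printed.
* The RNase10 cell prints 10% but its printed motif EPSQSCIAQY shares C6 and
  Q9 with the reference, i.e. 20%. No curation can be justified from the
  published material, so the cell is flagged irreproducible and excluded
  from acceptance checks.

With the curated motifs, 24 of the 25 table rows reproduce exactly; RNase10
is the only exception.

## The synthetic stand-in family

The original analysis ran on thirteen UniProt accessions. This package works
offline, so it ships a generator (`hrnasea_standin_family()`) for a
*labelled synthetic stand-in*: the target member is a 133-residue sequence
reconstructed from published anchors — the eleven unique motif texts with
their coordinates, the three HBR windows, and the individually named
residues (Arg1, Trp10, Gln14, His15, Trp35, Lys38, Gln40, Arg101, Arg104,
Arg105, His128). Twelve background members each carry one of the target's
shared stretches verbatim (every 3-mer outside the unique segments occurs in
exactly one background member), padded with deterministic pseudo-random
residues screened against the target's unique 3-mers. Construction asserts
the realizability condition that no 3-mer text occurs at both a unique and a
shared start of the target.

One anchor conflict had to be resolved: the published motif NCTYADRPGRRFYV
placed at 95–108 puts threonine at position 97, while the discussion text
(citing earlier literature) calls residue 97 an arginine. The motif placement
is the only one consistent with the third HBR window at 101–105, so the
stand-in uses the printed T97; the choice does not affect the screen (neither
T97 nor R97 changes the winning RPGRR window). Similarly, the second HBR
window is numbered 73–77 here, consistent with the motif coordinates, though
the source material also prints 75–79 in places.

What a green stand-in test does and does not establish: it validates the
pipeline machinery end to end — indexing, masking, merging, screening —
against the published outcome on a family with the same uniqueness
structure. It does not validate mature-chain boundaries or the actual
database sequences; `scripts/fetch_uniprot.R` re-runs the pipeline on the
real accessions when a network is available.

## The random synthetic generator

`generate_family()` emulates the statistical structure of such a family:
one random scaffold (default 130 residues, uniform residue background —
uniform keeps collision probabilities tractable; an organism-like
composition would only make planted uniqueness easier), 13 members by
default, per-member substitution noise 0.05, 2–4 planted unique segments of
5–14 residues per member (the length range of the eleven published motifs),
and 0–2 planted cationic windows (width 5, ≥3 basics, mirroring the screen
defaults), each in a distinct planted segment.

Planting is constructive, not hopeful. Three fixpoints make the ground truth
actually true:

1. **Uniqueness**: every `L`-window inside a planted segment must be absent
   from every other member; offending segments are resampled (and spliced in
   immediately) until a full sweep is clean. With a 20-letter alphabet this
   converges in tens of sweeps.
2. **Dominance**: a planted cationic window must be the strict winner of the
   basic-count scan over whatever maximal unique run it ends up in — noise
   can fuse a planted segment with adjacent noise-unique stretches, letting
   a background window tie and win the leftmost tie-break. Competing windows
   lose one basic residue (never inside a planted window); segments touched
   by such repairs stay basic-free under any later resample. Basics are pinned to
   both ends of the planted window, so any shifted window strictly loses one;
   this needs `min_basic >= 2`.
3. **Separation**: planted spans sit more than `flank` residues apart, and
   when two planted cationic windows end up fused into one unique run, the
   scaffold is restored in the gap between their segments so the run splits
   (only one representative window is reported per run).

Consequences worth knowing: planted-segment recall and planted-HBR recall
are 1.0 by construction (verified over many seeds), while *precision* may
legitimately be below 1 — substitution noise creates genuinely unique extra
segments, and that is a property of the world, not a detector error. Tests
therefore assert recall, and precision only in the noise-free case.
Everything is reproducible: the same configuration and seed give a
byte-identical family, and the generator restores the caller's RNG state.

## Degenerate inputs and numerical choices

* Families need ≥2 members for uniqueness analysis; single-member indexing
  is allowed (useful for inspection) but `unique_segments()` refuses it.
* A member shorter than `L` is an input error naming the member.
* An all-false mask merges to an empty segment table, not an error.
* Alignment scores mix BLOSUM62 integers with multiples of 0.2; traceback
  comparisons use an absolute tolerance of 1e-9, and cross-engine score
  checks 1e-4 (one engine quantizes the fractional gap penalty in single
  precision).
* Reports are written with 1-based inclusive coordinates, sorted by member
  then start, with provenance headers (tool version, parameters, input
  checksums); the timestamp line is suppressible so re-runs are
  byte-identical.

## Limitations

* The screening rule is a reverse-engineered minimal rule, not a published
  protocol; all five knobs are exposed and other families may need other
  settings.
* No structural accessibility, no docking, no affinity prediction: a
  cationic window on a buried face would still be nominated.
* Whole-protein identity percentages depend on the alignment engine when the
  optimum is non-unique; they are reported but never used as hard acceptance
  quantities.
* No approximate (mismatch-tolerant) uniqueness and no multiple-alignment
  construction; external alignments are read, not built.
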