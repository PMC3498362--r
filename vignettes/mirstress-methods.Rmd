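---
title: "miRstress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRstress: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRstress)
```

miRstress compares two small-RNA sequencing libraries — typically a control
condition ("A", e.g. nutrient-sufficient seedlings) against a stress
condition ("B", e.g. nitrogen-starved seedlings) — and reports the RNA-class
composition of each library, member-resolved expression of known miRNAs,
fold-change response classes, novel miRNA candidates supported by hairpin
precursor structure, and predicted target sites validated against degradome
(PARE) 5'-end tags. This vignette explains the models and the decisions
behind the defaults; nothing here states an empirical result that the test
suite or the acceptance script does not itself compute.

## The tag table

All quantification operates on *tags*: distinct insert sequences after 3'
adapter trimming, carrying a read count per library. Trimming cuts at the
leftmost occurrence of the adapter (a full match anywhere, or a prefix of at
least `min_overlap = 8` bases flush with the read's 3' end) and accepts
inserts of 18–30 nt by default. The window is deliberately wider than the
19–24 nt range where plant small RNAs concentrate: gel purification in
typical protocols captures 20–30 nt, and the length profile is computed
*after* collapsing, so the headline "fraction of reads at 19–24 nt" is a
measurement, not a filter. Sequences are normalized to the DNA alphabet
(U→T) because all genome matching is DNA-space. Reads containing a supplied
5' adapter are dropped as two-adapter ligation artifacts.

Trim-then-collapse conserves reads exactly: the collapsed counts plus the
per-reason rejection counts reproduce the raw read number, and the test
suite asserts this as a property.

## Perfect-match mapping

Tags are placed on both strands of the genome by exact substring match only
— no mismatches, no indels, and `N` never matches. Internally coordinates
are 0-based half-open; GFF3 I/O converts at the boundary. A multi-mapping
tag is counted **once per tag** in composition and quantification, with the
placement count (`n_loci`) carried along for reporting; this keeps library
totals equal to read totals, which is how published composition tables add
up. For discovery, candidates are capped at `n_loci <= 5` so repetitive
regions do not flood the hairpin evaluation.

## Class composition and library overlap

A tag is assigned a structural class when any of its loci overlaps (≥ 1 bp,
same strand by default) an annotated rRNA, tRNA, snRNA or snoRNA interval;
ties across classes are broken by the fixed precedence rRNA > tRNA > snRNA
> snoRNA, so classification is invariant under annotation order. Strandless
overlap is available as a switch since some annotation sets are unstranded.
Composition percentages follow the mixed dialect of deep-sequencing summary
tables — two decimals below 10%, one decimal at or above, halves rounded
away from zero — while the count columns are exact integers whose totals
row equals the column sums with no rounding.

Library overlap calls a sequence *common* when it has reads in both
libraries; unique percentages are over distinct sequences, total
percentages over combined read counts.

## Known-miRNA quantification and response classes

Deep sequencing distinguishes family members one nucleotide apart, so a tag
is assigned to a mature miRNA only by exact full-length identity. Members
with identical mature sequences are indistinguishable and merged into a
group named `miR169d-g` style. RPM is `count / library total × 10^6`.

The log2 fold change (condition B over A) uses **raw count ratios** by
default. When a published novel-miRNA table prints per-library counts next
to a fold column, the raw ratio reproduces that column at one decimal
(e.g. `log2(82/1145) = -3.80`), whereas per-million normalization shifts it
(−3.89 for the same pair, at the library totals involved); RPM mode remains
available for cross-library expression comparisons. If either count is
zero, 1 is added to both raw counts — only then — which keeps every
reported fold finite without perturbing nonzero pairs. Response classes use
strict thresholds: induced if `log2fc > log2(r)`, suppressed if below the
negative, with `r = 3` for known miRNAs ("greater than 3-fold") and `r = 2`
for novel candidates. Records with fewer than 5 combined reads are flagged
`low_count` and excluded from response calls; very low counts make fold
ratios meaningless, and the cutoff is configurable.

Classification is applied to the *unrounded* fold change; the printed value
is rounded half-away-from-zero to one decimal.

## Secondary structure and hairpin criteria

The default folding engine maximizes summed pair weights (GC = 3, AU = 2,
GU = 1) over nested structures with a minimum hairpin loop of three
unpaired bases — a weighted Nussinov dynamic program. It is deterministic:
on score ties the 5' base stays unpaired, and among co-optimal partners the
smallest index wins. This engine was chosen over thermodynamic folding
because it is dependency-free and exhaustively checkable (the tests compare
its optimum against full enumeration for short sequences); a
minimum-free-energy folder can be plugged in through `fold_fun` wherever a
dot-bracket string of the same length comes back.

Each candidate cluster is excised in two windows (flanks 150/20 nt and
20/150 nt — typical plant precursor spans) so the mature may sit on either
arm. A candidate passes when, in at least one window: all paired mature
bases pair to the far side of the terminal loop and no mature base lies in
the loop; at most 4 mature bases are unpaired; and no bulge or internal
loop inside the mature-spanning duplex exceeds 2 nt. These are declared
defaults for the community annotation criteria for plant miRNAs, which the
literature invokes but does not enumerate as numbers. If both windows pass,
the higher pairing score wins, then the longer stem.

The miRNA* interval is derived from the pairing partner of the mature 5'
end, extrapolated linearly across unpaired end bases, shifted 2 nt so both
duplex ends carry the canonical 2-nt 3' overhang. The same formula is an
involution — deriving the mature back from the star returns the original
interval — which the tests assert. Star support (a tag equal to the star
sequence, with 1-nt slack at either end) is *reported, never required*:
in real data only a minority of genuine loci have detectable star reads.

## Target prediction and degradome validation

The duplex model is ungapped and antiparallel: miRNA position *j* faces
site position *L + 1 − j*. Watson-Crick pairs cost 0, G:U wobble 0.5,
everything else 1; sites with penalty ≤ 3 ("three mismatches or less") are
reported. A strict Hamming mode (`gu_half = FALSE`) treats wobbles as
mismatches. Note that only the strict penalty is invariant under
reverse-complementing both strands: a G:U pair complements to C:A, so the
wobble-scored penalty is strand-asymmetric by construction.

Slicer cleavage is reported at the transcript position paired to miRNA
position 10 (`t1 + L − 10` for a site starting at `t1`), with evidence
pooled over a ±1 nt window. Evidence is categorized with the 5-level
degradome convention: 0 unique transcript maximum, 1 tied maximum, 2 above
the median of nonzero positions, 3 otherwise nonzero, 4 a single read,
`none` when absent. A single read is classified before the max/median rules
so the scheme is well defined.

## The synthetic-data generator

`make_reference()` plants three kinds of loci on a random genome, on fixed
non-overlapping slots:

* **miRNA hairpins** — mature + 8-nt `A` loop + reverse complement of the
  mature, followed by a 160-nt purine spacer. Matures are drawn from
  {C, T} with a fixed `C` at the 3' end. This composition is what makes
  the construction *provably* fold into the planted stem under the
  deterministic engine: the only direction in which the prefer-unpaired
  tie rule could strip a mature pair is an equal-weight re-pairing of a
  star-arm base to something 3' of it, and the purine spacer (no C, no T)
  offers no such partner inside the extraction window. The spacer also
  supplies the two bases of the star's 3' overhang.
* **structural-RNA loci** — random-background intervals annotated as
  rRNA/tRNA/snRNA/snoRNA, exercising the classification filter.
* **decoy loci** — purine-only blocks that emit abundant tags but cannot
  base-pair internally; they travel through clustering and folding and must
  fail the hairpin criteria, exercising the discovery filter as
  unstructured background.

Counts are negative binomial with variance `mu + alpha * mu^2`; `alpha = 0`
degenerates to deterministic rounded means, which makes the generator
analytically checkable (a planted `log2fc = +2` at base mean 100 yields
exactly 100 and 400 reads). Per planted miRNA the expected count ratio B/A
is exactly `2^log2fc`; background loci have equal expected counts in both
conditions, so any false response call is attributable to sampling noise
alone. The default fold palette spans −3.8 … +2.5 with both signs and
zero, matching the dynamic range reported for nutrient-starvation
responses; the default dispersion 0.1 is a modeling choice (published
two-library designs provide no replicate-based estimate), and the default
depth of 200k reads/library keeps simulations fast while leaving planted
loci hundreds of reads of headroom. The 3' adapter
(`TGGAATTCTCGGGTGCCAAGG`) is appended in full to every read by default;
a config fraction emits 8-nt truncated adapters to exercise the
min-overlap path separately.

Planted targets are exact reverse complements of the mature inserted into
random transcripts (penalty 0 ≤ 3 by construction), and the degradome
simulator puts a tag peak exactly at the position paired to miRNA position
10 plus uniform 1-count noise at a configurable rate.

What the generator does **not** emulate: sequencing errors and quality
variation, partial-degradation products of real structural RNAs, genomic
repeat families, isomiR heterogeneity, and expression biases linked to
secondary structure. Passing the recovery tests therefore demonstrates the
pipeline's internal correctness — planted signal in, planted truth out —
not robustness to every artifact of real libraries; real FASTA/FASTQ,
GFF3 and degradome inputs remain first-class citizens of every stage.

## Problem sizes and numerical choices

The bundled tests fold precursors of ~190 nt (the cubic dynamic program
handles 400 nt comfortably), simulate 15k–200k-read libraries on 20–120 kb
genomes, and compare the mapper, folder and target scanner against
brute-force oracles on inputs up to 10 kb — sizes chosen so the whole suite
runs in about a minute and a half while still exercising every code path.
Deterministic tie-breaks (lexicographic row order in the tag table,
smallest-partner traceback, fixed class precedence) make every output
byte-reproducible under a fixed seed, which the pipeline tests assert by
comparing written files across runs.

Known limitations: the discovery stage does not model siRNA phasing or
randomization-based precursor statistics; perfect-match mapping means a
single sequencing error drops a read rather than placing it; and the
degradome categories describe relative abundance only, not statistical
significance.
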