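---
title: "Mapping viral vector integration sites from LAM-PCR reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping viral vector integration sites from LAM-PCR reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampis)
library(dplyr)
```

## The problem

Integrating viral vectors (gamma-retroviral and lentiviral) insert their
genome semi-randomly into the chromosomes of transduced cells.  In
hematopoietic stem-cell gene therapy every engrafted clone is identified by
its vector integration site (IS), so mapping ISs from patient samples is how
clonal dynamics are tracked and insertional mutagenesis -- the perturbation
of genes near an insertion -- is monitored.  The laboratory workflow is
LAM-PCR: linear amplification across the vector/genome junction yields
products of roughly 100--1,000 bp containing part of the proviral long
terminal repeat (LTR), the flanking genomic DNA, and an artificial linker
cassette (LC), re-amplified with 6-nucleotide sample barcodes and sequenced.

`lampis` turns such reads into an annotated IS catalogue through six stages,
each exposed as a data-frame-first function and orchestrated by
`run_pipeline()`:

1. **Input conversion** -- FASTQ to FASTA (`fastq_to_fasta()`); paired-end
   mates are collapsed to a single LTR-first strand (`collapse_pairs()`).
2. **Demultiplexing** -- exact barcode prefix match (`demultiplex()`).
3. **Trimming** -- LTR and LC removal, length filter (`trim_reads()`).
4. **Alignment and classification** -- mapping against the reference plus
   the vector "dummy chromosome", then per-read ambiguity classification
   (`align_reads()`, `prefilter_hits()`, `classify_reads()`,
   `quality_filter()`).
5. **Locus merging** -- a 3-bp sliding window collapses redundant IS reads
   into distinct loci (`merge_loci()`).
6. **Annotation** -- nearest-feature assignment from a BED file
   (`annotate_loci()`).

The per-stage read sets are named as in the IS-analysis literature: **T**
(trimmed), **N** (unmapped), **LV** (vector-internal), **A** (ambiguous),
**U** (unambiguous), **R** (quality-passed redundant ISs), **L** (distinct
loci).  Every run satisfies the accounting identities
`|T| = |N| + |LV| + |A| + |U|`, `|R| = |U| - quality_discarded`, and
`sum(read_count over L) = |R|`; the test suite asserts them on every
fixture run.

## Trimming: finding the junction

The IS is the first host base after the LTR, so trimming is where mapping
precision is decided.  `find_ltr()` searches each read for the **last 63
nucleotides** of the configured LTR with a Smith--Waterman local alignment
(match +1, mismatch -1, gap open 2, gap extend 1; all configurable) and
accepts a match only when

* homology is at least **89%**, counted as alignment identities divided by
  the 63-base tail length -- i.e. at least `ceiling(0.89 * 63) = 57`
  identities.  The tail length is the conservative choice of denominator
  (an alignment-length denominator would let gapped alignments inflate
  their own score); with an LTR shorter than 63 nt the denominator scales.
* the final **3 bases** of the tail align gap-free and identically.  This
  perfect-end rule anchors the junction to single-base precision; a read
  whose last LTR base is miscalled is discarded rather than mapped one
  base off.

Reads without an acceptable LTR leave the pipeline (`no_ltr`): a read
without the junction cannot witness an IS, and aspecific amplification
products look exactly like LTR-less reads.  The LC is then searched with
the same machinery (89% homology over the full LC, no perfect-end
requirement -- the LC's boundary carries no positional information) and cut
away together with everything after it, but its *absence* never discards a
read, since short fragments legitimately run out before the cassette.
Finally, fragments shorter than **20 bp** are dropped (`too_short`):
they are too short to place uniquely on a mammalian-scale genome.

When one read contains several acceptable LTR matches the highest-scoring
one is used; exact score ties are resolved by the alignment engine.  These
thresholds (89, 3, 20) and the scoring parameters are all arguments with
the defaults above.

## Alignment and the ambiguity classifier

Trimmed fragments are aligned against the reference genome **plus the
vector genome appended as a dummy chromosome**.  Because both LTRs of an
integrated provirus are direct repeats, LAM-PCR also amplifies
vector-internal fragments; aligning against the vector alongside the host
genome catches them at alignment time, and any read with a vector hit is
labelled `LV` and removed from IS calling (a switch, `lv_any = FALSE`,
restricts `LV` to reads whose *best* hit is the vector).

The internal aligner is seed-and-extend -- exact 12-mer seeds from the
start, middle and end of the fragment nominate candidate windows on both
strands, each realigned with the same local aligner -- and is intended for
the desk-scale references the package targets (tens of kilobases).  Hits
from any external engine can be substituted through the conventional
12-column tabular format (`read_hits_tsv()`); all downstream logic is
engine-agnostic.  `align_reads()` processes reads in independent chunks
whose results are concatenated in input order, so output is invariant to
the chunk count -- the contract that replaces cluster-level distribution
while keeping results reproducible.

Hits are prefiltered: identity below **95%** or a query start beyond base
**3** disqualifies a hit (the junction can jitter by about +/- 3 bases, so
informative alignments begin at the fragment start).  For each surviving
hit the **homology score** is

    hs = 100 * |qs - qe| / read_length

the fraction of the read covered by the alignment, as a percentage.  The
numerator is deliberately the plain coordinate difference, one less than
the aligned span; `hs_inclusive = TRUE` switches to the `|qs - qe| + 1`
variant.  The difference is at most one part in 20 for the shortest
fragments that pass the length filter and vanishes with read length, but
the default follows the formula as conventionally printed so thresholds
calibrated against it transfer unchanged.

A read's hits are sorted by decreasing alignment score and the read is
**unambiguous (U)** iff the best hit beats the second best by more than
`as_t = 15` score units *and* by more than `hs_t = 20` homology
percentage points; otherwise it is **ambiguous (A)**, the fate of reads
from repetitive elements.  Two deliberate readings where the rule is
silent: a read with a *single* prefiltered hit is `U` (with no competitor
there is nothing to be ambiguous against), and exact score ties (perfect
repeats) sort deterministically by (subject, position) and necessarily
fail the gap test, yielding `A`.  Classification is invariant under
permutation of the hit list, which the suite checks property-style.

`U` reads then pass the final quality filter -- identity at least 95% and
`hs` at least 80% -- or are discarded; either failure suffices, the
stricter of the two possible readings of a conjunctive phrasing, and both
bounds are arguments.  Survivors form the redundant IS set **R**, and the
IS coordinate is the alignment's junction-side end: subject start on the
plus strand, subject end on the minus strand, so reads of different
lengths from one integration agree on the coordinate exactly.

## Locus merging

PCR and alignment jitter spread reads from one integration event over a
few neighbouring positions, so R-set reads are merged with a **3-bp
window**: per chromosome and strand, positions are sorted and the lowest
unassigned position `p` anchors a locus absorbing every read in
`[p, p + 2]`.  Windows are *anchored, not chained* -- positions
`{100, 102, 104}` yield loci at 100 (members 100 and 102) and 104, never
one locus smeared across 5 bp -- so any two loci on a chromosome/strand
are at least `window` bases apart, and `window = 1` degenerates to the
distinct position tuples.  Reads on opposite strands are never merged by
default (their junctions face opposite directions); `ignore_strand =
TRUE` gives the strand-blind behaviour for protocols where that is
preferred.  The per-locus read count is the integration's "signal power",
and `locus_offsets()` reports how reads distribute over the window
offsets -- the junction-precision profile of a run.

## Annotation

Each locus is associated with the closest feature(s) from a BED file
(0-based half-open, first six columns used, malformed lines rejected with
their line numbers).  "Closest" is measured to the **feature body** --
distance 0 inside the interval, otherwise the distance to the nearer
endpoint -- and *all* features at the minimal distance are reported, so an
IS exactly between two genes annotates to both.  The TSS distance is
reported separately: the TSS is the start of a plus-strand feature and the
last covered base of a minus-strand feature, and the signed distance is
positive downstream *in the feature's reading direction*, which is what
makes "upstream of gene X" biologically meaningful on either strand.  For
in-gene sites the integration percentage places the IS along the feature:
0% at the TSS, 100% at the opposite end, with denominator `length - 1` so
both endpoints map exactly (a single-base feature reports 0%).  The
percentage is invariant under mirroring the IS about the feature midpoint
while flipping the strand, a symmetry the suite checks on random
configurations.

## The synthetic-data generator

`make_reference()` + `make_reads()` (or the one-call
`simulate_dataset()`) generate the fixtures every stage is validated
against.  Reads have the real product structure -- barcode, the 63-nt LTR
tail verbatim, a genomic fragment from a planted coordinate in a planted
orientation, and optionally the LC -- with fragment lengths uniform on
100--1,000 bp, matching the LAM-PCR product-size range; smaller ranges are
used in unit tests purely to keep toy references small.  Planted sites are
drawn on a 10-bp grid so distinct ground-truth loci can never fall within
one merge window of each other.  Exact repeat blocks can be copied to
several locations to create genuinely ambiguous regions, and planting an
IS on the vector sequence produces vector-internal reads.  The error model
is substitutions at a per-base rate (indels separately configurable),
applied to the whole read -- the simplest model that exercises every
filter, including LTR rejection when an error lands in the final 3 bases.
One seeded RNG (`withr::with_seed`) drives the whole generator, so every
fixture is reproducible byte-for-byte.

What the generator does **not** emulate: platform-specific error profiles
(454 homopolymer errors, MiSeq quality decay), chimeric PCR products, PCR
duplication and clonal abundance skew, and genome-scale repeat structure
beyond planted exact copies.  Passing tests therefore demonstrate the
correctness of the decision rules and bookkeeping under controlled
conditions -- exact threshold behaviour, set-algebra conservation,
round-trip recovery of planted loci, known-miss behaviour for repeats and
vector reads -- not the sensitivity of the thresholds on real clinical
data, which depends on error profiles and the true repeat landscape.

## Numerical and design choices

* Alignment scoring: +1/-1 with gap open 2 / extend 1; `N` never matches,
  so undetermined bases cannot contribute identities.  Identity is
  gap-inclusive (identities / alignment columns), the convention of
  BLAST-style tabular output.
* All internal coordinates are 1-based inclusive (the tabular-alignment
  convention); conversion to 0-based half-open happens only at BED
  boundaries, in `load_bed()` and `loci_to_bed()`.
* Barcode lists are validated before any read is touched; nested tags
  (one a prefix of another) are rejected rather than resolved
  longest-match, since exact matching cannot disambiguate them.
* Paired-end merging requires a suffix/prefix overlap of at least 15
  bases at 95% identity (both arguments); within the overlap the
  LTR-containing mate wins disagreements, since it anchors the junction.
* Degenerate inputs: empty read sets, empty barcode tables, chromosomes
  without features, and empty loci all return empty tibbles with stable
  schemas rather than errors; an LTR ending at the last read base yields
  an empty fragment and falls to `too_short`.
* Test problem sizes: toy references of 2--25 kb, 60--200 reads per
  end-to-end case, 20 seeded pipeline runs for the conservation
  properties, 1,000 random cases each for the merging and annotation
  oracles -- sizes at which exhaustive brute-force oracles (full substring
  scans, all-pairs distance scans, direct greedy loops) are feasible and
  independent of the implementation under test.

## Limitations

The internal aligner is for desk-scale validation and toy references, not
genome-scale mapping; for real genomes, run an external aligner and feed
its tabular output to `read_hits_tsv()`.  Abundance estimation beyond raw
read counts (sonication-shear diversity, UMIs), cross-sample contamination
detection, and multi-source annotation joins are out of scope; the tool
annotates against one BED file per invocation.
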