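---
title: "Two-pass spliced alignment of noisy long RNA-seq reads"
author: "splicewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pass spliced alignment of noisy long RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Long-read RNA sequencing (PacBio, Oxford Nanopore) produces reads that span
many exons but carry per-base error rates between roughly 2% (PacBio
reads-of-insert) and 25% (ONT 1D). A spliced aligner must place each read
across introns, recover exon boundaries to a few bases, and do so when a
fifth of the bases are wrong. One-pass aligners decide each read's introns
from that read's own noisy matches; short exons (under ~31 bp) in particular
rarely carry enough anchor sequence in a single noisy read.

`splicewalk` implements a two-pass strategy. The first pass computes a cheap
*alignment skeleton* for every read; skeletons from the whole dataset are
pooled to infer the exonic regions of the genome; the second pass aligns each
read at base level against a *local spliced reference sequence* (LSRS)
stitched from the inferred exons. Evidence is thereby shared across reads:
an exon needs to be anchored by only some reads to become available to all of
them.

## Pipeline and model

### Genome index

The reference is indexed as a de Bruijn graph over all N-free genomic k-mers
(default `k = 22`). Unitigs -- maximal non-branching paths -- are extracted,
and each genomic position is assigned to a unitig offset. Occurrences are
stored as *runs*: maximal stretches of consecutive genome positions mapping
to consecutive unitig offsets, so the footprints of all runs cover every
N-free k-mer position exactly once, including partial occurrences at sequence
boundaries. An l-mer table (default `l = 15`) over the unitig sequences
serves first-pass seeding. Unitigs with more than `repeat_cap = 300`
occurrence runs are marked repetitive and their seeds are ignored. The index
is built on the forward strand only; reverse-strand reads are handled by
seeding the read's reverse complement.

### First pass: alignment skeletons

Seeds are sampled every `m = 5` bases, looked up in the l-mer table, and
extended base-by-base in both directions into unitig maximal exact matches
(U-MEMs). Co-linear same-diagonal U-MEMs on one unitig merge into SU-MEMs
(merge slack 2 bp), which are projected through the occurrence runs onto the
genome as match blocks (MBs). MBs form a DAG whose edges connect strictly
co-linear blocks with genomic gap at most `T_intron = 200000` bp; the edge
weight is the incoming block's (overlap-trimmed) length minus
`log2(1 + |genomic gap - read gap|)`, floored at 1. Sparse dynamic
programming returns the maximum-weight chain as the skeleton, plus any
non-overlapping chain within 5% of the best score (at most 5), mirroring
reads with several near-equal placements.

When the best skeleton anchors less than half of the read -- routine at high
error rates, where exact 15-mers are rare and stride-5 sampling misses many
of them -- seeding is retried at stride 1 and the better result kept.

### Exon inference

All skeletons are projected to a per-position coverage profile; gaps shorter
than 20 bp between consecutive MBs of one skeleton are counted as intra-exon
scoring gaps rather than introns. Runs of covered positions (merged across
gaps under 10 bp) become draft exons; drafts shorter than 10 bp or with mean
coverage below 1 are dropped. When a GTF annotation is supplied its exons are
injected as additional draft regions (never displacing read-derived ones).

Draft boundaries are refined with a donor/acceptor scoring model in windows
of half-width `W = 15`: a log-odds dinucleotide score (+1 per matching base,
-1 otherwise) rewarding AG immediately before the exon start and GT
immediately after its end, evaluated in both orientations (GT-AG and CT-AC)
with each boundary taking the better orientation. A positional taper anchors
the choice to the draft: candidates interior to the draft pay 0.05/bp for the
first 3 bp and 0.5/bp beyond (skeleton coverage overshoots a true boundary by
1-3 bp through chance matches, but larger interior shifts are almost always
wrong), while exterior candidates pay a flat 0.05/bp. The matrices are
replaceable from a TSV for non-canonical signals.

### Second pass: LSRS alignment

Per skeleton, read parts between neighboring MBs vote for "spanning exons"
inside the skeleton's genomic corridor: an exon is hit when an exact 8-mer of
the part occurs in its (10 bp-flanked) sequence; exons of 64 bp or more
facing long parts need two hits to damp chance matches. Anchor-overlapping
exons are always included; anchor MB footprints contribute only residual
pieces of at least 4 bp so that a chance 1-3 bp MEM overhang across a splice
junction cannot override a refined exon boundary. The selected segments are
stitched into the LSRS; terminal segments are padded 20 bp outward (free
under semi-global alignment, and they repair terminal exon boundaries that
refinement nudged inward).

The whole read (oriented per the skeleton strand) is aligned end-to-end
against the LSRS with affine-gap semi-global DP (match 2, mismatch -4, gap
open -4, extend -2; reference ends free). This deviates deliberately from
aligning each read part separately against partial LSRSs: a single whole-read
pass guarantees a total alignment and avoids stitching artifacts at part
boundaries; the per-part formulation is recovered implicitly because the DP
is free to spend each part's bases in its own segments.

Deletion runs of `D_min = 30` bp or more are excised from the LSRS (creating
a junction) and the read realigned, up to three rounds. The realignment is
adopted only if it outscores the original *after refunding the excised runs'
gap penalties* -- a deletion this large becomes an intron either way, and an
unrefunded comparison would let excision eat true exon sequence whenever the
first-round tail was misaligned.

Lifting to genome coordinates inserts an N operation at every crossed
segment junction. Three cleanups follow, all answering the same structural
fact that the DP treats segment junctions as free concatenations:

* **D absorption**: reference bases next to a junction that the read does
  not support (D runs adjacent to an N, possibly separated by a 1-3 bp
  chance-matched island) belong to the intron and are merged into the N.
* **Micro-exon cleanup**: exon segments of the final CIGAR carrying fewer
  than 8 aligned bases are spurious chance matches; internal ones are
  absorbed into the intron (query bases become insertions), terminal ones
  become soft clips.
* **Junction polishing**: each N flanked by M runs slides within a 16 bp
  window to the offset maximizing base matches plus a +3 bonus per matching
  canonical splice dinucleotide (GT..AG or CT..AC, either orientation),
  moving query bases between the flanking exons while keeping the intron
  length fixed. Small insertion runs stuck against a junction (query bases
  the LSRS had no room for) are first given intron reference to align to.
  Polishing recovers exact junctions per read even when the pooled inferred
  boundary was several bases off.

During development, three more aggressive junction rewrites (a pure-M
neighborhood rebuild, a two-segment mini-DP realignment, and an
outward-biased boundary prior) were each measured to *reduce* aggregate exon
accuracy on noisy data and were discarded; the conservative slide is the one
mechanism that never lost.

The highest-scoring candidate over all skeletons becomes the primary
alignment (ties to the leftmost coordinate); others are emitted as secondary
records. MAPQ is `min(60, floor(40 (s1 - s2) / s1) + 20)`, 60 for a unique
candidate, 0 on a tie. Reads without any skeleton are reported unmapped, so
read accounting stays closed.

## The synthetic-data generator

`gene_model_spec()` / `generate_genome()` lay out non-overlapping forward-
strand genes (optionally plus a nested antisense gene) with uniform-random
exon counts, exon/intron lengths and intergenic gaps; every intron carries
canonical GT..AG. A fraction of genes (default 0.5) receives a second
isoform skipping one exon, and a fraction (default 0.2) of genes with at
least 3 exons gets one short internal exon (20-30 bp), emulating the short
exons the two-pass design targets. Expression follows the benchmark's rule:
one isoform per multi-isoform gene is highly expressed (30x), the rest lowly
(4x), single-isoform genes highly.

Reads are drawn per transcript until cumulative bases reach depth x length.
Read length is gamma-distributed (CV 0.35 -- a closed-form stand-in for the
empirical long-read length spread) truncated at the transcript length; start
positions are uniform; strands 50/50. Errors are injected per base as
substitution / insertion / deletion in model-specific proportions (PacBio
25/45/30, ONT 40/25/35 -- approximations to published profile studies; both
configurable).

Four named models carry the benchmark's printed parameters: PacBio ROI (2%,
2000 bp), PacBio subreads (15%, 8000 bp), ONT 2D (13%, 7800 bp), ONT 1D
(25%, 7800 bp). The realized error rate is *measured* as unit-cost edit
distance divided by optimal-alignment columns; because dense error events
partially cancel in an optimal alignment (adjacent insertion/deletion pairs
realign as substitutions, inserted bases chance-match), the internal
event rate is calibrated at generation time: starting from the analytic
guess `q = e / (1 - e * p_ins)` (insertions add alignment columns), a fixed
random-sequence pilot is injected and measured, and `q` is refined
multiplicatively until the realized rate matches the nominal one. The pilot
RNG stream is fixed, so the calibrated rate is a deterministic function of
the model alone and simulation outputs remain byte-reproducible under a
seed.

Every read carries a truth record: its genomic exon intervals plus the exact
genome-oriented alignment CIGAR of the simulation, serialized as a plain
TSV. The CIGAR column exists because per-base accuracy (Base%) cannot be
evaluated for noisy reads from exon intervals alone.

What a green test on this generator does **not** establish: performance on
real genomes (repeat families, paralogs, GC structure, non-canonical splice
sites), realistic homopolymer-biased ONT error profiles, chimeric or
poly-A-carrying reads, or genome-scale index behaviour.

## Evaluation metrics

From truth: Base% (bases placed within 5 bp of truth; unaligned reads stay
in the denominator), Exon% (truth exons with both boundaries within 5 bp),
Read80%/Read100% (reads with true-positive exon fractions strictly above 80%
/ exactly 100% against both truth and prediction; predicted-to-truth exon
matching is greedy one-to-one in genomic order). From annotation: #BaseA,
#BaseGA, #ExonP, #ExonGO (at least 10 bp overlap), #ExonGA (both boundaries
within 5 bp), #ExonGA(x) (matched exons shorter than x bp), #ReadGA (every
junction boundary within 5 bp of an annotated exon boundary; junction-free
reads satisfy the condition vacuously, configurably). Only primary
alignments are evaluated.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based conversion happens
  only at the SAM/GTF boundary.
* A gap of length L costs `gap_open + L * gap_extend`.
* DP tie-breaking prefers diagonal (match) moves and the leftmost reference
  position; chain tie-breaking prefers the leftmost genome coordinate.
* Reads shorter than `l` yield no seeds and are reported unmapped.
* Splice refinement falls back to the draft interval whenever the refined
  donor would not lie beyond the refined acceptor; `W = 0` disables
  refinement.
* Alignment problems beyond ~3.2e8 DP cells are refused; the second pass
  retreats to anchor-only LSRSs if a corridor blows up.

## Known limitations

On this package's synthetic worlds (transcripts of a few hundred bases to a
few kb), absolute exon recovery at the ONT 1D error rate (25%) is low: such
a read offers only a few hundred 15-mer windows, of which about 1% are
error-free, so first-pass skeletons are sparse even with stride-1 rescue.
The depth-monotonicity property (more reads, better exons) still holds and
is what the tests assert. Read-level full-correctness metrics (Read80%,
strictly >80% of exons correct in both directions) are similarly punishing:
at 15% error a single boundary error anywhere in a 4-6 exon read fails the
read; the package reaches ~0.86 on its hardest internal fixture against an
internal target of 0.90, documented rather than tuned away.
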