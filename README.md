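# splicewalk

Two-pass spliced alignment of noisy long RNA-seq reads (PacBio / Oxford
Nanopore), in R.

Long RNA-seq reads span many exons but carry 2-25% base errors. One-pass
spliced aligners decide each read's introns from that read's own noisy
matches, which fails most often at short exons and exon boundaries.
`splicewalk` shares evidence across the dataset instead:

1. **Alignment skeletons** — each read's l-mer seeds (l = 15, every 5 bp)
   are matched to the unitigs of a reference de Bruijn graph index (k = 22),
   extended into maximal exact matches, projected onto the genome as match
   blocks, and chained by sparse dynamic programming into a maximum-weight
   co-linear skeleton (intron gaps up to T_intron = 200,000 bp).
2. **Exon inference** — skeletons from *all* reads (plus an optional GTF)
   are pooled into a genomic coverage profile; covered regions become draft
   exons whose boundaries are refined with donor/acceptor dinucleotide
   scoring (GT..AG / CT..AC).
3. **Refined alignment** — for each read the spanning exons are stitched
   into a local spliced reference sequence (LSRS); the read is aligned
   end-to-end against it with affine-gap semi-global DP, large deletions
   trigger LSRS excision and realignment, and the result is lifted to a
   spliced genome CIGAR (`N` introns) with per-read junction polishing.

The package ships a synthetic genome/transcriptome/long-read simulator with
four named error models — PacBio ROI (2%, 2000 bp), PacBio subreads (15%,
8000 bp), ONT 2D (13%, 7800 bp), ONT 1D (25%, 7800 bp) — with exact per-read
ground truth, and the full evaluation suite (Base%, Exon%, Read80%, Read100%,
#BaseA/#BaseGA/#ExonP/#ExonGO/#ExonGA(x)/#ReadGA), so the whole pipeline is
testable without downloads.

## Worked example

```r
library(splicewalk)

## a 20-gene synthetic world: 2-10 exons of 20-300 bp, introns 200-5000 bp
spec <- gene_model_spec(n_genes = 20, exon_count = c(2, 10),
                        exon_len = c(20, 300), intron_len = c(200, 5000))
g  <- generate_genome(spec, seed = 11)
tx <- make_transcripts(g$annotation, g$reference)

## 15% error PacBio-subread reads at uniform 30x
prof <- assign_expression(g$annotation, seed = 11, d_high = 30, d_low = 30)
sim  <- simulate_reads(tx, prof, error_model("pacbio-subread"),
                       g$annotation, seed = 13)

## two-pass alignment and evaluation against the ground truth
aln <- align_all(g$reference, sim$reads, pipeline_config())
sim_metrics(aln, sim$truth)
#> Base%: 0.9711  Exon%: 0.9474  Read80%: 0.8613  Read100%: 0.7903
```

Base%: 97.1% of read bases land within 5 bp of their true genome position.
Exon%: 94.7% of the exon instances carried by reads are recovered with both
boundaries within 5 bp. Read80%/Read100% count reads whose recovered exon
fraction exceeds 80% / equals 100% against both truth and prediction — the
strictest full-length measures. On error-free reads the same pipeline
reaches 1.0 on all four metrics.

The two-pass benefit is exposed directly: `pipeline_config(single_pass =
TRUE)` disables exon inference (LSRS = anchor blocks only). On a fixture
with short internal exons (< 31 bp) at 15% error and 30x, two-pass mode
recovers 143 short-exon instances within +-5 bp versus 17 in single-pass
mode.

A thin CLI over the same functions is installed at
`system.file("scripts", "splicewalk", package = "splicewalk")` with
`index`, `align`, `simulate` and `evaluate sim|anno` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch, the simulator-fidelity quantities: the mean
realized per-base error rate of each named error model (measured by banded
edit-distance alignment of 1000 simulated reads back to their source
transcripts, in %) and the mean read length of 1000 reads drawn from
transcripts long enough not to truncate the length distribution (in bp),
and writes them as JSON.
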