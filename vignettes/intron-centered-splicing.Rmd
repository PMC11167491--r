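---
title: "Intron-centered alternative splicing quantification with splicefreq"
author: "splicefreq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron-centered alternative splicing quantification with splicefreq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefreq)
```

## The model

Most genes express one predominant ("major") isoform. `splicefreq` measures
alternative splicing from the point of view of each *intron* rather than each
exon-skipping event: every intron in a species-level catalogue receives three
read counts in each RNA-seq sample,

* **Ns** — spliced reads whose splice junction matches the intron's two
  boundaries exactly (precise excision of the focal intron);
* **Na** — spliced reads supporting *variants* of the focal intron, i.e.
  reads whose junction shares exactly one of the two boundaries (alternative
  donor or acceptor);
* **Nu** — unspliced reads, co-linear with the genome, that span an
  exon–intron boundary with at least 10 bp aligned on each side. Both
  boundaries are counted additively, so a single read covering a short intron
  end to end contributes 2.

Two ratios summarize each intron:

$$\mathrm{RAS} = \frac{N_s}{N_s + N_a}, \qquad
  \mathrm{RANS} = \frac{N_s}{N_s + N_u/2}.$$

RAS contrasts the focal splicing event with boundary-sharing variants; RANS
contrasts it with intron retention. `Nu` is halved because a retention event
produces co-linear coverage at *both* boundaries of the same intron, so `Nu/2`
is an estimate of the number of retained molecules on the same scale as `Ns`.
Each ratio is reported only when its denominator reaches 10 reads; otherwise
it is `NA`. Under this convention RANS is a consistent estimator of the
true spliced fraction *f* of a junction: with `Ns ~ Binomial(d, f)` and two
boundary reads per retained molecule, `E[Ns + Nu/2] = d` and
`E[RANS] → f`.

Introns are then classified: **major-isoform** introns have both ratios
defined and above 0.5; **minor-isoform** introns have at least one defined
ratio at or below 0.5; everything else — including introns whose ratios are
undefined for lack of coverage — is **unclassified**. An undefined ratio can
satisfy neither the strict ">" of the major rule nor the "≤" of the minor
rule, so low-coverage introns fall to unclassified rather than being forced
into a class.

## From alignments to counts

The toolkit consumes spliced alignments (SAM/BAM, e.g. from HISAT2);
alignment itself is out of scope. Read-level filters keep only mapped,
primary, *uniquely mapped* records (NH tag equal to 1; when NH is absent a
MAPQ floor of 60 — the value HISAT2 gives unique alignments — stands in)
whose mismatch fraction `NM / aligned length` is at most 0.02. The
denominator is the aligned portion of the read (CIGAR M/=/X), not the full
read length: soft-clipped bases say nothing about the quality of the aligned
part, so this is the conservative reading. A switch
(`mismatch_denominator = "read"`) provides the full-length alternative.

Junctions are the `N` operations of the CIGAR string; each junction
observation carries its two *anchors*, the reference-aligned spans of the
read segments flanking the junction. Two anchor thresholds serve different
purposes:

* **discovery** of a new (unannotated) intron requires one observation with
  both anchors ≥ 8 bp *and* canonical splice-site dinucleotides — GT–AG,
  GC–AG or AT–AC — at the intron's ends in one orientation, which also sets
  the intron's strand;
* **quantification** (counting into `Ns`) accepts anchors ≥ 5 bp, because
  mis-assignment of a junction already present in the catalogue is much less
  likely than a spurious novel junction.

Junctions longer than 2 Mb are discarded as implausible introns. Annotated
introns (gaps between consecutive exons of any annotated transcript,
deduplicated per gene) always enter the catalogue, with or without RNA-seq
support, and are trusted even when their splice signal is non-canonical
(flagged `signal = "none"`).

Catalogue introns are assigned to genes when a flanking exonic position
(`start − 1` or `end + 1`) lies within 1 bp of an annotated exon boundary of
exactly one gene; introns matching several genes are kept but flagged
ambiguous and excluded from per-gene outputs. Within a uniquely assigned
gene, an intron inside the extreme CDS coordinates (minimum CDS start to
maximum CDS end across isoforms) interrupts the coding region; introns
strictly outside interrupt UTRs. An intron *straddling* a CDS extreme is
classified coding-region — only strictly upstream/downstream introns are
UTR-interrupting, which is the literal reading of the definition.

## Expression and sequencing depth

Gene expression uses a transparent union-exon FPKM: each gene's *exon
blocks* are the per-gene union of all annotated exon intervals across
isoforms, a read is assigned to the gene holding the majority (> 50%) of its
aligned bases within exon blocks, and

$$\mathrm{FPKM} = \frac{\text{assigned reads}}
  {\text{exonic kb} \times \text{assigned millions}}.$$

This deliberately avoids isoform-level deconvolution (as performed by e.g.
Cufflinks): per-isoform abundance is out of scope, and the union-exon
measure is fully auditable against per-base coverage. Cross-sample
summaries are the mean, the median, and a depth-weighted mean
("weighted FPKM", `Σ fpkm·depth / Σ depth`).

A sample's **sequencing depth** is the median per-base exonic coverage
across BUSCO genes (near-universal single-copy orthologs), which makes depth
comparable across samples and species regardless of annotation size. The
weight used in the weighted FPKM defaults to this depth; the total of
assigned reads is available as an alternative weight
(`weight = "total_assigned"`) since "sequencing depth" admits both readings.

## Saturation analysis

To ask how many samples are needed before major-isoform discovery
saturates, the per-sample count tables are subsampled: for each replicate a
random permutation of the samples is drawn and prefixes of length
`n = 1 … N` are analyzed, so subsets are *nested within a replicate* (each
prefix is a uniform draw of `n` distinct samples, and nesting makes
detected-intron monotonicity checkable); 10 replicates by default, a single
seed for the whole grid. For each subset, counts are summed, ratios and
classes recomputed on the sums (never averaged), and the pooled depth is the
BUSCO-median of the *summed* per-base coverage, not the sum of per-sample
medians. Discovered (unannotated) introns are kept only if some sample in
the subset contains a discovery-grade observation, so the catalogue is
consistent with what that subset alone could have produced; a flag restores
the full-catalogue behaviour.

## The synthetic-data generator

`simulate_genome_annotation()` and `simulate_reads()` build a fully
ground-truthed dataset: a random genome on one chromosome; genes of 2–5
exons (80–250 bp) separated by introns of 60–300 bp whose terminal
dinucleotides follow a configurable signal mix (default 96% GT–AG, 3%
GC–AG, 1% AT–AC, close to the canonical frequencies in well-annotated
genomes); ~40% of genes on the minus strand; CDS extremes leaving short UTR
margins in the terminal exons; a configurable fraction of genes flagged as
BUSCO orthologs (default 50%). Each intron draws a true spliced fraction
*f* uniformly from a configurable range. Reads are emitted pre-aligned as
minimal standard SAM: each of `per_intron_depth` transcript events is
spliced with probability *f* (one junction read, anchors ≥ 10 bp unless a
small short-anchor fraction is requested) or retained with probability
1 − *f* (one co-linear read over *each* boundary, so `Nu/2` matches the
retention count by construction). Optional alternative-donor variants
(shifted 12 bp into the intron, annotated on a second transcript or left
unannotated to exercise discovery) generate `Na`; optional decoy reads
(NH = 2, or mismatch fraction 3%) exercise the filters.

What the generator does *not* emulate: sequencing errors and quality
strings, GC and positional bias, paired-end fragments, expression
heterogeneity between genes, non-canonical real splice sites, overlapping
genes. Passing tests therefore demonstrate the correctness of the counting
and classification machinery under clean alignments, not robustness to
aligner artefacts on real data.

## Numerical and design choices

* Coordinates are 1-based, fully closed, everywhere (GFF3 convention); an
  intron's `start`/`end` are its first/last *intronic* bases.
* `Nu/2` is applied inside RANS only; the stored `Nu` is the raw additive
  count.
* Ties in read-to-gene assignment (two genes with equal exonic overlap) or
  sub-majority overlap leave the read unassigned rather than guessing.
* Mate pairs are treated as independent records; the generator is
  single-end and the counting semantics follow suit.
* Multi-junction reads contribute one observation to each junction they
  span cleanly — counting is per junction observation, not per read.
* Aggregation across samples is a field-wise sum with ratios recomputed on
  the sums; it is associative and commutative, so partial aggregates can be
  combined.
* Deterministic throughout: the only random number consumers are the
  simulator and the saturation subsampler, each governed by one explicit
  seed.

## Problem sizes used in the test-suite

The unit and acceptance tests run on simulated fixtures chosen to exercise
every code path at desk scale: 20 micro-fixtures of ≤ 5 genes / ≤ 200 reads
for the exact brute-force comparison of Ns/Na/Nu; an exhaustive
(Ns, Na, Nu) grid up to 30 per component for the ratio formulas and the
class partition; 200 introns at 200 events each for parameter recovery
(rank correlation of RANS with the true *f* > 0.95); a 20-sample dataset
for saturation monotonicity; 50 random sample partitions for aggregation
algebra; and 1000 random instances for the FPKM invariances. These sizes
are the package's own validation design: large enough for tight statistical
assertions, small enough that the whole suite runs in minutes.

## Limitations

The union-exon FPKM understates the expression of genes whose dominant
isoform uses a minority of the exonic bases. Gene assignment by the ±1 bp
boundary rule cannot place introns of entirely unannotated genes. `Na`
aggregates all boundary-sharing variants without distinguishing alternative
donors from acceptors or from exon skipping. The saturation analysis
reuses per-sample tables, so it cannot model batch effects between samples
beyond what the per-sample counts capture.
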