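---
title: "Structural classification of long-read isoforms and cross-group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural classification of long-read isoforms and cross-group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoclass)
```

## The problem

Long-read (PacBio/ONT) single-nucleus RNA sequencing yields full-length
transcript models that frequently disagree with the reference annotation.
`isoclass` answers two questions about a set of collapsed long-read isoforms
from a targeted panel of genes:

1. *Structurally*, how does each isoform relate to the reference
   annotation — and for isoforms using unannotated splice sites, what
   exactly is novel about each junction?
2. *Quantitatively*, how does isoform usage differ between condition
   groups and cell types — which genes switch their dominant isoform, and
   which proportion changes are statistically supported?

All coordinates inside the package are 0-based, half-open genomic
intervals; GTF and BED I/O convert at the boundary. This removes the
±1 bookkeeping that otherwise plagues splice-site comparisons.

## Structural categories

Categories are entirely **splice-defined**: only the ordered chain of
introns (junctions) matters, never the 5′/3′ end positions, because ends
vary with reverse-transcription truncation. Against the transcripts of the
assigned gene:

* **FSM** (full splice match): the junction chain equals a reference
  transcript's chain.
* **ISM** (incomplete splice match): the chain is a *consecutive* sub-run
  of a reference chain — a truncated read. Internal deletions are not ISM.
* **NIC** (novel in catalog): every splice site is known to the gene but
  the combination is new. Subtypes, checked in a fixed order:
  `full_intron_retention` (a query exon fully spans a reference junction
  together with both flanking exons), then `known_junction_combination`
  (all junctions known, chain novel), then `known_splicesite_combination`
  (a junction pairs known sites never joined in the reference).
* **NNC** (novel not in catalog): at least one splice site is absent from
  the gene's donor or acceptor set.

Two ordering decisions deserve note. First, full intron retention is
tested *before* the ISM rule: retaining the first or last intron of a
transcript leaves a chain that is formally a consecutive sub-run, but a
truncated read never spans a reference junction, so a junction-spanning
exon identifies retention, not truncation. Second, the universe of "known"
splice sites is the assigned gene's sites, not the genome-wide set — the
whole feature taxonomy below reasons within one gene's reference isoforms.

Monoexon queries carry no junctions, so the categories above do not apply
directly. The package uses a fixed, documented convention: a monoexon
query contained in a single reference exon is reported as ISM (a truncated
fragment); one spanning a complete reference junction is NIC full intron
retention; anything else overlapping the gene is `genic_other`. Queries
overlapping no gene are `intergenic` — with one important exception below.

Gene assignment picks the same-strand gene with maximal exonic base
overlap; ties fall back to shared splice-site counts, then lexicographic
gene id, and are flagged.

When a genome is supplied, isoforms whose introns do not start/end with
the spliceosomal motifs GT..AG, GC..AG or AT..AC (read in transcription
sense) can be removed; classification itself needs no sequence, so the
filter is optional.

## The seven NNC features

Each NNC isoform is annotated junction by junction. A splice site is
*novel* when its boundary coordinate is missing from the gene's donor (or
acceptor) set; novel sites are then located as CDS, UTR, intron or
intergenic. Seven features cover the pure cases:

| feature | novel sites | location | junction size |
|---|---|---|---|
| `alt3_junction` | acceptor | exonic | enlarges a reference junction |
| `alt5_junction` | donor | exonic | enlarges a reference junction |
| `cds_cds_junction` | both | CDS/CDS | intra-exonic (exitron when within one exon) |
| `cds_utr_junction` | both | CDS/UTR | intra-exonic |
| `utr_utr_junction` | both | UTR/UTR | intra-exonic |
| `partial_intron_retention` | one | intron | shrinks a reference junction |
| `novel_exon` | two | intron | splits a reference junction in two |

Novel exons are detected first: an internal query exon whose two boundary
sites are both novel and intronic, and which overlaps no reference exon,
consumes *both* of its flanking junctions. Without this precedence those
flanking junctions would each be mis-read as partial intron retentions.
Remaining junctions receive exactly one label each; several features can
coexist in one isoform, and a feature occurring at two distinct junctions
counts twice (distinct (junction, feature) pairs).

Patterns outside the pure cases — a novel intergenic site, or a junction
mixing a novel intronic with a novel exonic site — are labelled `complex`
and surfaced in the output rather than guessed. No NNC isoform is ever
silently feature-less.

### Priority rules for multi-transcript genes

Transcripts of one gene disagree about what a position is: CDS in one
isoform can be UTR (alternate start codon) or intron (skipped exon) in
another. Rather than labelling such sites arbitrarily, two fixed rules
apply: a position in the exonic CDS of *any* transcript is CDS; otherwise
a position exonic in *any* transcript is UTR. Intron and intergenic only
remain for positions outside every transcript's exons. Both rules are
baked into `label_position()`, so every downstream feature call inherits
them.

### Single-exon genes

A spliced (two-exon) isoform mapping to a single-exon gene has no known
sites to match and historically risked being discarded as intergenic. Here
such isoforms always classify as NNC, and their junction — two novel
exonic sites — receives the appropriate intra-exonic label. Within the
CDS this is an exitron: internal coding sequence spliced out of a
single-exon gene.

## The comparison layer

Molecules are identified by their (cell barcode, UMI, sample) triple;
duplicated triples count once, keeping the first-seen isoform assignment
(conflicts are tallied). Barcodes missing from the cell-type map
accumulate under cell type `NA` — reads from unassigned cell types remain
visible rather than vanishing.

**Proportions.** For each gene, isoform proportions are computed per
sample (summing to 1) and then averaged *unweighted* within each group:
samples first, then the mean. The alternative — pooling counts across a
group — would let a deeply sequenced sample dominate; it remains available
behind a flag, but the sample-then-average order is the default. Samples
with zero reads for a gene are excluded from the average (a zero vector is
not a proportion) and reported.

**Major-isoform switching.** The major isoform of a gene in a group is
the argmax of the group-mean proportions (ties broken lexicographically
and flagged). A switch event is a group pair whose major isoforms differ;
one event is emitted per unordered pair.

**ANOVA with Sidak correction.** Each isoform's per-sample proportions
are compared between every non-reference group and the reference (control)
group with a one-way ANOVA; the resulting p-values are Sidak-adjusted,
p* = 1 − (1 − p)^m. The family size m is the number of non-reference
groups *per isoform* (each condition versus control) — not all isoforms
jointly; the choice is configurable. Groups contributing fewer than two
samples, or comparisons with zero variance everywhere, are reported NA
rather than fabricating an F statistic. Because the comparisons share the
control samples they are positively correlated, and Sidak's correction is
exact only under independence; the realised family-wise type-I error
under a simulated null sits at or slightly below the nominal α, which is
the expected (conservative) direction.

**Intersections.** An isoform belongs to a group when its reads summed
over the group's samples reach `min_reads`; intersection counts partition
the detected isoforms by exact membership pattern (the cells of an UpSet
plot). The default threshold is 1 for membership and 2 for "unique novel
isoform" summaries, where requiring at least two supporting reads guards
against single-read artefacts.

**ORFs.** For novel isoforms, the longest ATG-to-stop open reading frame
over the three forward frames is selected (length in nucleotides including
the stop; ties to the smallest start; default minimum 75 nt, i.e. a
24-residue peptide).

## The synthetic study

Because the sequencing data this class of analysis is applied to is
access-controlled patient material, validation rests on a deterministic
generator (`fixture_spec()`, `generate_annotation()`, `plant_isoform()`,
`simulate_molecules()`) that emulates the study design rather than the
reads themselves:

* a multi-gene annotation in which multi-transcript genes contain
  exon-skipping transcripts with alternate CDS starts — so positions that
  are CDS-in-one/UTR-in-another and exonic-in-one/intronic-in-another are
  always present, exercising both priority rules;
* a configurable fraction of single-exon genes (default 0.2);
* planted query isoforms whose true category or feature set is known by
  construction, for every category and all seven features, including the
  single-exon-gene exitron and multi-feature isoforms;
* grouped molecule tables: four condition groups with five control and
  three samples per disease group (the study's design), eight cortical
  cell types, 25 barcodes per cell type per sample, 300 molecules per gene
  per sample, a 10% duplicate-injection rate to exercise deduplication and
  5% unassigned barcodes. Isoform abundances decay geometrically with
  rank (ratio 0.6), a typical shape for a dominant-isoform gene; planted
  switches shift a chosen isoform's expected proportion in one group,
  scaling the others down proportionally;
* genomes of uniform random sequence with every reference intron forced
  to the canonical GT..AG motif (strand-aware), which is all the canonical
  splice filter consumes.

The same seed always reproduces byte-identical files: one pseudo-random
stream per spec, consumed in a documented order.

What the generator does **not** emulate: sequencing error and chimeras,
transcript-length capture bias, barcode collisions and whitelist
correction, non-canonical splice motifs in the reference, inter-gene
overlaps and fusions, and any real biological effect sizes. Passing the
validation suite therefore demonstrates the correctness of the rules and
the statistics on clean structures, not robustness to noisy alignments —
which is the collapse pipeline's responsibility upstream.

## Validation problem sizes

The test suite checks the chain-matching classifier against an exhaustive
per-transcript oracle on 1,000 generated loci (2,000 random queries, zero
disagreements required); recovers 50 planted isoforms per feature across
10 seeds (3,500 plants, 100% exact recovery required); verifies the
single-exon-gene rule, both priority rules, strand-mirror invariance on
100 loci, and the junction-size directions on every plant; calibrates the
ANOVA+Sidak null (four groups of three samples, 2,000 replicates, the
family-wise rejection rate within two binomial standard errors of 0.05);
and requires planted proportion shifts of 0.3 to surface as switch events
in at least 95% of 40 seeds. `scripts/acceptance.R` recomputes all of
these quantities from scratch with a caller-supplied seed.

## Known limitations

* Antisense and fusion categories are out of scope; a query overlapping
  two genes is assigned to one by maximal exonic overlap.
* The "known splice site" universe is per-gene; a site annotated only in
  a neighbouring gene counts as novel here. Genome-wide universes would
  change NNC calls near overlapping loci.
* GFF3 input is not supported (GTF and BED12 only).
* The monoexon convention is a deterministic choice among reasonable
  options; monoexon-heavy data should be interpreted with that in mind.
* `complex` labels are deliberate refusals to guess; their junctions are
  reported for manual review.
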