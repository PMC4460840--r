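---
title: "Comparing rearranged and fragmented mitochondrial genomes with mitofrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rearranged and fragmented mitochondrial genomes with mitofrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Animal mitochondrial genomes are usually a single circular chromosome of
10–35 kb carrying a fixed cast of 37 genes (13 protein-coding genes, 22
tRNAs, 2 rRNAs) plus a non-coding control region. In a few insect lineages
— parasitic lice, booklice, and thrips — this architecture is unstable: gene
orders are heavily rearranged and the genome can fission into multiple
circles. mitofrag implements the comparative analyses used to characterise
one such case, the *Scirtothrips dorsalis* cryptic species complex, where one
member carries the ordinary unipartite genome and another a bipartite genome
whose second chromosome is a ~0.9 kb mini-circle carrying only *nad6* and
*trnC* together with near-identical paralogous copies of the control region
and *trnS1*.

Four analyses make up the workflow, each exercisable on synthetic genomes
with planted truth:

1. **Gene-order rearrangement classification** — signed, anchored
   linearization of each genome; adjacency (gene-boundary) algebra; and
   classification of differences into tRNA inversions, translocations, and
   chromosome fission with feature duplication.
2. **Homolog divergence** — pairwise global alignment of each named homolog
   with an explicit counting rule: every mismatch column is one difference,
   every maximal gap run is one difference regardless of length, and
   non-overlapping termini of tRNA alignments are ignored.
3. **In-silico PCR architecture test** — primer-site finding and amplicon
   prediction on circular templates, used to discriminate a unipartite null
   model from a bipartite mini-circle model by presence/absence of products.
4. **NGS error audit** — discrepancies between an NGS contig and a validated
   reference, classified by contig-terminal position and A/T homopolymer
   context, with raw and context-filtered error rates.

## The divergence statistic

For an alignment of homolog $g$ with $S$ mismatch columns, $G$ gap columns
and $I$ maximal gap runs, the package reports

$$ d_g = 100 \cdot \frac{S + I}{C - G + I} $$

where $C$ is the total column count. The numerator follows the source
convention (an indel is a single difference regardless of size); the
denominator — *effective columns* — is this package's choice, made so that
$d_g$ is invariant to indel length: a $k$-base indel contributes one
difference over one effective column for any $k$. For tRNAs, terminal
columns belonging to leading/trailing gap runs are removed before counting
(`trim_trna_termini()`), since tRNA boundary annotations differ between
genomes more than their sequences do.

Aggregates come in two modes: `pooled` (total differences over total
effective columns, weighting each homolog by its aligned length) and `mean`
(unweighted average of the per-homolog percentages). Re-aggregating the
published per-homolog table settles which one the original analysis used:
pooling the 38 printed values with typical insect gene lengths reproduces the
published 15.17 % (all homologs) and 16.22 % (protein-coding genes)
essentially exactly, while the unweighted means (12.2 %, 17.2 %) do not.
`pooled` is therefore the default, and both are always reported.

Alignment itself is standard global Needleman–Wunsch with affine gaps
(via `Biostrings::pairwiseAlignment`), defaults match +1, mismatch −1, gap
open −2, gap extend −0.5 (a gap run of length $k$ costs $-2 - 0.5k$). The
original analysis aligned sequences in an interactive contig editor with
unstated parameters, so the scoring here is a declared, configurable
stand-in; accession-derived divergences are therefore checked with a
tolerance (±0.5 points on aggregates) rather than exactly. The test suite
verifies the alignment score against exhaustive enumeration of all global
alignments on short sequences.

## Gene-order algebra and event classification

`extract_order()` rotates each circular chromosome so that the anchor gene
(*cox1*, the conventional start of mitogenome linearizations) comes first on
the + (majority-coding, "J") strand, flipping the chromosome if the anchor is
on the minority ("N") strand; anchor-less chromosomes (a mini-circle) are
normalized on their lexicographically smallest gene. Adjacencies are
*strand-blind* by default: the boundary between two genes is the unordered
pair of their names. This is deliberate — a gene inverted in place keeps
both its boundaries — and it is the only reading under which the five
published thrips gene orders share a 10-gene block (*trnY*–*atp6*)
containing *trnY* and *trnF*, which differ in strand between the two cryptic
species. Orientation is consulted only when calling inversions.

Paralogous duplicates are reduced to a *home* chromosome (the one carrying
the most genes) before adjacency analysis, so a mini-circle's recently
duplicated control-region copy does not fabricate breakpoints.

`classify_events()` proceeds in three steps, mirroring the restricted event
taxonomy appropriate to these genomes (no DCJ/HP distance machinery):

1. **Fragmentation/duplication** — chromosomes of one order with no
   counterpart in the other are fission products; their non-redundant genes
   form the fragmentation event, and copy-number gains ride along as a
   duplication sub-event.
2. **Translocations** — greedy removal of the gene whose deletion from both
   circles most reduces the symmetric difference of strand-blind adjacency
   sets, iterated until the sets agree (ties broken alphabetically; if no
   single gene is productive, candidate pairs are tried, which resolves
   two genes that exchanged places). Removed genes that were adjacent in
   both source orders are merged into a single moved-run event.
3. **Inversions** — once translocated genes are set aside, the residual
   orders share every boundary, so any remaining sign disagreement is an
   in-place inversion.

Doing inversions after translocations matters: a gene inverted next to a
translocated gene has different neighbours in the two full orders and would
otherwise be missed. On toy orders the classifier's event count is tested
against a breadth-first exhaustive search over single-gene operations. One
ambiguity is inherent and worth knowing about: a gene translocated across
exactly one neighbour is indistinguishable from that neighbour hopping the
other way; both are single-event explanations and the classifier picks
deterministically (alphabetically).

`shared_blocks()` intersects the strand-blind adjacency sets of any number
of orders and reports maximal runs of conserved boundaries, read along the
first order.

## The synthetic generator

The generator is first-class, tested code; it defines the study-like
conditions everything else is validated under.

* **Gene lengths** (defaults in `default_gene_lengths()`) are typical insect
  mitogenome values — *cox1* 1530 bp, *nad5* 1700 bp, tRNAs 65 bp, control
  region 330 bp, *nad6* 460 bp — chosen once so that the genome scale of the
  study emerges naturally: main chromosomes of ~14.5–15.4 kb and, after
  fission of {*nad6*, *trnC*} with duplicated {control region, *trnS1*}, a
  mini-circle of ~920 bp.
* **Composition**: sequence is i.i.d. with P(A)=P(T)=`at_target`/2 (default
  77 %, between the two published genome-wide values); the control region is
  generated A+T-enriched (+12 points, capped at 95 %) and carries a 14-nt
  T-stretch and an A+T-rich segment, the motifs that distinguish a true
  control region from other non-coding DNA.
* **Divergence planting**: substitutions with replacement bases drawn from
  the local equilibrium (conditioned on differing), so composition is
  approximately held. Because an optimal aligner re-explains some of a dense
  substitution load as indels, the planted count is *calibrated*: plant,
  re-align, measure with the package's own statistic, adjust, with rejection
  capped at 100 tries. Realized per-homolog divergence is contracted to ±1
  point of target (the tests assert this), limited by the granularity of
  short tRNAs (one difference on a 65-bp tRNA is ~1.6 points).
* **Contig errors** (`simulate_contig()`): per-site error probability is a
  base rate multiplied in the first/last 80 nt and in (or within one base
  of) A/T runs ≥ 8 nt; homopolymer errors are mostly single-base indels
  (run-length miscounts), other sites mostly substitutions. Defaults
  (base 0.005, terminal ×5, homopolymer ×6) echo the published enrichment:
  7 of 15 observed changes terminal, 11 of 15 in homopolymers. Planted
  changes are spaced ≥3 nt apart and indels are kept out of the outermost
  3 bases, so every planted change maps to one alignment-resolvable record;
  both choices are generator conveniences, not claims about real contigs.

What the generator does *not* emulate: codon structure and selection (genes
are i.i.d. sequence, so protein-coding geometry is name-deep), transfer-RNA
secondary structure, read-level sequencing (no FASTQ, no quality values,
no coverage variation), and recombination. Passing tests therefore show the
*analyses* are correct under controlled truth, not that real data will be as
clean. One visible consequence: heavy planted divergence (29 % on the
control region) slightly erodes its extreme A+T content, so the synthetic
mini-circle's composition sits near the published value but the genome-wide
A+T of the diverged lineage drifts ~1.5 points below its ancestor's target.

## In-silico PCR

Primer annealing is exact string matching (configurable mismatches, 3'
terminal base always exact) with no thermodynamics — the architecture
question is purely topological presence/absence, not melting behaviour.
All convergent site combinations under the size cap (default 5 kb, the
practical reach of standard PCR) are reported; on circular templates
products may traverse the origin, which is exactly how outward-facing
primers inside *nad6* amplify "the rest of the circle" and complete a
mini-circle. `architecture_test()` predicts each panel pair's
presence/size under both candidate architectures and returns the verdict of
the hypothesis matching every observation (sizes within ±10 %, gel
precision); if both or neither match, the verdict is `ambiguous` — the
all-products pattern that would suggest coexistence of both architectures.
The unipartite null model is built with `merge_minicircle()`, which
re-inserts the mini-circle genes at their proposed ancestral location using
the bipartite genome's own sequences, so the same primers anneal exactly
under both hypotheses.

## Error audit rules

`diff_contig()` aligns the contig globally against the (doubled, for
circular references) reference and collapses each maximal gap run into one
insertion/deletion record; alignments covering less than half the reference
are rejected. `classify_changes()` flags each change as *terminal* (contig
position within 80 nt of either contig end — measured on the contig, since
the effect is an assembly artefact of contig ends) and/or *homopolymer*
(reference footprint within, or adjacent to, an A/T run ≥ 8 nt; runs are
measured on the reference). "Adjacent" means one base by default
(`margin = 1`), a declared convention — indel placement inside a run is
alignment-ambiguous, so run-edge changes are still run-type errors; set
`margin = 0` to disable. The raw rate divides all changes by the reference
length (15/921 ≈ 1.6 %); the filtered rate keeps only changes explained by
neither context (3/921 ≈ 0.3 %), a residual-error estimate after
discounting the two known artefact classes.

## Data transcribed from the source study

`sd_gene_orders()`, `sd_divergence_table()` and `sd_audit_counts()` carry the
published comparison-table gene orders/strands, the 38 per-homolog divergence
percentages, and the 15/7/11/3 audit counts; these are inputs, available
without network access. The deposited sequence records themselves are not
redistributed: sequence-level checks against them run only if GenBank flat
files are placed under `inst/extdata/accessions/`. The gene orders of the
three previously sequenced reference thrips genomes are likewise not
reproduced in full anywhere in the text; `synthetic_reference_orders()`
provides clearly-labelled synthetic stand-ins constrained only by what is
reported (protein-coding/rRNA order and strand identical, differences
confined to tRNA translocations/inversions outside the conserved block), and
they support block-structure analysis only.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is fully deterministic
given it. The test suite generates genomes at full study scale (~15 kb, 38
features), recovers planted events over 150 random pairs (up to 4
non-overlapping events each), checks alignment scores against exhaustive
enumeration on sequences up to 6 nt (all 1–2-mer pairs exhaustively), and
runs 1,150 randomized contig audits on 200–400 bp circles; the whole suite
runs in about a minute on one CPU. The acceptance script
(`scripts/acceptance.R`) regenerates everything from scratch at the same
scales, with 60 random event-recovery pairs.

## Known limitations

* The event model is restricted to single-gene (or single-run)
  inversions/translocations, fission and duplication; it is not a
  rearrangement-distance method and does not infer event polarity or order
  along a phylogeny.
* Divergences are raw percent differences (as in the source analysis), not
  model-corrected evolutionary distances; no codon-aware alignment.
* The greedy translocation search is exact on the event densities tested
  (≤ 4 non-overlapping events; pair lookahead for exchanges) but is not
  guaranteed minimal for arbitrarily entangled rearrangements.
* Primer annealing ignores thermodynamics, so "product present" means a
  perfect (or within-mismatch-budget) site pair within the size cap.
* GenBank I/O supports the feature dialect used by organelle records (gene/
  CDS/tRNA/rRNA/D-loop/misc_feature keys; join-wrapped circular locations);
  it is not a general GenBank parser.
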