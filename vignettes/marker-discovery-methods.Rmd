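---
title: "Marker discovery and genotype analysis: models and methods"
author: "TranscriptMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery and genotype analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TranscriptMarkers)
```

# Scope and data model

TranscriptMarkers implements the computational core of molecular-marker
development from 454-style transcriptome sequencing of a panel of inbred
crop lines (the default panel names five winter rye lines: Lo7, Lo152,
Lo225, P87, P105). Four analysis tracks are covered:

1. **SSR mining** on line-specific assemblies, with mixed-motif merging
   and cross-line redundancy removal;
2. **SNP discovery** from a multi-line read pileup, with a
   probe-design filter ladder;
3. **genotyping-array statistics**: allele frequencies, residual versus
   expected heterozygosity under selfing, and an exact binomial excess
   test;
4. **homology post-processing**: best-hit filtering of tabular
   alignment-search output, contamination screening, and sliding-window
   density mapping onto a model-grass reference.

The central container is the `ContigSet`, a `DNAStringSet` with
per-contig provenance: which inbred lines and which assemblers
contributed constituents. Provenance drives two classifications used
when building a high-confidence consensus assembly: contigs are
*accepted* only when all required assemblers contributed (agreement
across independent assembly algorithms makes in-silico artefacts
unlikely), and contigs are *multi-line* when two or more lines
contributed. Because constituent membership of merged assemblies is not
generally recoverable from FASTA alone, provenance is injectable, either
as `key=value` tokens on the description line or as a sidecar TSV.

Coordinates are 0-based half-open everywhere internally; all report
output (VCF, MISA-like tables) is 1-based, as those formats require.

# SSR mining

`findSSRs()` reports all maximal perfect tandem repeats with unit
lengths 1--6 bp meeting a per-unit-length minimum repeat count. The
defaults (10, 6, 5, 5, 5, 5 repeats for mono- through hexanucleotide
units) follow the commonly distributed default parameter file of SSR
mining tools; all are configurable. Three normalisations make output
well-defined:

* **Primitivity** — a unit is never itself a repetition of a shorter
  unit, so a span explainable at two unit lengths is reported at the
  shortest primitive unit ((AT)~n~ rather than (ATAT)~n/2~).
* **Leftmost anchoring** — a maximal repeat region whose length is not
  an exact multiple of the unit admits several phases; the leftmost is
  reported, so each locus appears exactly once.
* **N handling** — N breaks repeats and never occurs in a unit;
  absence of evidence is not a base.

Mononucleotide motifs are detected but removed by
`dropMononucleotide()` before marker development, monomer-run length
miscalls being the dominant 454 sequencing error. `mergeMixed()`
implements the mixed-motif rule: motifs on one contig separated by less
than 100 bp collapse (transitively) into one `mixed` record. Because
every surviving inter-record gap is at least the threshold, merging is
idempotent.

`crossmatchNonredundant()` combines per-line SSR datasets. The
redundancy criterion is deliberately explicit, since locus identity
across de novo assemblies of different lines has no shared coordinate
system: two motifs are the same locus when (i) their canonical units
match — the canonical unit is the lexicographic minimum over all
rotations of the unit and of its reverse complement — and (ii) the
flanking context (default 50 bp per side) agrees at >= 90% identity
over >= 30 aligned bp on either side, by ungapped sliding comparison
(shifts up to 10 bp). Redundant groups keep the copy of a designated
reference line — chosen as the line with the richest SSR dataset —
and record all member lines. Primer design itself is out of scope; the
exported flanks feed external primer tools.

# SNP discovery

## Pileup

`buildPileup()` tallies read evidence per contig column and per line,
with lines resolved through SAM read groups. Deletion evidence is
attributed to every deleted column and insertion evidence to the column
left of the insertion point, so indel columns are well-defined point
features for the distance filter. Base evidence arising in the first 10
bases of a read is additionally tallied separately: 454 errors
concentrate at read starts, and this tally feeds an optional screening
proxy (below). CIGAR arithmetic is delegated to GenomicAlignments.

## Candidate calling

The caller is a transparent count-threshold model, not a Bayesian
posterior: a column is a candidate when at least two distinct bases
each have, in at least one line, >= 2 supporting reads
(`minReadsPerLineAllele`). Within a line, the major allele is called
homozygous when it carries >= 80% of the line's reads
(`1 - maxMinorReadFraction`, compared with `>=`), two alleles each
strictly above 20% with >= 2 reads give a heterozygous call, anything
else is a no-call. The boundary conventions (>= for the major
threshold, > for the minor) are fixed so behaviour at exact fractions
is deterministic. The design intent is that the scientific substance
lies in the *selection criteria*, which are explicit and testable,
rather than in caller internals.

## The filter ladder

`filterCandidates()` annotates each candidate with three distances and
sets flags; a candidate passes when no flag is set:

| criterion | flag | rule |
|---|---|---|
| bi-allelic | `not_biallelic` | exactly two supported bases |
| parent polymorphism | `not_parent_polymorphic` | some configured pair (default Lo7 x Lo225, P87 x P105) has opposite homozygous calls |
| homopolymer distance | `near_homopolymer` | strictly > 5 bp from the nearest run of >= 4 identical bases |
| indel distance | `near_indel` | strictly > 60 bp from the nearest indel column (>= 2 supporting reads) |
| contig-end distance | `near_contig_end` | strictly > 60 bp from either contig terminus |

Distances are measured in bp from the SNP column (itself excluded) to
the nearest base of the feature; all comparisons are strict, following
the `> 5` / `> 60` / `> 60` wording of the selection criteria. The
60 bp end margin is what guarantees `probeContext()` can always cut a
full 60 bp flank for array probe design; contexts are emitted as
`LEFT[A/G]RIGHT` with alleles in alphabetical order.

The homopolymer minimum run length defaults to 4 bp — the point where
454 length miscalls become common in the error literature — and is
configurable, since "homopolymer" has no universal length definition.
A column counts as an indel column from 2 supporting reads, the same
evidence bar as for alleles.

Manual inspection of assemblies (read viewers, haplotype plausibility)
is approximated by two automatable, individually toggleable proxies,
both off by default: `dropReadStartOnly` flags candidates whose minor
allele is supported exclusively by read-start evidence, and
`flagPhaseConflicts()` flags candidate pairs within a line whose
co-occurrence on reads implies three or more haplotypes — an inbred
line carries at most two, so a third indicates collapsed paralogs.
These are declared substitutes for by-eye curation, not a reproduction
of it.

# Genotype statistics

`cleanSnps()` removes assays with *strictly more than* 5% missing
calls. Allele frequencies use the allele-count formula
$f_A = (2 n_{AA} + n_{AB}) / (2 n_{called})$, which guarantees
$f_A + f_B = 1$. `frequencyHistogram()` bins are left-open and
right-closed with 0 assigned to the first bin, so counts are conserved
for any input in [0, 1].

Residual heterozygosity of a line is $n_{AB} / n_{assayed}$. The
expectation under selfing halves each generation:
$E[h] = (1/2)^s$ after $s$ selfing rounds. Generation labels parse as
`F<g>` with $s = g - 1$ (F1 is the initial cross; F7 means six rounds,
1.5625%, printed 1.6%) and as seed-increase notation `F<a>:<b>` with
$s = a - 1$ (F6:9 means five rounds, 3.125%, printed 3.1%): after the
generation-`a` single-plant selection, seed increase does not advance
inbreeding. Display rounding is half-up to one decimal (6.25 prints
as 6.3); raw fractions are always retained.

Excess heterozygosity is tested one-sided (greater) with the exact
binomial upper tail — the hypothesis is directional, residual
heterozygosity *exceeding* the selfing expectation, e.g. through
cross-pollination during line maintenance or collapsed paralogous loci
that mimic heterozygous calls. A two-sided variant is available by
flag. Star codes follow the conventional thresholds (* 0.05, ** 0.01,
*** 0.001). `poolSummary()` reports per-heterotic-pool means and the
fraction of SNPs monomorphic within a pool (all non-missing calls
identical and homozygous).

# Homology post-processing

`filterHits()` applies the conservative >= 70% identity / >= 30 bp
length cutoff and keeps one hit per query (maximum bit score, ties by
minimum e-value, then input order) — counting homologs, not HSPs.
`contaminationScreen()` discards a contig when a contaminant-database
hit is both significant (e-value <= 1e-20) and substantial (query span
>= 10% of contig length). The e-value direction is an interpretation:
read literally, the screening rule as usually stated would discard
contigs with *weak* contaminant hits, which would be nonsensical; the
implementation discards on strong evidence.

`windowDensity()` slides a 0.5 Mb window with a 0.1 Mb shift along
reference chromosomes. A hit is assigned to a window when its
subject-span midpoint falls inside — the midpoint rule makes
assignment unique, so with non-overlapping tiling the per-window counts
sum exactly to the number of mapped hits. Coverage is the union of hit
spans intersected with the window (never above 100%), densities are
extrapolated to hits/Mb, and windows whose assembly-gap (N) fraction
exceeds 60% are zeroed rather than reported as spuriously empty. Only
full windows are placed — `floor((L - window)/shift) + 1` per
chromosome — so every reported window has the same denominator; a
chromosome shorter than the window gets one truncated window.

# The simulator

`simulateStudy()` makes every pipeline testable hermetically, with no
external data or aligner. It emulates the study *design*, not 454
chemistry:

* transcripts of 300--3,000 bp; at most one planted SSR per transcript,
  rejection-sampled so that the SSR truth table is exhaustive (no
  background repeat above threshold);
* bi-allelic substitution SNPs at 0.002/bp (about one per 500 bp,
  a realistic divergence between inbred crop lines), each line
  homozygous, both alleles represented in the panel; at most one 1--3 bp
  insertion or deletion per transcript, carried by a random subset of
  lines, placed > 70 bp from transcript ends so that carrier evidence
  always reaches the 2-read bar at default coverage;
* reads of truncated-normal length (mean 216 bp, sd 20) at 5x per-line
  coverage, laid out as two end-anchored reads plus jittered systematic
  interior starts. The layout guarantees >= 2 overlapping reads per
  line at every position that can pass the contig-end criterion, which
  is what makes exact precision/recall statements meaningful rather
  than coverage-lottery outcomes;
* truth SAM alignments with per-line read groups and exact CIGARs
  derived from the planted variants, so no aligner enters the test
  loop;
* an optional error model with the two dominant 454 failure modes:
  substitution errors in the first 10 read bases and +/-1 bp length
  miscalls inside homopolymer runs.

What the simulator does *not* emulate: flowgram-level signal, quality
score realism, chimeric contigs, paralog collapse, or expression-driven
coverage variation. Passing tests on simulated data therefore
demonstrate correctness of the computational rules (detection,
distances, filters, statistics), not robustness to every artefact of
real 454 assemblies.

The genotype-matrix simulator draws per-SNP allele frequencies
uniformly on 0.1--0.9 (arrays are designed from discovered, hence
common, polymorphisms) and per-line calls with planted
residual-heterozygosity rates; the default 59-line panel carries a
27-line seed-parent pool at 5.5% and a 27-line pollen-parent pool at
11.5% alongside the five sequenced lines.

All generators are byte-deterministic under the configuration seed;
sub-generators derive their streams as fixed small offsets of it.

# Numerical and design choices

* **Strict boundaries everywhere the source rules say "more than"**:
  missing-data cleaning keeps exactly-5% columns; distance criteria
  require > 5 / > 60 / > 60.
* **Selfing arithmetic**: the model $E[h] = (1/2)^{g-1}$ for
  generation F~g~ is the self-consistent reading of the published
  generation table; informal statements of the form "after two cycles,
  12.5%" in the surrounding literature off-by-one this mapping
  (0.5^2 = 25%), and the package follows the formula, not the slogan.
* **Histogram edge values**: 0 and 1 are assigned to the first and
  last bins by the closed-boundary rule, so degenerate frequencies are
  never dropped.
* **Tie-breaks** in best-hit selection (bit score, then e-value, then
  input order) make `filterHits()` deterministic and idempotent.
* **Problem sizes** used by the shipped checks: 200 transcripts x 5
  lines at 5x for the end-to-end SNP study, 1,000 random 500 bp
  sequences for the SSR oracle comparison, 400-hit tracks on two
  synthetic chromosomes for window conservation. These sizes give
  hundreds of truth SNPs and stable run times on a laptop-class
  machine.

# Known limitations

* The caller is count-based; it does not model base quality or
  sequencing-error posteriors, and very low-coverage columns simply
  yield no-calls rather than calibrated uncertainty.
* Cross-assembly SSR redundancy uses flank identity, which can split a
  true locus whose flanks diverged by indels (the comparison is
  ungapped) and cannot merge loci whose flanks were truncated below
  30 bp.
* Parent-polymorphism requires clean opposite homozygous parents; a
  heterozygous sequenced parent removes the candidate even if the
  population would segregate.
* The window-density "percent coverage" is window-denominated; a
  gene-model-denominated variant is not implemented.
* `expectedHeterozygosity()` assumes strict self-fertilisation with no
  selection against heterozygotes.
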