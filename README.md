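# TranscriptMarkers

Marker discovery and genotype analysis for multi-line transcriptome
assemblies of inbred crop lines.

When a crop species has no reference genome, molecular markers are
developed straight from de novo transcriptome assemblies: microsatellites
(SSRs) are mined from line-specific assemblies, and SNPs are discovered by
piling up reads from several inbred lines onto a joint assembly and
filtering candidate columns hard enough that the survivors work as
genotyping-array probes. TranscriptMarkers implements that computational
pipeline for a five-line inbred panel design (454-style reads, lines such
as Lo7, Lo152, Lo225, P87, P105), plus the statistics used to evaluate the
resulting array on a breeding panel, and the homology post-processing used
to place contigs on a model-grass genome.

## What it computes

* **SSR mining** — all maximal perfect 1–6 bp-unit repeats above
  per-unit-length repeat thresholds (defaults 10/6/5/5/5/5), primitive
  units, mixed-motif merging for repeats closer than 100 bp, and
  cross-line redundancy removal: two motifs are the same locus when their
  canonical units (minimum over rotations and reverse complement) match
  and their 50 bp flanks agree at ≥ 90% identity over ≥ 30 bp.
* **SNP discovery** — per-line pileups from SAM read groups, a
  transparent count-threshold caller (allele supported at ≥ 2 reads in
  some line; within-line homozygous call at ≥ 80% of reads), and the
  probe-design filter ladder: bi-allelic, polymorphic between the parents
  of a mapping population (Lo7 × Lo225 and/or P87 × P105), distance to
  homopolymer runs > 5 bp, to the nearest indel column > 60 bp, to the
  contig end > 60 bp. Passing SNPs get 125-character probe contexts
  `LEFT[A/G]RIGHT`.
* **Genotype statistics** — for an AA/AB/BB call matrix: cleaning of
  assays with > 5% missing data, allele frequencies
  f_A = (2·n_AA + n_AB)/(2·n_called), left-open/right-closed frequency
  histograms, residual heterozygosity n_AB/n_assayed per line, its
  expectation (1/2)^s after s selfing generations (F_g ⇒ s = g−1,
  F_a:b ⇒ s = a−1), and a one-sided exact binomial test for excess
  heterozygosity with \*/\*\*/\*\*\* codes.
* **Homology post-processing** — 12-column tabular hits: ≥ 70%
  identity / ≥ 30 bp best-hit filtering, contamination screening
  (e ≤ 1e−20 and ≥ 10% of contig covered), and 0.5 Mb / 0.1 Mb
  sliding-window hit densities with 60% N-masking and hits/Mb
  extrapolation.
* **Simulation** — a deterministic generator of transcripts with planted
  SSRs/SNPs/indels, per-line 454-style reads with truth SAM alignments,
  and genotype matrices with planted pool-level heterozygosity, so every
  pipeline is testable without any external data.

## Worked example

Per-line heterozygosity report from heterozygous/assayed locus counts of
a genotyped five-line panel (bundled fixture):

```r
library(TranscriptMarkers)
counts <- read.delim(system.file("extdata", "rye5k_line_counts.tsv",
                                 package = "TranscriptMarkers"))
heterozygosityReport(counts)
#>   line_id total het generation observed_pct expected_pct      p_value stars
#> 1     Lo7  3145 141         F7          4.5          1.6 2.899735e-27   ***
#> 2   Lo152  3133 128         F7          4.1          1.6 1.622865e-21   ***
#> 3   Lo225  3134 147         F7          4.7          1.6 2.556539e-30   ***
#> 4     P87  3148 151      F7:10          4.8          1.6 4.082829e-32   ***
#> 5    P105  3127 139       F6:9          4.4          3.1 3.673477e-05   ***
```

Observed residual heterozygosity (e.g. 141/3145 = 4.5% for Lo7) exceeds
the selfing expectation (1/64 = 1.6% after six rounds) in every line,
each with a vanishing one-sided exact binomial p-value.

A full simulated study, SNP discovery and probe design:

```r
cfg <- simulationConfig(seed = 42, nTranscripts = 20)
sim <- simulateStudy(cfg, dir = tempfile())
res <- discoverSnps(sim$paths$sam, sim$reference$contigs)
res$funnel
#>                    detected          flag_not_biallelic
#>                          55                           0
#> flag_not_parent_polymorphic       flag_near_homopolymer
#>                          12                           7
#>             flag_near_indel        flag_near_contig_end
#>                           0                           4
#>                     passing
#>                          36
cand <- res$candidates[res$candidates$pass, ][1, ]
probeContext(cand, contigSeqs(sim$reference$contigs)[[cand$contig_id]])
#> "CGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGA[G/T]AGC..."
```

Of 55 detected candidate columns, 36 survive the filter ladder (a
candidate can carry several flags); each survivor yields a 60 bp-flank
probe context with alleles in alphabetical order.

A command-line wrapper covering the same pipelines
(`simulate`, `ssr`, `snp-discover`, `geno-stats`, `homology`, `density`)
ships in `inst/scripts/markertools.R`:

```sh
Rscript inst/scripts/markertools.R geno-stats \
    --counts inst/extdata/rye5k_line_counts.tsv --out report.tsv
```

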