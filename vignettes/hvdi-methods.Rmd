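---
title: "Estimating phage community diversity with the Homologous Virus Diversity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phage community diversity with the Homologous Virus Diversity Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hvdi)
```

## The estimation problem

Shotgun sequencing of purified virus-like particles yields reads from phage
communities whose members are mostly absent from reference databases, so
relative abundances cannot be obtained by read classification. The
alternative is the **contig spectrum**: assemble the reads, count how many
reads each contig absorbed, and treat that multiset of counts as a
surrogate for the community's abundance structure. Two failure modes bias
diversity estimates computed from contig spectra:

1. **Assembly splitting.** Reads from one viral genotype can end up in
   several contigs (coverage gaps, strain microheterogeneity, assembler
   branch ambiguity). Each extra contig looks like an extra genotype, so
   richness and Shannon diversity are overestimated.
2. **Undersampling.** Genotypes sequenced at depths near zero appear as
   one-read contigs or not at all.

The **Homologous Virus Diversity Index (HVDI)** addresses the first
problem: before applying a diversity statistic, contigs that align to one
another with very high similarity (E-value below $10^{-20}$ over at least
half the length of the shorter contig) are merged into single *viral
genotypes* by single linkage, and their read counts are summed into a
**corrected contig spectrum**. The HVDI is then the Shannon index
$H = -\sum_i p_i \ln p_i$ (or, for rarefaction, the Chao1 richness
estimate $S_{obs} + F_1^2 / 2F_2$) computed on the corrected counts.
Pielou evenness $J = H / \ln S$ accompanies every Shannon value; natural
logarithms are used throughout because the evenness definition forces
them.

## Pipeline stages and their contracts

`run_pipeline()` wires the stages in order; each is exported on its own.

**Simulation** (`generate_genome_pool()`, `construct_abundance_profile()`,
`sample_reads()`). Synthetic double-stranded DNA phage genomes are i.i.d.
uniform over A/C/G/T at a target GC content. This is deliberate: i.i.d.
genomes share essentially no 25-mers (the maximum pairwise shared 25-mer
fraction is reported on every pool), so simulated genotypes are perfectly
separable and any contig splitting observed downstream is attributable to
coverage, not to sequence similarity between genotypes. Real phage genomes
share modules and mosaic regions; the simulator therefore bounds the
*best case* for the clustering correction, and passing validation on it
does not certify behavior on communities of closely related strains. A
FASTA loader (`load_genome_pool()`) accepts real genomes when that matters.

Abundance profiles follow a one-parameter geometric family
$p_i \propto r^{i-1}$, $r \in (0, 1]$. Achieved evenness is continuous and
strictly increasing in $r$, from near 0 to exactly 1 at the uniform limit,
so a requested Pielou evenness is solved by root bracketing
(`uniroot`, tolerance $10^{-12}$ on $r$; the profile must land within
0.01 of the target or the solver errors out). The geometric family is our
choice; the construction of profiles "to meet specific evenness
requirements" is not otherwise operationalized in the literature this
package follows, and a one-parameter family makes the solver monotone and
auditable.

Reads have lengths from a discretized normal (mean 200 nt, sd 25 nt)
truncated by rejection to [150, 250] nt — the truncation is symmetric, so
the mean stays 200 nt. Source genotypes are multinomial in the profile,
start positions uniform over positions where the read fits (genomes are
linear; reads never wrap), strands uniform. Optional artifact models
(per-base substitutions, injected homopolymer runs, injected `N`s) exist
solely to exercise quality control and default to off. The per-read
ground truth and the realized per-genotype read counts
(`truth_spectrum`) are always retained.

**Quality control** (`filter_reads()`). Reads shorter than 50 nt or longer
than 300 nt, reads containing a run of 8 or more identical bases, and
reads with non-ACGT characters are removed, categorized by the first
failing rule in that order. Platform-specific quality trimming (the
semiconductor-sequencing workflow this replaces used a proprietary
modified-Phred trim) is intentionally not reproduced; these deterministic
filters are the package's substitute, and that is a documented limitation
rather than an equivalence claim.

**Assembly** (`assemble()`). A deterministic greedy
overlap-layout-consensus assembler. Candidate overlaps are seeded by exact
25-mers (both strands, every position indexed; the query scan is thinned
to a step that still guarantees a seed inside any acceptable overlap of
error-free reads). An overlap is accepted only when its ungapped identity
is at least 0.98 **and** its length is at least
$\max(25, 0.5 \times \text{shorter read length})$ — the published
thresholds this package reimplements. Accepted overlaps are processed
longest first (ties: higher identity, then lexicographic read ids), each
merge placing the two reads' contigs into a common coordinate frame via a
union–find structure with orientation-aware offset transforms. The
consensus is called per column by majority over all member reads, with
the alphabetically first base on ties; contigs shorter than 200 nt, with
ambiguous consensus columns, or holding a single read are demoted to
unassembled singletons. Coordinates are 0-based half-open, strands
`+`/`-`.

Numerical/engineering choices worth knowing:

* Overlap evaluation is ungapped. The default simulations are error-free
  and the optional error model is substitution-dominated, so gapped
  (banded) extension would change nothing while costing determinism
  scrutiny. With indel-rich real reads the assembler will fragment more;
  that is out of the simulator's scope.
* Two work caps bound the quadratic cost of very deep coverage piles:
  per read and orientation at most 4096 raw seed candidates are collected
  and 512 distinct (partner, offset) pairs evaluated, and at most 128
  accepted overlaps are stored per read. The caps are deterministic
  (applied in scan order) and only bind where coverage is so deep that
  connectivity is massively redundant; junctions at low local coverage
  are never capped.
* `contig_spectrum()` counts unassembled singleton reads as weight-1
  units by default (`include_singletons = TRUE`), so the spectrum total
  equals the retained read count.

**Genotype clustering** (`contig_similarity_search()`,
`correct_contig_spectrum()`). The similarity engine is an ungapped
seed-and-extend local aligner (exact 13-mer words, X-drop 30, match +1 /
mismatch −2) with Karlin–Altschul E-values over a search space of query
length × total subject length ($\lambda \approx 1.332$ solved from the
score distribution at uniform composition, $K = 0.621$). It reproduces
BLASTN-like decisions for the near-identical alignments that matter here
(the test suite cross-checks it against command-line BLASTN), and it is
pluggable: any tool emitting the standard 12-column tabular format can
stand in. Clustering is single linkage — connected components of the hit
graph — because "assigned to the same genotype" does not specify a
linkage and single linkage is the only one invariant to hit direction.
Within-sample clustering uses E < $10^{-20}$; cross-virome comparisons
(`cross_sample_shared_fraction()`) use E < $10^{-10}$, and the
50 %-of-shorter coverage requirement is applied there too (exposed as a
flag; the symmetric default keeps the two thresholds comparable).

**Diversity** (`shannon_index()`, `pielou_evenness()`, `chao1_index()`,
`hvdi()`, `rarefaction_curve()`). Zero counts are ignored by the Shannon
index; evenness at $S_{obs} = 1$ is reported as `NA` (flagged) rather
than 0 or 1, since $\ln 1 = 0$. Chao1 uses the classic form when
doubletons exist and the bias-corrected form
$S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$ when $F_2 = 0$, avoiding division
by zero. Rarefaction subsamples reads without replacement at depths
$\{500, 1000, 2000, 5000, 10000, 20000\}$ (clipped to the sample size),
reassigns each subsampled read to its genotype via the full-data
assembly-plus-clustering assignment, and reports mean ± sd of the
Chao1-based HVDI per depth; at full depth it reproduces the non-rarefied
estimate exactly.

**Community comparison** (`permutation_shared_test()`,
`assembly_membership_matrix()`, `bray_curtis_matrix()`, `pcoa()`).
The shared-contig permutation test draws, per iteration, one random
within-group virome pair and one random between-group pair, computes each
pair's shared fraction on freshly sampled contigs (1000 by default, with
replacement only when a virome has fewer), and reports the fraction of
iterations in which the between-group value is at least the within-group
value — the `paired` scheme, with `>=` chosen conservatively. Because the
original description is ambiguous about the pairing, a `label_perm`
scheme is also provided: the observed statistic is the mean within-group
minus mean between-group shared fraction, the null is built by permuting
virome group labels, and $p = (1 + \#\{null \ge obs\}) / (B + 1)$. The
two schemes answer subtly different questions: under a fully exchangeable
null the label-permutation p-value is approximately uniform (a property
the test suite checks), whereas the paired p-value concentrates near 0.5
— it estimates $P(\text{between} \ge \text{within})$, which is a
description of effect size, not a calibrated test level. Same-subject
pairs are excluded when subject labels are given.

Bray–Curtis distances are delegated to `vegan::vegdist` (cells where both
profiles are all-zero are undefined and flagged `NA`). PCoA is classical
metric scaling — double-centering of $-D^2/2$ and eigendecomposition —
implemented directly so that negative eigenvalues are reported (as a
`negative_fraction`) instead of silently dropped; `stats::cmdscale` is
the independent oracle for it in the tests.

## The validation grid and its coverage regime

`run_validation_grid()` reproduces the method-validation design: simulate
viromes at every combination of genotype richness
$S \in \{10, 50, 100, 500, 1000\}$ and evenness target
$\{0.10, 0.33, 0.50, 0.67, 0.90\}$, run the full pipeline, and compare
the Shannon-form HVDI against the true Shannon index of each virome's
realized genotype read counts (the realized counts, not the constructed
proportions, because the HVDI can at best recover what was actually
sampled). Both genome pools and abundance-to-genotype assignments are
redrawn per replicate.

The package's default problem sizes are a desk-scale miniature: 10-kb
genomes, 20,000 reads per virome (the rarefaction ceiling), grids
restricted to $S \le 100$, three to ten replicates per cell. At these
sizes the whole grid runs in minutes on one CPU.

One behavior of the estimator deserves emphasis, because the validation
grid computes it directly. The clustering correction can only merge
contigs that *share sequence*; disjoint fragments of one genome produced
by coverage gaps share nothing and stay separate genotypes. Fragmentation
is governed by coverage: a genotype at proportion $p$ sequenced with $n$
reads of length $\bar L$ over a genome of length $G$ has expected depth
$c = n p \bar L / G$, and gaps longer than a read minus the minimum
overlap appear at rate $\propto e^{-c/2}$. Consequently the HVDI is
well calibrated when most abundance mass sits at depths of roughly 10×
and above, and it inflates — predictably, and worst at low evenness,
where rare genotypes are far below 1× — when it does not. The pipeline
reports the expected minimum coverage per cell and flags shortfalls; the
end-to-end test asserts the 12 % calibration at a coverage-adequate
configuration, and the acceptance grid at 20,000 reads per virome
quantifies the inflation in the starved cells. Users estimating diversity
from real viromes should read the rarefaction curve and the singleton
fraction before trusting a point estimate.

```{r grid}
grid <- run_validation_grid(genotype_counts = c(10, 50, 100),
                            evenness_targets = c(0.33, 0.50, 0.67, 0.90),
                            reps = 3, reads_per_virome = 20000, seed = 1)
attr(grid, "cells")
```

## Reproducibility

Every stochastic stage consumes a seed derived from one master integer by
a counter-based fan-out (`derive_seed()`), so a `(config, seed)` pair
reproduces every artifact byte for byte; pipeline outputs are stamped
with an MD5 hash of the configuration (excluding the output directory).
The C++ core contains no randomness and breaks all ties by explicit rank
order. `generate_fixture_set()` emits the deterministic FASTA/TSV
fixtures used by the test suite; a thin command-line wrapper
(`inst/scripts/hvdi-cli.R`) exposes the stages as subcommands for shell
use, with the multi-virome comparisons remaining R-level functions.

## Known limitations

* The simulator's i.i.d. genomes cannot probe the correction's behavior
  on mosaic or closely related phage genomes, where single-linkage
  merging may over-collapse genuinely distinct genotypes.
* Quality trimming is replaced by deterministic filters; indel-rich
  platforms will fragment more than the substitution-only error model
  suggests.
* The assembler is a faithful, auditable realization of the published
  identity/overlap thresholds, not a de Bruijn graph; at very low
  coverage it reports the information-theoretic fragmentation floor of
  those thresholds (the tests verify its unit counts against the true
  positional overlap graph).
* Chao1 confidence intervals and other diversity families (Simpson, Hill
  numbers) are out of scope; replicate standard deviations are the only
  uncertainty reported.
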