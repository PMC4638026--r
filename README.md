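# hvdi — Homologous Virus Diversity Index for shotgun viromes

Most bacteriophages in shotgun viromes have no database relatives, so
community diversity must be estimated directly from assembly structure:
the **contig spectrum**, the multiset of read counts per assembled contig,
stands in for the community's abundance profile. Assembly limitations
split single viral genotypes across several contigs and inflate apparent
richness. The **Homologous Virus Diversity Index (HVDI)** corrects for
this by merging contigs with very high sequence similarity (E-value
< 10⁻²⁰ over ≥ 50 % of the shorter contig, single linkage) into single
viral genotypes, summing their read counts into a *corrected contig
spectrum*, and applying a diversity statistic to the corrected counts:

- Shannon index **H = −Σ pᵢ ln pᵢ** (natural log), with Pielou evenness
  **J = H / ln S**;
- Chao1 richness **S₁ = S_obs + F₁² / (2 F₂)** (bias-corrected when
  F₂ = 0), using singleton (F₁) and doubleton (F₂) contigs, for
  rarefaction analysis.

The package is a complete, tested implementation of that methodology for
people studying phage communities in feces, chemostat cultures and
similar ecosystems:

- a **virome simulator** with controlled genotype richness and Pielou
  evenness (geometric abundance family solved for a target `H/ln(S)`),
  read lengths 150–250 nt (mean 200), full ground truth;
- **read QC** (length, homopolymer and ambiguity filters);
- a deterministic greedy **overlap-consensus assembler** honoring the
  98 % identity / 50 % read-overlap / 25-nt minimum-overlap thresholds,
  with majority-rule consensus (Rcpp core);
- **genotype clustering** via an ungapped seed-and-extend similarity
  engine with Karlin–Altschul E-values (BLASTN-compatible decisions;
  cross-checked against BLAST+ in the tests);
- **diversity**: Shannon, evenness, Chao1, rarefaction curves, and the
  HVDI-versus-true-Shannon validation grid;
- **community comparison**: shared-contig permutation tests, global
  assembly membership/persistence matrices, Bray–Curtis distances and
  PCoA.

## Worked example

Simulate a five-genotype virome at evenness 0.9, run the pipeline, and
compare the HVDI with the true Shannon index of the realized read counts:

```r
library(hvdi)

pool    <- generate_genome_pool(5, c(5000, 5000), seed = 1)
profile <- construct_abundance_profile(5, 0.9, seed = 1,
                                       genotype_ids = names(pool))
print(profile)
virome  <- sample_reads(pool, profile, 5000, seed = 1)
qc      <- filter_reads(virome)
print(qc$report)
asm     <- assemble(qc$reads)
print(asm)
spec    <- contig_spectrum(asm)
hits    <- contig_similarity_search(contig_sequences(asm),
                                    contig_sequences(asm))
corr    <- correct_contig_spectrum(spec, hits)
hvdi(corr)
shannon_index(qc$reads$truth_spectrum)
```

which prints

```
abundance_profile: S = 5, target evenness 0.900, achieved 0.9000 (r = 0.654483)
qc_report: 5000 reads in, 4985 retained (0 short, 0 long, 15 homopolymer, 0 ambiguous removed)
assembly_result: 4985 reads -> 6 contigs (4985 reads) + 0 singletons
  contig lengths 204-4999 nt, max read count 1926
diversity_result (shannon): H = 1.4522, S_obs = 6, evenness = 0.8105, chao1 = 6.00 (F1 = 0, F2 = 1)
[1] 1.449824
```

Reading this: the evenness solver hit the 0.90 target exactly; QC removed
15 reads containing chance 8-base homopolymer runs; the assembler
reconstructed the five genomes (one genome split into a long contig plus
a 204-nt terminal fragment, hence six contigs); and the HVDI (1.4522)
agrees
with the true Shannon index of the sampled community (1.4498) to within
0.2 %. At 5000 reads over five 5-kb genomes the rarest genotype still has
~26× expected coverage — the calibration regime. As coverage falls, the
HVDI inflates predictably (disjoint fragments of one genome cannot be
merged by sequence similarity); `run_validation_grid()` quantifies this
and flags coverage shortfalls per cell.

An end-to-end driver (`run_pipeline()`), a fixture generator
(`generate_fixture_set()`) and a shell wrapper
(`inst/scripts/hvdi-cli.R`, subcommands `simulate`, `qc`, `assemble`,
`cluster`, `diversity`, `rarefy`, `validate-grid`, `make-fixtures`,
`pipeline`) are included. See the methods vignette
(`vignettes/hvdi-methods.Rmd`) for the model, parameter meanings and
design decisions.

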