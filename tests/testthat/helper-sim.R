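# Shared builders for test fixtures; everything is generated in code under
# fixed seeds.

# a small virome with well-separated genomes at generous coverage, so that
# assembly is near-perfect and contigs are pure
small_virome <- function(S = 5, n_reads = 2500, evenness = 0.9,
                         genome_len = 5000, seed = 42) {
  pool <- generate_genome_pool(S, c(genome_len, genome_len), seed = seed)
  prof <- construct_abundance_profile(S, evenness, seed = seed,
                                      genotype_ids = names(pool))
  list(pool = pool, profile = prof,
       virome = sample_reads(pool, prof, n_reads, seed = seed))
}

# deterministic random DNA without a fixed global seed side-effect
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads tiling a genome every `by` nt, alternating strands
tile_reads <- function(genome, len = 200, by = 50) {
  starts <- seq(0, nchar(genome) - len, by = by)
  seqs <- substring(genome, starts + 1, starts + len)
  strand <- rep(c("+", "-"), length.out = length(starts))
  neg <- strand == "-"
  seqs[neg] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
  setNames(seqs, sprintf("tile_%04d", seq_along(seqs)))
}

# synthetic homologue indicators for permutation tests: one logical vector
# per ordered virome pair, i.i.d. across pairs (label-exchangeable)
synthetic_indicators <- function(n_viromes, n_contigs = 150, seed = 1,
                                 q_range = c(0.2, 0.4)) {
  set.seed(seed)
  out <- vector("list", n_viromes)
  names(out) <- paste0("v", seq_len(n_viromes))
  for (i in seq_len(n_viromes)) {
    out[[i]] <- vector("list", n_viromes)
    names(out[[i]]) <- names(out)
    for (j in seq_len(n_viromes)) {
      if (i == j) next
      q <- runif(1, q_range[1], q_range[2])
      out[[i]][[j]] <- setNames(runif(n_contigs) < q,
                                sprintf("c%03d", seq_len(n_contigs)))
    }
  }
  out
}

# full pipeline on a simulated virome, returning truth and HVDI Shannon
hvdi_vs_truth <- function(S, evenness, n_reads, seed,
                          include_singletons = TRUE) {
  pool <- generate_genome_pool(S, c(10000, 10000), seed = seed)
  prof <- construct_abundance_profile(S, evenness, seed = seed,
                                      genotype_ids = names(pool))
  vir <- sample_reads(pool, prof, n_reads, seed = seed)
  qc <- filter_reads(vir)
  asm <- assemble(qc$reads)
  spec <- contig_spectrum(asm, include_singletons)
  hits <- contig_similarity_search(
    contig_sequences(asm, include_singletons),
    contig_sequences(asm, include_singletons))
  corr <- correct_contig_spectrum(spec, hits)
  truth <- qc$reads$truth_spectrum
  list(H_true = shannon_index(truth[truth > 0]), H_hvdi = hvdi(corr)$H,
       spectrum = spec, corrected = corr, assembly = asm,
       virome = qc$reads)
}
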