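test_that("genome pools honor size, bounds and seed determinism", {
  one <- generate_genome_pool(1, c(5000, 5000), gc_content = 0.5, seed = 7)
  expect_length(one, 1)
  expect_equal(nchar(one[[1]]), 5000)
  expect_false(grepl("[^ACGT]", one[[1]]))

  a <- generate_genome_pool(10, c(5000, 20000), gc_content = 0.455, seed = 1)
  b <- generate_genome_pool(10, c(5000, 20000), gc_content = 0.455, seed = 1)
  expect_identical(unclass(a), unclass(b))
  expect_false(anyDuplicated(names(a)) > 0)
  expect_true(all(nchar(a) >= 5000 & nchar(a) <= 20000))

  expect_error(generate_genome_pool(0), "n_genomes")
  expect_error(generate_genome_pool(2, c(100, 200)), "length_range")
})

test_that("pool GC content matches the target and genomes are separable", {
  pool <- generate_genome_pool(50, c(5000, 10000), gc_content = 0.5, seed = 3)
  bases <- strsplit(paste(pool, collapse = ""), "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  # i.i.d. genomes share essentially no 25-mers
  expect_lt(attr(pool, "max_shared_kmer_fraction"), 0.001)
})

test_that("evenness solver hits targets within tolerance", {
  # uniform limit
  p <- construct_abundance_profile(10, 1)
  expect_equal(p$proportions, rep(0.1, 10))
  expect_equal(p$achieved_evenness, 1)

  p <- construct_abundance_profile(100, 0.90, tolerance = 0.01)
  expect_true(p$achieved_evenness >= 0.89 && p$achieved_evenness <= 0.91)
  p <- construct_abundance_profile(50, 0.33, tolerance = 0.01)
  expect_true(p$achieved_evenness >= 0.32 && p$achieved_evenness <= 0.34)

  expect_error(construct_abundance_profile(1, 0.5), "S = 1")
  expect_error(construct_abundance_profile(10, 0), "target_evenness")
  expect_error(construct_abundance_profile(10, 1.2), "target_evenness")

  # proportions sum to one and evenness is reproduced from them
  for (tgt in c(0.10, 0.33, 0.50, 0.67, 0.90)) {
    p <- construct_abundance_profile(25, tgt)
    expect_equal(sum(p$proportions), 1, tolerance = 1e-9)
    H <- shannon_index(p$proportions)
    expect_equal(H / log(25), p$achieved_evenness, tolerance = 1e-12)
    expect_lt(abs(p$achieved_evenness - tgt), 0.01)
  }
})

test_that("achieved evenness is monotone in the family parameter", {
  r <- seq(0.05, 1, by = 0.05)
  ev <- vapply(r, function(x) {
    p <- hvdi:::.geometric_profile(40, x)
    shannon_index(p) / log(40)
  }, numeric(1))
  expect_true(all(diff(ev) > 0))
  expect_equal(ev[length(ev)], 1)
})

test_that("read sampling respects the length law, truth and determinism", {
  sv <- small_virome(S = 2, n_reads = 0, seed = 1)
  empty <- sample_reads(sv$pool, sv$profile, 0, seed = 1)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(sum(empty$truth_spectrum), 0)

  # single-genotype profile: every read is an exact substring of the genome
  pool <- generate_genome_pool(2, c(3000, 3000), seed = 2)
  prof <- construct_abundance_profile(2, 0.2, tolerance = 0.2,
                                      genotype_ids = names(pool))
  prof$proportions <- c(1, 0)  # degenerate: one source
  vir <- sample_reads(pool, prof, 100, seed = 3)
  g1 <- pool[[1]]
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  ok <- vapply(seq_len(100), function(i) {
    s <- vir$reads$sequence[i]
    grepl(s, g1, fixed = TRUE) || grepl(rc(s), g1, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(vir$reads$genotype == names(pool)[1]))

  # length law and truth bookkeeping
  sv <- small_virome(S = 4, n_reads = 4000, seed = 5)
  lens <- nchar(sv$virome$reads$sequence)
  expect_true(all(lens >= 150 & lens <= 250))
  expect_lt(abs(mean(lens) - 200), 2)
  expect_equal(sum(sv$virome$truth_spectrum), 4000)
  tab <- table(sv$virome$reads$genotype)
  expect_equal(as.integer(tab[names(sv$virome$truth_spectrum)]),
               unname(sv$virome$truth_spectrum))

  # byte-identical under the same seed
  again <- sample_reads(sv$pool, sv$profile, 4000, seed = 5)
  expect_identical(again$reads, sv$virome$reads)

  expect_error(sample_reads(sv$pool, sv$profile, 10, len_max = 10000,
                            seed = 1), "read length")
})

test_that("multinomial genotype sampling matches the profile", {
  pool <- generate_genome_pool(10, c(5000, 5000), seed = 6)
  prof <- construct_abundance_profile(10, 1, genotype_ids = names(pool))
  vir <- sample_reads(pool, prof, 10000, seed = 5)
  sd3 <- 3 * sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(vir$truth_spectrum - 1000) <= sd3))
})

test_that("truth-spectrum Shannon converges to the profile's H", {
  pool <- generate_genome_pool(20, c(5000, 5000), seed = 8)
  prof <- construct_abundance_profile(20, 0.6, seed = 8,
                                      genotype_ids = names(pool))
  vir <- sample_reads(pool, prof, 1e5, seed = 8)
  H_prof <- shannon_index(prof$proportions)
  H_real <- shannon_index(vir$truth_spectrum[vir$truth_spectrum > 0])
  expect_lt(abs(H_real - H_prof) / H_prof, 0.02)
})

test_that("artifact models inject QC-relevant features", {
  pool <- generate_genome_pool(2, c(3000, 3000), seed = 9)
  prof <- construct_abundance_profile(2, 1, genotype_ids = names(pool))
  vir <- sample_reads(pool, prof, 400, homopolymer_rate = 0.5,
                      ambiguous_rate = 0.5, seed = 9)
  expect_gt(sum(grepl("(.)\\1{7,}", vir$reads$sequence)), 100)
  expect_gt(sum(grepl("N", vir$reads$sequence, fixed = TRUE)), 100)
  # substitutions change sequences but not lengths
  v0 <- sample_reads(pool, prof, 200, error_rate = 0, seed = 10)
  v1 <- sample_reads(pool, prof, 200, error_rate = 0.05, seed = 10)
  expect_equal(nchar(v1$reads$sequence), nchar(v0$reads$sequence))
  expect_false(all(v1$reads$sequence == v0$reads$sequence))
})

test_that("FASTA round-trip preserves a genome pool", {
  pool <- generate_genome_pool(4, c(2000, 3000), seed = 11)
  tf <- tempfile(fileext = ".fasta")
  write_fasta(pool, tf)
  back <- load_genome_pool(tf)
  expect_identical(as.character(unclass(back)), as.character(unclass(pool)))
  expect_identical(names(back), names(pool))
  unlink(tf)
  expect_error(load_genome_pool(tf), "not found")
})
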