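test_that("similarity search finds duplicates and containments, not noise", {
  a <- random_dna(1000, 51)
  hits <- contig_similarity_search(c(c1 = a, c2 = a), c(c1 = a, c2 = a))
  h12 <- hits[hits$query_id == "c1" & hits$subject_id == "c2", ]
  expect_equal(nrow(h12), 1)
  expect_equal(h12$identity, 100)
  expect_equal(h12$alignment_length, 1000)
  expect_true(all(hits$query_id != hits$subject_id))  # self-hits excluded

  # unrelated random contigs: nothing at E < 1e-20
  u <- c(r1 = random_dna(1000, 52), r2 = random_dna(1000, 53))
  expect_equal(nrow(contig_similarity_search(u, u)), 0)

  # a 500-nt contig contained verbatim in a 2-kb contig: full coverage of
  # the shorter sequence
  big <- random_dna(2000, 54)
  small <- substring(big, 701, 1200)
  hits2 <- contig_similarity_search(c(s = small), c(b = big))
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$alignment_length, 500)
  expect_equal(hits2$q_start, 1)
  expect_equal(hits2$q_end, 500)

  # reverse-complement homology is found and coordinates are flipped
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  hits3 <- contig_similarity_search(c(s = rc(small)), c(b = big))
  expect_equal(nrow(hits3), 1)
  expect_true(hits3$s_start > hits3$s_end)

  # the coverage-of-shorter filter is enforced
  part <- substring(big, 1, 220)  # 220 of 1000 < 50 %
  hits4 <- contig_similarity_search(c(p = paste0(part, random_dna(780, 55))),
                                    c(b = big))
  expect_equal(nrow(hits4), 0)

  expect_error(contig_similarity_search(c(x = "ACGT"), c(y = "ACGT"),
                                        e_value_max = 0), "e_value_max")
})

test_that("the similarity engine agrees with command-line BLASTN", {
  g <- generate_genome_pool(4, c(2000, 2000), seed = 56)
  qs <- c(q1 = substring(g[[1]], 1, 1500),
          q2 = substring(g[[2]], 1, 1200),
          q3 = random_dna(1000, 57))
  ss <- c(s1 = substring(g[[1]], 301, 1800),   # overlaps q1 by 1200
          s2 = g[[2]],                          # contains q2
          s3 = substring(g[[3]], 1, 1500))      # unrelated to all queries
  dir <- tempfile()
  dir.create(dir)
  write_fasta(qs, file.path(dir, "q.fa"))
  write_fasta(ss, file.path(dir, "s.fa"))
  system2("makeblastdb", c("-in", file.path(dir, "s.fa"), "-dbtype", "nucl",
                           "-out", file.path(dir, "db")),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastn", c("-query", file.path(dir, "q.fa"), "-db",
                             file.path(dir, "db"), "-evalue", "1e-10",
                             "-outfmt", "6"), stdout = TRUE)
  bl <- read.table(text = out, sep = "\t", stringsAsFactors = FALSE)
  bl_pairs <- unique(paste(bl$V1, bl$V2))

  mine <- contig_similarity_search(qs, ss, e_value_max = 1e-10,
                                   min_frac_shorter = 0)
  my_pairs <- paste(mine$query_id, mine$subject_id)
  expect_setequal(my_pairs, bl_pairs)
  # identities and alignment lengths agree on the shared pairs
  for (p in my_pairs) {
    m <- mine[my_pairs == p, ][1, ]
    b <- bl[paste(bl$V1, bl$V2) == p, ][1, ]
    expect_equal(m$identity, b$V3, tolerance = 0.5)
    expect_equal(m$alignment_length, b$V4, tolerance = 0.01)
  }
  unlink(dir, recursive = TRUE)
})

test_that("spectrum correction merges by single linkage and conserves counts", {
  counts <- structure(c(a = 5L, b = 3L, c = 2L, d = 2L, e = 2L),
                      n_reads = 14L, class = "contig_spectrum")
  no_hits <- data.frame(query_id = character(0), subject_id = character(0))
  corr0 <- correct_contig_spectrum(counts, no_hits)
  expect_equal(sort(as.integer(corr0)), sort(as.integer(counts)))

  one <- data.frame(query_id = "a", subject_id = "b")
  corr1 <- correct_contig_spectrum(counts, one)
  expect_equal(as.integer(corr1), c(8L, 2L, 2L, 2L))

  # chain c-d, d-e with no c-e hit still forms one genotype
  chain <- data.frame(query_id = c("c", "d"), subject_id = c("d", "e"))
  corr2 <- correct_contig_spectrum(counts, chain)
  expect_equal(sort(as.integer(corr2)), c(3L, 5L, 6L))
  expect_equal(sum(corr2), sum(counts))
  mem <- attr(corr2, "membership")
  expect_equal(length(unique(mem[c("c", "d", "e")])), 1)

  bad <- data.frame(query_id = "zz", subject_id = "a")
  expect_error(correct_contig_spectrum(counts, bad), "absent")
})

test_that("correction never increases Shannon diversity", {
  for (seed in 61:64) {
    sv <- small_virome(S = 4, n_reads = 1200, evenness = 0.7,
                       genome_len = 5000, seed = seed)
    asm <- assemble(sv$virome)
    spec <- contig_spectrum(asm)
    hits <- contig_similarity_search(contig_sequences(asm),
                                     contig_sequences(asm))
    corr <- correct_contig_spectrum(spec, hits)
    expect_lte(shannon_index(corr), shannon_index(spec) + 1e-12)
    expect_equal(sum(corr), sum(spec))
    expect_lte(length(corr), length(spec))
  }
})

test_that("cross-sample shared fractions track genome sharing", {
  big <- generate_genome_pool(6, c(5000, 5000), seed = 65)
  mk <- function(gs, seed) {
    sub <- structure(big[gs], class = "genome_pool")
    prof <- construct_abundance_profile(length(gs), 1,
                                        genotype_ids = names(sub))
    assemble(filter_reads(sample_reads(sub, prof, 3000, seed = seed))$reads)
  }
  a <- mk(1:4, 21)
  b <- mk(c(3, 4, 5, 6), 22)   # shares half of a's genomes
  c0 <- mk(5:6, 23)            # shares none

  expect_equal(cross_sample_shared_fraction(a, a, n_sampled = 400,
                                            seed = 7), 1.0)
  f50 <- cross_sample_shared_fraction(a, b, n_sampled = 400, seed = 7)
  expect_lt(abs(f50 - 0.5), 0.05)
  expect_lt(cross_sample_shared_fraction(a, c0, n_sampled = 400, seed = 7),
            0.02)
  expect_error(cross_sample_shared_fraction(character(0), a), "non-empty")
})

test_that("truth-table clustering recovers the realized genotype counts", {
  sv <- small_virome(S = 5, n_reads = 2500, evenness = 0.9,
                     genome_len = 5000, seed = 66)
  asm <- assemble(sv$virome)
  corr <- truth_clustering(asm, sv$virome)
  truth <- sv$virome$truth_spectrum
  truth <- sort(truth[truth > 0], decreasing = TRUE)
  expect_equal(unname(as.integer(corr)), unname(as.integer(truth)))
  expect_equal(length(corr), sum(sv$virome$truth_spectrum > 0))
})
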