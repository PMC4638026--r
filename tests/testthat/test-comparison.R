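test_that("paired permutation test separates distinct groups", {
  # within-group pairs share everything, between-group pairs share nothing
  ind <- synthetic_indicators(4, n_contigs = 100, seed = 81)
  groups <- c("x", "x", "y", "y")
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    same <- groups[i] == groups[j]
    ind[[i]][[j]][] <- same
  }
  res <- permutation_shared_test(ind, groups, B = 200, n_sampled = 50,
                                 seed = 1, indicators = ind)
  expect_equal(res$p_value, 0)
  expect_equal(res$within_mean, 1)
  expect_equal(res$between_mean, 0)

  # degenerate equality: all viromes identical
  for (i in 1:4) for (j in 1:4) if (i != j) ind[[i]][[j]][] <- TRUE
  res2 <- permutation_shared_test(ind, groups, B = 200, n_sampled = 50,
                                  seed = 1, indicators = ind)
  expect_gte(res2$p_value, 0.4)
})

test_that("paired p-values center near one half under exchangeability", {
  ps <- vapply(1:50, function(s) {
    ind <- synthetic_indicators(6, n_contigs = 120, seed = 1000 + s)
    permutation_shared_test(ind, rep(c("x", "y"), each = 3), B = 200,
                            n_sampled = 60, seed = s,
                            indicators = ind)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("label-permutation p-values are approximately uniform under the null", {
  ps <- vapply(1:200, function(s) {
    ind <- synthetic_indicators(10, n_contigs = 120, seed = 2000 + s)
    permutation_shared_test(ind, rep(c("x", "y"), each = 5), B = 199,
                            n_sampled = 60, scheme = "label_perm",
                            seed = s, indicators = ind)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation test validates its inputs and honors exclusions", {
  ind <- synthetic_indicators(4, n_contigs = 50, seed = 83)
  expect_error(permutation_shared_test(ind, c("x", "x", "x", "y"),
                                       B = 10, indicators = ind),
               "two viromes per group")
  expect_error(permutation_shared_test(ind, c("x", "x", "y", "y"),
                                       subjects = c("s1", "s2", "s1", "s2"),
                                       B = 10, n_sampled = 10,
                                       indicators = ind),
               NA)  # s1/s2 exclusions leave admissible pairs
})

test_that("sequence-level permutation test flags individual-specific viromes", {
  poolA <- generate_genome_pool(4, c(4000, 4000), seed = 84)
  poolB <- generate_genome_pool(4, c(4000, 4000), seed = 85)
  mk <- function(pool, seed) {
    prof <- construct_abundance_profile(length(pool), 1,
                                        genotype_ids = names(pool))
    assemble(sample_reads(pool, prof, 1600, seed = seed))
  }
  viromes <- list(a1 = mk(poolA, 1), a2 = mk(poolA, 2),
                  b1 = mk(poolB, 3), b2 = mk(poolB, 4))
  res <- permutation_shared_test(viromes, c("a", "a", "b", "b"), B = 100,
                                 n_sampled = 50, seed = 9)
  expect_equal(res$p_value, 0)
  expect_gt(res$within_mean, 0.9)
  expect_lt(res$between_mean, 0.1)
})

test_that("membership matrices summarize persistence", {
  big <- generate_genome_pool(7, c(4000, 4000), seed = 86)
  slice <- function(i) substring(big[[i]], 1, 2000)
  contigs <- c()
  labels <- c()
  for (t in 1:5) {
    cs <- c(slice(1), if (t <= 2) slice(2), slice(2 + t))
    names(cs) <- sprintf("t%d_c%d", t, seq_along(cs))
    contigs <- c(contigs, cs)
    labels <- c(labels, rep(sprintf("t%d", t), length(cs)))
  }
  m <- assembly_membership_matrix(contigs, labels)
  pct <- attr(m, "percentages")
  # genome 1 persists in all samples, genome 2 only in t1/t2; transient
  # genomes stay singletons and are not persistence-informative
  expect_equal(nrow(m), 2)
  expect_equal(unname(pct[c("t1", "t2")]), c(100, 100))
  expect_equal(unname(pct[c("t3", "t4", "t5")]), c(50, 50, 50))
  expect_true(all(rowSums(m) >= 1))

  # relabeling permutes percentages (equivariance)
  relab <- c(t1 = "u4", t2 = "u5", t3 = "u1", t4 = "u2", t5 = "u3")
  m2 <- assembly_membership_matrix(contigs, unname(relab[labels]))
  pct2 <- attr(m2, "percentages")
  expect_equal(unname(pct2[unname(relab[names(pct)])]), unname(pct))

  # all contigs from one sample
  two <- c(x1 = substring(big[[1]], 1, 1500), x2 = substring(big[[1]], 701,
                                                             2200))
  m3 <- assembly_membership_matrix(two, c("only", "only"))
  expect_equal(unname(attr(m3, "percentages")), 100)

  # identical contig sets from two samples
  m4 <- assembly_membership_matrix(
    c(p1 = slice(1), q1 = slice(1)), c("p", "q"))
  expect_equal(unname(attr(m4, "percentages")), c(100, 100))

  expect_error(assembly_membership_matrix(two, c("only", NA)), "label")
})

test_that("Bray-Curtis distances match the closed form", {
  prof <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0))
  d <- bray_curtis_matrix(prof)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # disjoint support gives distance 1
  d2 <- bray_curtis_matrix(rbind(a = c(2, 0), b = c(0, 3)))
  expect_equal(d2["a", "b"], 1)
  expect_warning(
    d3 <- bray_curtis_matrix(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))),
    "all-zero")
  expect_true(is.na(d3["a", "b"]))      # both profiles empty: undefined
  expect_equal(d3["a", "c"], 1)         # one-sided empty profile: defined
  expect_error(bray_curtis_matrix(rbind(c(-1, 2), c(0, 1))), "non-negative")
})

test_that("PCoA reproduces Euclidean configurations", {
  # all-zero distances embed at the origin
  z <- matrix(0, 3, 3)
  expect_true(all(pcoa(z, k = 2)$points == 0))

  # two samples at distance d separate by exactly d
  d <- matrix(c(0, 1.7, 1.7, 0), 2)
  pts <- pcoa(d, k = 1)$points
  expect_equal(abs(pts[1, 1] - pts[2, 1]), 1.7, tolerance = 1e-12)

  # a full-rank Euclidean distance matrix is reproduced exactly
  set.seed(87)
  x <- matrix(rnorm(6 * 5), 6, 5)
  D <- as.matrix(dist(x))
  res <- pcoa(D, k = 5)
  emb <- as.matrix(dist(res$points))
  expect_lt(max(abs(emb - D)), 1e-8)
  expect_equal(res$negative_fraction, 0, tolerance = 1e-9)

  # independent oracle: classical scaling in stats::cmdscale
  cm <- stats::cmdscale(D, k = 5)
  expect_equal(abs(res$points), abs(cm), tolerance = 1e-6,
               ignore_attr = TRUE)

  # negative eigenvalues from non-Euclidean distances are reported:
  # four points with one stretched distance violate Euclidean embeddability
  ne <- matrix(1, 4, 4) - diag(4)
  ne[1, 2] <- ne[2, 1] <- 1.95
  res2 <- pcoa(ne, k = 2)
  expect_true(any(res2$eigenvalues < -1e-8))
  expect_gt(res2$negative_fraction, 0)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
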