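#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over relative abundances `p_i`; zero counts
#' are ignored. Natural logarithms are used throughout the package because
#' Pielou evenness is defined as `H / ln(S)`.
#'
#' @param counts non-negative abundances with at least one positive entry.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon_index(rep(1, 10))  # ln(10)
shannon_index <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(counts < 0) || !any(counts > 0)) {
    stop("counts must be non-negative with at least one positive entry")
  }
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `J = H / ln(S)`, equal to 1 for a uniform community and approaching 0
#' when a few genotypes dominate. Undefined at `S = 1` (`ln(1) = 0`).
#'
#' @param H Shannon index in nats (>= 0).
#' @param S number of categories (>= 2).
#' @return evenness in `[0, 1]`; values exceeding 1 by rounding are clamped
#'   with a warning.
#' @export
pielou_evenness <- function(H, S) {
  if (S < 2) stop("evenness is undefined for S < 2")
  if (H < 0) stop("H must be >= 0")
  e <- H / log(S)
  if (e > 1) {
    if (e > 1 + 1e-8) warning("H exceeds ln(S); evenness clamped to 1")
    e <- 1
  }
  e
}

#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 * F2)` where `F1` and `F2` are the numbers of
#' categories observed exactly once (singletons) and exactly twice
#' (doubletons). When `F2 = 0` the bias-corrected form
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` is used, which avoids division
#' by zero.
#'
#' @param counts positive integer abundances.
#' @return the Chao1 estimate (always `>= S_obs`).
#' @export
#' @examples
#' chao1_index(c(1, 1, 2, 5))  # 4 + 4/2 = 6
chao1_index <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("counts must be positive integers")
  }
  S_obs <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (F2 > 0) S_obs + F1^2 / (2 * F2)
  else S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))
}

#' Homologous Virus Diversity Index
#'
#' Computes the HVDI from a corrected contig spectrum: the selected
#' diversity statistic (Shannon or Chao1) applied to the per-genotype read
#' counts after merging highly similar contigs. A raw [contig_spectrum()]
#' is also accepted (equivalent to a correction with no hits).
#'
#' @param corrected a `corrected_spectrum` (or `contig_spectrum`).
#' @param index `"shannon"` (default) or `"chao1"`.
#' @return a `diversity_result`: a list with `value` (the selected index),
#'   `index`, `H` (Shannon, nats), `S_obs`, `evenness` (`H/ln(S_obs)`;
#'   `NA` flagged when `S_obs = 1`), `chao1`, `F1` and `F2`.
#' @export
hvdi <- function(corrected, index = c("shannon", "chao1")) {
  index <- match.arg(index)
  if (!inherits(corrected, c("corrected_spectrum", "contig_spectrum"))) {
    stop("corrected must be a corrected_spectrum or contig_spectrum")
  }
  counts <- as.integer(corrected)
  if (length(counts) == 0) stop("empty spectrum")
  H <- shannon_index(counts)
  S_obs <- length(counts)
  evenness <- if (S_obs >= 2) pielou_evenness(H, S_obs) else NA_real_
  chao1 <- chao1_index(counts)
  structure(list(
    value = if (index == "shannon") H else chao1,
    index = index, H = H, S_obs = S_obs, evenness = evenness,
    chao1 = chao1, F1 = sum(counts == 1L), F2 = sum(counts == 2L)),
    class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(
    "diversity_result (%s): H = %.4f, S_obs = %d, evenness = %s, chao1 = %.2f (F1 = %d, F2 = %d)\n",
    x$index, x$H, x$S_obs,
    if (is.na(x$evenness)) "undefined (S = 1)" else sprintf("%.4f", x$evenness),
    x$chao1, x$F1, x$F2))
  invisible(x)
}

#' Rarefaction of the Chao1-based HVDI
#'
#' Subsamples reads without replacement at a grid of depths, rebuilds the
#' corrected genotype spectrum from each subsample via the full-data
#' read-to-genotype assignment, and reports the mean and sd of the
#' Chao1-based HVDI per depth.
#'
#' @param assignments a named character vector mapping read id to genotype
#'   (see [read_assignments()], optionally composed with a clustering
#'   membership), or a list with elements `assembly` and optionally
#'   `clustering` (a `corrected_spectrum`) from which the map is built.
#' @param depths subsampling depths; defaults to
#'   `c(500, 1000, 2000, 5000, 10000, 20000)` clipped to the sample size
#'   (the full depth is always appended).
#' @param reps_per_depth replicate subsamples per depth (default 10).
#' @param seed integer seed.
#' @return a data.frame with columns `depth`, `mean_chao1`, `sd_chao1`,
#'   `reps`.
#' @export
rarefaction_curve <- function(assignments,
                              depths = c(500, 1000, 2000, 5000, 10000, 20000),
                              reps_per_depth = 10, seed = 1) {
  if (is.list(assignments) && !is.null(assignments$assembly)) {
    map <- read_assignments(assignments$assembly)
    if (!is.null(assignments$clustering)) {
      mem <- attr(assignments$clustering, "membership")
      map <- setNames(unname(mem[map]), names(map))
    }
    assignments <- map
  }
  genotype <- as.character(assignments)
  n <- length(genotype)
  if (n == 0) stop("no read assignments")
  if (reps_per_depth < 1) stop("reps_per_depth must be >= 1")
  depths <- sort(unique(c(depths[depths <= n], n)))
  if (any(depths < 1)) stop("depths must be >= 1")

  set.seed(derive_seed(seed, "diversity"))
  rows <- lapply(depths, function(d) {
    vals <- vapply(seq_len(reps_per_depth), function(r) {
      sub <- if (d == n) genotype else genotype[sample.int(n, d)]
      chao1_index(as.integer(table(sub)))
    }, numeric(1))
    data.frame(depth = d, mean_chao1 = mean(vals),
               sd_chao1 = if (length(vals) > 1) sd(vals) else 0,
               reps = reps_per_depth)
  })
  do.call(rbind, rows)
}

#' Truth-table clustering oracle
#'
#' Clusters spectrum units by the true source genotype of their member
#' reads (majority vote), using the simulator's ground truth instead of
#' sequence similarity. With pure contigs the corrected spectrum equals the
#' realized truth spectrum exactly, which makes this the reference point
#' for similarity-based clustering.
#'
#' @param assembly an `assembly_result` built from a simulated virome.
#' @param virome the `simulated_virome` the reads came from.
#' @param include_singletons as in [contig_spectrum()].
#' @return a `corrected_spectrum`.
#' @export
truth_clustering <- function(assembly, virome, include_singletons = TRUE) {
  stopifnot(inherits(assembly, "assembly_result"),
            inherits(virome, "simulated_virome"))
  spectrum <- contig_spectrum(assembly, include_singletons)
  read_src <- setNames(virome$reads$genotype, virome$reads$id)
  unit_src <- vapply(names(spectrum), function(u) {
    mem <- if (u %in% names(assembly$members)) assembly$members[[u]] else u
    src <- read_src[mem]
    names(sort(table(src), decreasing = TRUE))[1]
  }, character(1))
  sums <- tapply(as.integer(spectrum), unit_src, sum)
  ord <- order(-as.integer(sums), names(sums))
  counts <- setNames(as.integer(sums)[ord], names(sums)[ord])
  structure(counts,
            membership = setNames(unname(unit_src), names(spectrum)),
            n_reads = sum(counts), class = "corrected_spectrum")
}

#' HVDI-versus-Shannon validation grid
#'
#' Simulates viromes over a grid of genotype richness and evenness values,
#' runs the full estimation pipeline (QC, greedy assembly, genotype
#' clustering, HVDI), and compares the Shannon-form HVDI against the true
#' Shannon index of each virome's realized genotype read counts. Per cell,
#' the mean and sd of the percent difference `100 * |HVDI - H| / H` are
#' reported.
#'
#' Reads per virome default to 20,000. The expected coverage of the rarest
#' genotype is reported per cell; when it falls below `coverage_warn` the
#' cell is flagged, since low coverage fragments genomes into disjoint
#' contigs that sequence-similarity clustering cannot rejoin, inflating
#' the HVDI.
#'
#' @param genotype_counts richness levels (default `c(10, 50, 100, 500,
#'   1000)`).
#' @param evenness_targets Pielou evenness targets (default `c(0.10, 0.33,
#'   0.50, 0.67, 0.90)`).
#' @param reps viromes per cell (default 10).
#' @param reads_per_virome reads per simulated virome (default 20000).
#' @param genome_length genome length range in nt (default 10-kb genomes).
#' @param oracle use the [truth_clustering()] oracle instead of
#'   similarity-based clustering (default `FALSE`).
#' @param coverage_warn flag cells whose rarest genotype has expected
#'   coverage below this (default 1).
#' @param seed integer master seed.
#' @return a `validation_grid`: a data.frame with one row per
#'   `(S, evenness, replicate)` holding `H_true`, `H_hvdi`, `pct_diff`,
#'   `S_obs_hvdi`, `min_expected_coverage` and `coverage_shortfall`; the
#'   attribute `cells` holds per-cell means and sds.
#' @export
run_validation_grid <- function(genotype_counts = c(10, 50, 100, 500, 1000),
                                evenness_targets = c(0.10, 0.33, 0.50, 0.67,
                                                     0.90),
                                reps = 10, reads_per_virome = 20000,
                                genome_length = c(10000, 10000),
                                oracle = FALSE, coverage_warn = 1,
                                seed = 1) {
  stopifnot(all(genotype_counts >= 2), all(evenness_targets > 0),
            all(evenness_targets <= 1), reps >= 1, reads_per_virome >= 1)
  grid <- expand.grid(S = genotype_counts, evenness = evenness_targets,
                      rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]
    ev <- grid$evenness[i]
    cell_seed <- derive_seed(seed, 0L) + 7919L * i
    pool <- generate_genome_pool(S, genome_length, seed = cell_seed)
    prof <- construct_abundance_profile(S, ev, tolerance = 0.01,
                                        seed = cell_seed,
                                        genotype_ids = names(pool))
    vir <- sample_reads(pool, prof, reads_per_virome, seed = cell_seed)
    min_cov <- reads_per_virome * min(prof$proportions) * 200 /
      max(nchar(pool))
    qc <- filter_reads(vir)
    asm <- assemble(qc$reads)
    spec <- contig_spectrum(asm)
    corrected <- if (oracle) {
      truth_clustering(asm, qc$reads)
    } else {
      hits <- contig_similarity_search(contig_sequences(asm),
                                       contig_sequences(asm),
                                       e_value_max = 1e-20,
                                       min_frac_shorter = 0.50)
      correct_contig_spectrum(spec, hits)
    }
    H_hvdi <- hvdi(corrected, "shannon")$H
    truth <- qc$reads$truth_spectrum
    H_true <- shannon_index(truth[truth > 0])
    rows[[i]] <- data.frame(
      S = S, evenness = ev, rep = grid$rep[i],
      H_true = H_true, H_hvdi = H_hvdi,
      pct_diff = 100 * abs(H_hvdi - H_true) / H_true,
      S_obs_hvdi = length(corrected),
      min_expected_coverage = min_cov,
      coverage_shortfall = min_cov < coverage_warn)
  }
  out <- do.call(rbind, rows)
  cells <- do.call(rbind, lapply(split(out, list(out$S, out$evenness),
                                       drop = TRUE), function(d) {
    data.frame(S = d$S[1], evenness = d$evenness[1],
               mean_pct_diff = mean(d$pct_diff),
               sd_pct_diff = if (nrow(d) > 1) sd(d$pct_diff) else 0,
               mean_H_true = mean(d$H_true), mean_H_hvdi = mean(d$H_hvdi),
               coverage_shortfall = any(d$coverage_shortfall))
  }))
  cells <- cells[order(cells$S, cells$evenness), ]
  rownames(cells) <- NULL
  structure(out, cells = cells, class = c("validation_grid", "data.frame"))
}

#' @export
print.validation_grid <- function(x, ...) {
  cells <- attr(x, "cells")
  cat(sprintf("validation_grid: %d cells x %d replicates\n", nrow(cells),
              max(x$rep)))
  print.data.frame(cells, digits = 4)
  invisible(x)
}
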