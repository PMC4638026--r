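#' Generate a pool of synthetic phage genomes
#'
#' Draws `n_genomes` independent random double-stranded DNA genomes with a
#' target GC content. Bases are i.i.d., so distinct genomes share essentially
#' no k-mers and behave as well-separated viral genotypes: the simulator's
#' stand-in for sampling unrelated phage genomes from reference databases.
#' The maximum pairwise shared 25-mer fraction across the pool is computed
#' and attached so callers can confirm genotypes are separable before using
#' the pool as assembly/clustering ground truth.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param length_range integer length interval in nt, within `[1000, 500000]`.
#'   Genome lengths are drawn uniformly from this interval.
#' @param gc_content target GC fraction in `(0, 1)`.
#' @param seed integer seed; pools are reproducible given the seed.
#' @return an object of class `genome_pool`: a named character vector of
#'   genome sequences with attributes `seed` and `max_shared_kmer_fraction`
#'   (maximum over genome pairs of the shared fraction of distinct 25-mers,
#'   relative to the smaller 25-mer set).
#' @export
#' @examples
#' pool <- generate_genome_pool(3, c(2000, 3000), seed = 1)
#' nchar(pool)
generate_genome_pool <- function(n_genomes, length_range = c(10000, 10000),
                                 gc_content = 0.5, seed = 1) {
  if (!is.numeric(n_genomes) || length(n_genomes) != 1L || n_genomes < 1) {
    stop("n_genomes must be a single integer >= 1")
  }
  n_genomes <- as.integer(n_genomes)
  if (length(length_range) != 2L || any(!is.finite(length_range)) ||
      length_range[1] > length_range[2] ||
      length_range[1] < 1000 || length_range[2] > 500000) {
    stop("length_range must be an increasing interval within [1000, 500000]")
  }
  if (gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must be in (0, 1)")
  }
  set.seed(derive_seed(seed, "pool"))
  probs <- c((1 - gc_content) / 2, gc_content / 2,
             gc_content / 2, (1 - gc_content) / 2)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n_genomes,
                     replace = TRUE) + length_range[1] - 1L
  seqs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  ids <- sprintf("genome_%04d", seq_len(n_genomes))
  names(seqs) <- ids
  shared <- if (n_genomes >= 2) cpp_max_shared_kmer_fraction(seqs, 25L) else 0
  structure(seqs, seed = seed, max_shared_kmer_fraction = shared,
            class = "genome_pool")
}

#' Load a genome pool from a FASTA file
#'
#' Accepts any user-supplied set of genomes (for example real phage
#' reference sequences) as the sampling pool for [sample_reads()].
#' Sequences are uppercased; ambiguous characters are rejected because the
#' simulator requires unambiguous ground truth.
#'
#' @param path FASTA file of genome sequences.
#' @return a `genome_pool` object.
#' @export
load_genome_pool <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids in ", path)
  }
  .assert_dna(seqs, "genome")
  structure(seqs, seed = NA_integer_,
            max_shared_kmer_fraction =
              if (length(seqs) >= 2) cpp_max_shared_kmer_fraction(seqs, 25L)
              else 0,
            class = "genome_pool")
}

#' @export
print.genome_pool <- function(x, ...) {
  cat(sprintf("genome_pool: %d genomes, lengths %d-%d nt, GC %.3f\n",
              length(x), min(nchar(x)), max(nchar(x)),
              mean(unlist(strsplit(paste(x, collapse = ""), "")) %in%
                     c("G", "C"))))
  cat(sprintf("  max pairwise shared 25-mer fraction: %.3g\n",
              attr(x, "max_shared_kmer_fraction")))
  invisible(x)
}

# Shannon index of a geometric abundance series p_i proportional to r^(i-1),
# normalized over S genotypes; r = 1 is the uniform limit.
.geometric_profile <- function(S, r) {
  if (r >= 1) return(rep(1 / S, S))
  w <- r^(seq_len(S) - 1)
  w / sum(w)
}

.profile_evenness <- function(p) {
  p <- p[p > 0]
  H <- -sum(p * log(p))
  H / log(length(p))
}

#' Construct an abundance profile with a target Pielou evenness
#'
#' Builds relative abundances over `S` viral genotypes whose Pielou evenness
#' `H/ln(S)` (with `H` the Shannon index in nats) matches a requested target.
#' Abundances follow a one-parameter geometric series `p_i` proportional to
#' `r^(i-1)` with the ratio `r` in `(0, 1]`; evenness is monotone increasing
#' in `r` (from near 0 up to exactly 1 at the uniform limit where `r` equals
#' 1), so `r` is solved by root bracketing on the achieved evenness.
#'
#' @param S number of genotypes; must be >= 2 (evenness is undefined at
#'   `S = 1` because `ln(1) = 0`).
#' @param target_evenness requested evenness in `(0, 1]`.
#' @param tolerance maximum allowed `|achieved - target|` (default 0.01).
#' @param seed optional integer seed used to shuffle which genotype receives
#'   which abundance rank; the multiset of proportions is deterministic.
#' @param genotype_ids optional character vector of `S` genotype ids
#'   (defaults to `g1 ... gS`), e.g. the names of a [generate_genome_pool()].
#' @return an object of class `abundance_profile`: a list with
#'   `genotype_ids`, `proportions` (summing to 1), `target_evenness`,
#'   `achieved_evenness`, `S` and the solved family parameter `r`.
#' @export
#' @examples
#' p <- construct_abundance_profile(10, 0.5)
#' p$achieved_evenness
construct_abundance_profile <- function(S, target_evenness, tolerance = 0.01,
                                        seed = NULL, genotype_ids = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 2) {
    stop("S must be >= 2: evenness H/ln(S) is undefined at S = 1")
  }
  S <- as.integer(S)
  if (!is.numeric(target_evenness) || target_evenness <= 0 ||
      target_evenness > 1) {
    stop("target_evenness must be in (0, 1]")
  }
  if (is.null(genotype_ids)) {
    genotype_ids <- paste0("g", seq_len(S))
  }
  if (length(genotype_ids) != S || anyDuplicated(genotype_ids)) {
    stop("genotype_ids must be S unique ids")
  }

  if (target_evenness == 1) {
    r <- 1
    p <- rep(1 / S, S)
  } else {
    f <- function(r) .profile_evenness(.geometric_profile(S, r)) -
      target_evenness
    lo <- 0.5
    while (f(lo) > 0 && lo > 1e-12) lo <- lo / 2
    if (f(lo) > 0) {
      stop("evenness solver failed to bracket target ", target_evenness)
    }
    r <- stats::uniroot(f, c(lo, 1), tol = 1e-12)$root
    p <- .geometric_profile(S, r)
  }
  achieved <- .profile_evenness(p)
  if (abs(achieved - target_evenness) > tolerance) {
    stop(sprintf(
      "evenness solver did not converge: achieved %.6f for target %.3f",
      achieved, target_evenness))
  }
  if (!is.null(seed)) {
    set.seed(derive_seed(seed, "profile"))
    p <- p[sample.int(S)]
  }
  structure(list(genotype_ids = genotype_ids, proportions = p,
                 target_evenness = target_evenness,
                 achieved_evenness = achieved, S = S, r = r),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf(
    "abundance_profile: S = %d, target evenness %.3f, achieved %.4f (r = %.6g)\n",
    x$S, x$target_evenness, x$achieved_evenness, x$r))
  invisible(x)
}

.revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Discretized normal read lengths, mean len_mean / sd len_sd, truncated by
# rejection to [len_min, len_max]; symmetric truncation keeps the mean.
.sample_read_lengths <- function(n, len_mean, len_sd, len_min, len_max) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(round(stats::rnorm(max(n, 100), len_mean, len_sd)))
    out <- c(out, cand[cand >= len_min & cand <= len_max])
  }
  out[seq_len(n)]
}

#' Simulate shotgun reads from a genome pool
#'
#' Draws reads whose source genotype follows the abundance profile, with
#' start positions uniform over valid positions, strands uniform, and
#' lengths from a discretized normal (mean `len_mean`, sd `len_sd`)
#' truncated to `[len_min, len_max]`. Reads never cross genome ends
#' (genomes are treated as linear). The full ground truth (source genotype,
#' start, strand) is retained per read, together with the realized
#' per-genotype read counts (`truth_spectrum`).
#'
#' Optional artifact models exist solely to exercise quality control:
#' per-base substitutions (`error_rate`), injected homopolymer runs
#' (`homopolymer_rate`, per-read probability of overwriting a window with a
#' single-base run of 8-12 nt) and injected ambiguous bases
#' (`ambiguous_rate`, per-read probability of one `N`).
#'
#' @param pool a `genome_pool`.
#' @param profile an `abundance_profile` whose genotype ids are a subset of
#'   the pool's genome ids.
#' @param n_reads number of reads (>= 0).
#' @param len_mean,len_min,len_max read length law in nt (defaults 200,
#'   150, 250).
#' @param len_sd standard deviation of the untruncated length law (default 25).
#' @param error_rate per-base substitution probability (default 0).
#' @param homopolymer_rate per-read homopolymer artifact probability (default 0).
#' @param ambiguous_rate per-read ambiguous-base artifact probability (default 0).
#' @param seed integer seed.
#' @return an object of class `simulated_virome`: a list with `reads` (a
#'   data.frame with columns `id`, `sequence`, `genotype`, `start`
#'   (0-based), `strand`), `truth_spectrum` (named read counts per profile
#'   genotype) and `seed`.
#' @export
#' @examples
#' pool <- generate_genome_pool(2, c(2000, 2000), seed = 1)
#' prof <- construct_abundance_profile(2, 1, genotype_ids = names(pool))
#' v <- sample_reads(pool, prof, 10, seed = 1)
#' v$truth_spectrum
sample_reads <- function(pool, profile, n_reads, len_mean = 200,
                         len_min = 150, len_max = 250, len_sd = 25,
                         error_rate = 0, homopolymer_rate = 0,
                         ambiguous_rate = 0, seed = 1) {
  stopifnot(inherits(pool, "genome_pool"), inherits(profile, "abundance_profile"))
  if (!all(profile$genotype_ids %in% names(pool))) {
    stop("profile genotype ids must be a subset of pool genome ids")
  }
  if (n_reads < 0) stop("n_reads must be >= 0")
  n_reads <- as.integer(n_reads)
  glens <- nchar(pool)
  if (len_max > min(glens[profile$genotype_ids])) {
    stop("maximum read length exceeds the shortest genome in the profile")
  }
  if (len_min > len_mean || len_mean > len_max || len_min < 1) {
    stop("require 1 <= len_min <= len_mean <= len_max")
  }

  truth <- setNames(integer(profile$S), profile$genotype_ids)
  if (n_reads == 0L) {
    reads <- data.frame(id = character(0), sequence = character(0),
                        genotype = character(0), start = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    return(structure(list(reads = reads, truth_spectrum = truth, seed = seed),
                     class = "simulated_virome"))
  }

  set.seed(derive_seed(seed, "reads"))
  src <- sample(profile$genotype_ids, n_reads, replace = TRUE,
                prob = profile$proportions)
  lens <- .sample_read_lengths(n_reads, len_mean, len_sd, len_min, len_max)
  gl <- glens[src]
  start <- floor(stats::runif(n_reads) * (gl - lens + 1))  # 0-based
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(pool[src], start + 1, start + lens)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- .revcomp(seqs[neg])

  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, lens, error_rate)
    for (i in which(n_err > 0)) {
      s <- strsplit(seqs[i], "")[[1]]
      pos <- sample.int(lens[i], n_err[i])
      for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  if (homopolymer_rate > 0) {
    hit <- stats::runif(n_reads) < homopolymer_rate
    for (i in which(hit)) {
      run <- sample(8:12, 1)
      at <- sample.int(lens[i] - run + 1, 1)
      substr(seqs[i], at, at + run - 1) <-
        strrep(sample(DNA_BASES, 1), run)
    }
  }
  if (ambiguous_rate > 0) {
    hit <- stats::runif(n_reads) < ambiguous_rate
    for (i in which(hit)) {
      at <- sample.int(lens[i], 1)
      substr(seqs[i], at, at) <- "N"
    }
  }

  tab <- table(factor(src, levels = profile$genotype_ids))
  truth[names(tab)] <- as.integer(tab)
  reads <- data.frame(
    id = sprintf("read_%06d", seq_len(n_reads)),
    sequence = unname(seqs), genotype = src, start = as.integer(start),
    strand = strand, stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  structure(list(reads = reads, truth_spectrum = truth, seed = seed),
            class = "simulated_virome")
}

#' @export
print.simulated_virome <- function(x, ...) {
  cat(sprintf(
    "simulated_virome: %d reads from %d genotypes (%d with >= 1 read), seed %s\n",
    nrow(x$reads), length(x$truth_spectrum), sum(x$truth_spectrum > 0),
    format(x$seed)))
  if (nrow(x$reads) > 0) {
    cat(sprintf("  read lengths: %d-%d nt, mean %.1f\n",
                min(nchar(x$reads$sequence)), max(nchar(x$reads$sequence)),
                mean(nchar(x$reads$sequence))))
  }
  invisible(x)
}
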