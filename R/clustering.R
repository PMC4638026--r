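# Ungapped Karlin-Altschul parameters for match +1 / mismatch -2 at uniform
# base composition: lambda solves 0.25*exp(l) + 0.75*exp(-2l) = 1.
.ka_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lambda <- stats::uniroot(
        function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1,
        c(0.1, 3), tol = 1e-12)$root
      cache <<- list(lambda = lambda, K = 0.621)
    }
    cache
  }
})

.as_seqset <- function(x, what = "sequences") {
  if (inherits(x, "assembly_result")) x <- contig_sequences(x)
  nm <- names(x)
  x <- as.character(x)  # as.character() drops names; restore them
  names(x) <- nm
  if (is.null(names(x))) names(x) <- sprintf("seq_%05d", seq_along(x))
  if (any(nchar(x) == 0)) stop(what, " must be non-empty")
  x
}

#' Pairwise local-similarity search between contig sets
#'
#' Finds local similarities between nucleotide sequences with an ungapped
#' seed-and-extend engine (exact word seeds, X-drop extension, match +1 /
#' mismatch -2) and Karlin-Altschul E-values computed over a search space
#' equal to the query length times the total subject length. Both strands
#' are searched. The engine reproduces BLASTN-like E-value semantics for
#' the near-identical alignments relevant to genotype clustering and
#' cross-virome sharing; hits are reported only when the alignment covers
#' at least `min_frac_shorter` of the shorter of the two sequences and
#' `e_value < e_value_max`. Self-hits (identical ids) are excluded.
#'
#' @param queries,subjects named character vectors of sequences, or
#'   `assembly_result` objects (their contigs plus singletons are used).
#' @param e_value_max E-value threshold; `1e-20` is used for within-sample
#'   genotype clustering and `1e-10` for cross-virome comparison.
#' @param min_frac_shorter minimum aligned fraction of the shorter
#'   sequence (default 0.50).
#' @param word_size exact seed length (default 13).
#' @return a data.frame in tabular pairwise-search format with columns
#'   `query_id`, `subject_id`, `identity` (percent), `alignment_length`,
#'   `mismatches`, `gap_openings` (always 0: alignments are ungapped),
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based; `s_start > s_end` on
#'   the minus strand), `e_value`, `bit_score`.
#' @export
contig_similarity_search <- function(queries, subjects,
                                     e_value_max = 1e-20,
                                     min_frac_shorter = 0.50,
                                     word_size = 13) {
  if (e_value_max <= 0) stop("e_value_max must be > 0")
  q <- .as_seqset(queries, "queries")
  s <- .as_seqset(subjects, "subjects")
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), alignment_length = integer(0),
                      mismatches = integer(0), gap_openings = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(s) == 0 || length(q) == 0) return(empty)

  ka <- .ka_params()
  # minimum score worth reporting: solve E = e_value_max at the largest
  # plausible search space, with head-room for the coverage filter
  space <- as.double(max(nchar(q))) * sum(as.double(nchar(s)))
  min_score <- max(word_size,
                   floor((log(ka$K * space) - log(e_value_max)) /
                           ka$lambda) - 5)
  hits <- cpp_local_search(unname(q), unname(s), as.integer(word_size),
                           30L, as.integer(min_score))
  if (nrow(hits) == 0) return(empty)

  qid <- names(q)[hits$q]
  sid <- names(s)[hits$s]
  qlen <- nchar(q)[hits$q]
  slen <- nchar(s)[hits$s]
  e_value <- ka$K * as.double(qlen) * sum(as.double(nchar(s))) *
    exp(-ka$lambda * hits$score)
  bit_score <- (ka$lambda * hits$score - log(ka$K)) / log(2)

  # convert oriented-query coordinates to 1-based original-query/subject
  q_start <- ifelse(hits$strand == 0, hits$qstart + 1L,
                    qlen - hits$qend + 1L)
  q_end <- ifelse(hits$strand == 0, hits$qend, qlen - hits$qstart)
  s_start <- ifelse(hits$strand == 0, hits$sstart + 1L, hits$send)
  s_end <- ifelse(hits$strand == 0, hits$send, hits$sstart + 1L)

  out <- data.frame(
    query_id = qid, subject_id = sid,
    identity = 100 * hits$matches / hits$length,
    alignment_length = hits$length,
    mismatches = hits$length - hits$matches,
    gap_openings = 0L,
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    e_value = e_value, bit_score = bit_score,
    stringsAsFactors = FALSE)

  keep <- out$query_id != out$subject_id &
    out$e_value < e_value_max &
    out$alignment_length >= min_frac_shorter * pmin(qlen, slen) - 1e-9
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correct a contig spectrum by genotype clustering
#'
#' Contigs linked by high-similarity hits are assigned to the same viral
#' genotype by single linkage (connected components of the hit graph), and
#' their read counts are summed into a corrected contig spectrum: the input
#' for the Homologous Virus Diversity Index.
#'
#' @param spectrum a `contig_spectrum` (see [contig_spectrum()]).
#' @param hits a hit table from [contig_similarity_search()] run with the
#'   spectrum's sequences as both queries and subjects; all hit ids must be
#'   spectrum ids.
#' @return a `corrected_spectrum`: a named integer vector of summed read
#'   counts per genotype cluster, sorted decreasing, with attributes
#'   `membership` (named character: contig id -> cluster id) and `n_reads`.
#' @export
correct_contig_spectrum <- function(spectrum, hits) {
  stopifnot(inherits(spectrum, "contig_spectrum"))
  ids <- names(spectrum)
  if (nrow(hits) > 0) {
    bad <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
    if (length(bad) > 0) {
      stop("hit ids absent from the spectrum: ", paste(head(bad, 3),
                                                       collapse = ", "))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(hits) > 0) hits[, c("query_id", "subject_id")]
        else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[ids]
  sums <- tapply(as.integer(spectrum), comp, sum)
  # deterministic cluster naming: decreasing count, then smallest member id
  first_id <- tapply(ids, comp, min)
  ord <- order(-as.integer(sums), first_id)
  cluster_ids <- setNames(sprintf("gt_%05d", order(ord)), names(sums))
  counts <- setNames(as.integer(sums)[ord], cluster_ids[names(sums)][ord])
  membership <- setNames(cluster_ids[as.character(comp)], ids)
  structure(counts, membership = membership,
            n_reads = sum(counts), class = "corrected_spectrum")
}

#' Fraction of one virome's contigs with homologues in another
#'
#' Samples `n_sampled` contigs from virome A (without replacement, or with
#' replacement when `n_sampled` exceeds the set size) and reports the
#' fraction having at least one similarity hit in virome B at
#' `e_value < e_value_max`.
#'
#' @param contigs_a,contigs_b named character vectors of contig sequences
#'   or `assembly_result` objects; both must be non-empty.
#' @param e_value_max E-value threshold (default `1e-10`).
#' @param min_frac_shorter minimum aligned fraction of the shorter sequence
#'   (default 0.50).
#' @param n_sampled contigs sampled from A (default 1000).
#' @param seed integer seed for the contig sample.
#' @return the shared fraction in `[0, 1]`.
#' @export
cross_sample_shared_fraction <- function(contigs_a, contigs_b,
                                         e_value_max = 1e-10,
                                         min_frac_shorter = 0.50,
                                         n_sampled = 1000, seed = 1) {
  a <- .as_seqset(contigs_a, "contigs_a")
  b <- .as_seqset(contigs_b, "contigs_b")
  if (length(a) == 0 || length(b) == 0) {
    stop("both contig sets must be non-empty")
  }
  if (n_sampled < 1) stop("n_sampled must be >= 1")
  # the two viromes are distinct samples: namespace the ids so that
  # coincidentally equal contig ids are not mistaken for self-hits
  names(a) <- paste0("a|", names(a))
  names(b) <- paste0("b|", names(b))
  set.seed(derive_seed(seed, "comparison"))
  pick <- sample.int(length(a), n_sampled,
                     replace = n_sampled > length(a))
  qs <- a[unique(pick)]
  hits <- contig_similarity_search(qs, b, e_value_max = e_value_max,
                                   min_frac_shorter = min_frac_shorter)
  has_hit <- setNames(names(qs) %in% hits$query_id, names(qs))
  mean(has_hit[names(a)[pick]])
}

#' Per-contig homologue indicators between viromes
#'
#' For every ordered pair of viromes, records which contigs of the first
#' have at least one similarity hit in the second. This is the
#' precomputation behind [permutation_shared_test()]: iterations then only
#' resample contig indices.
#'
#' @param viromes a named list of contig sets (named character vectors or
#'   `assembly_result` objects).
#' @inheritParams cross_sample_shared_fraction
#' @return a list of lists of logical vectors: `x[[i]][[j]]` has one entry
#'   per contig of virome `i`, `TRUE` when that contig has a homologue in
#'   virome `j`. Diagonal entries are `NULL`.
#' @export
shared_contig_indicators <- function(viromes, e_value_max = 1e-10,
                                     min_frac_shorter = 0.50) {
  sets <- lapply(viromes, .as_seqset)
  n <- length(sets)
  if (is.null(names(sets))) names(sets) <- paste0("virome_", seq_len(n))
  out <- vector("list", n)
  names(out) <- names(sets)
  for (i in seq_len(n)) {
    out[[i]] <- vector("list", n)
    names(out[[i]]) <- names(sets)
    for (j in seq_len(n)) {
      if (i == j) next
      qi <- sets[[i]]
      sj <- sets[[j]]
      names(qi) <- paste0("q|", names(qi))
      names(sj) <- paste0("s|", names(sj))
      hits <- contig_similarity_search(qi, sj,
                                       e_value_max = e_value_max,
                                       min_frac_shorter = min_frac_shorter)
      out[[i]][[j]] <- setNames(names(qi) %in% hits$query_id,
                                names(sets[[i]]))
    }
  }
  out
}
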