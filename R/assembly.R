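.extract_reads <- function(reads) {
  if (inherits(reads, "simulated_virome")) {
    setNames(reads$reads$sequence, reads$reads$id)
  } else if (is.data.frame(reads)) {
    stopifnot(all(c("id", "sequence") %in% names(reads)))
    setNames(reads$sequence, reads$id)
  } else {
    nm <- names(reads)
    x <- as.character(reads)  # as.character() drops names; restore them
    names(x) <- nm
    if (is.null(names(x))) names(x) <- sprintf("read_%06d", seq_along(x))
    x
  }
}

#' Greedy overlap-consensus assembly of virome reads
#'
#' Assembles reads by a deterministic greedy overlap-layout-consensus
#' strategy. Candidate overlaps are found by exact 25-mer seeding (both
#' strands) and evaluated ungapped; an overlap is accepted only when its
#' identity is at least `min_identity` and its length is at least
#' `max(min_overlap_abs, min_overlap_frac * shorter read length)`.
#' Accepted overlaps are merged highest-scoring (longest, then most
#' identical) first, with ties broken by lexicographic read id. The
#' consensus is called per column by majority rule over all member reads,
#' alphabetical base on ties. Contigs shorter than `min_contig_len`, with
#' ambiguous consensus characters, or consisting of a single read are
#' demoted to unassembled singletons.
#'
#' Coordinates are 0-based half-open; strand is recorded as `+`/`-`.
#'
#' @param reads a `simulated_virome`, a data.frame with `id`/`sequence`
#'   columns, or a (named) character vector of read sequences. Reads should
#'   already be QC-filtered (see [filter_reads()]).
#' @param min_identity minimum identity over the overlap (default 0.98).
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   sequence in the merge (default 0.50).
#' @param min_overlap_abs absolute minimum overlap in nt (default 25).
#' @param min_contig_len minimum retained contig length in nt (default 200).
#' @return an object of class `assembly_result`: a list with `contigs`
#'   (data.frame `id`, `sequence`, `length`, `read_count`,
#'   `mean_coverage`), `members` (per-contig character vectors of read
#'   ids), `layouts` (per-contig data.frames `read_id`, `offset`,
#'   `strand`), `singletons` (data.frame `read_id`, `sequence`),
#'   `parameters`, and `n_reads`. Every input read appears in exactly one
#'   contig or as exactly one singleton.
#' @export
assemble <- function(reads, min_identity = 0.98, min_overlap_frac = 0.50,
                     min_overlap_abs = 25, min_contig_len = 200) {
  if (min_identity <= 0 || min_identity > 1 || min_overlap_frac <= 0 ||
      min_overlap_frac > 1 || min_overlap_abs < 1) {
    stop("assembly parameters out of range")
  }
  x <- .extract_reads(reads)
  params <- list(min_identity = min_identity,
                 min_overlap_frac = min_overlap_frac,
                 min_overlap_abs = min_overlap_abs,
                 min_contig_len = min_contig_len)
  empty <- structure(list(
    contigs = data.frame(id = character(0), sequence = character(0),
                         length = integer(0), read_count = integer(0),
                         mean_coverage = numeric(0),
                         stringsAsFactors = FALSE),
    members = list(), layouts = list(),
    singletons = data.frame(read_id = character(0), sequence = character(0),
                            stringsAsFactors = FALSE),
    parameters = params, n_reads = 0L), class = "assembly_result")
  if (length(x) == 0) return(empty)
  if (anyDuplicated(names(x))) stop("read ids must be unique")

  rank <- match(names(x), sort(names(x)))
  res <- cpp_assemble(unname(x), rank, min_identity, min_overlap_frac,
                      as.integer(min_overlap_abs), 25L)

  n_comp <- length(res$members)
  keep <- logical(n_comp)
  for (i in seq_len(n_comp)) {
    keep[i] <- length(res$members[[i]]) >= 2 &&
      nchar(res$consensus[i]) >= min_contig_len && !res$ambiguous[i]
  }

  singleton_reads <- character(0)
  for (i in which(!keep)) {
    singleton_reads <- c(singleton_reads, names(x)[res$members[[i]]])
  }
  singleton_reads <- sort(singleton_reads)

  idx <- which(keep)
  if (length(idx) > 0) {
    counts <- vapply(res$members[idx], length, integer(1))
    lens <- nchar(res$consensus[idx])
    first_member <- vapply(idx, function(i) {
      min(names(x)[res$members[[i]]])
    }, character(1))
    ord <- order(-counts, -lens, first_member)
    idx <- idx[ord]
    counts <- counts[ord]
    lens <- lens[ord]
    ids <- sprintf("ctg_%05d", seq_along(idx))
    contigs <- data.frame(id = ids, sequence = res$consensus[idx],
                          length = as.integer(lens),
                          read_count = as.integer(counts),
                          mean_coverage = res$mean_coverage[idx],
                          stringsAsFactors = FALSE)
    members <- lapply(idx, function(i) names(x)[res$members[[i]]])
    layouts <- lapply(idx, function(i) {
      data.frame(read_id = names(x)[res$members[[i]]],
                 offset = res$offsets[[i]],
                 strand = c("+", "-")[res$strands[[i]] + 1L],
                 stringsAsFactors = FALSE)
    })
    names(members) <- ids
    names(layouts) <- ids
  } else {
    contigs <- empty$contigs
    members <- list()
    layouts <- list()
  }

  structure(list(
    contigs = contigs, members = members, layouts = layouts,
    singletons = data.frame(read_id = singleton_reads,
                            sequence = unname(x[singleton_reads]),
                            stringsAsFactors = FALSE),
    parameters = params, n_reads = length(x)), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf(
    "assembly_result: %d reads -> %d contigs (%d reads) + %d singletons\n",
    x$n_reads, nrow(x$contigs), sum(x$contigs$read_count),
    nrow(x$singletons)))
  if (nrow(x$contigs) > 0) {
    cat(sprintf("  contig lengths %d-%d nt, max read count %d\n",
                min(x$contigs$length), max(x$contigs$length),
                max(x$contigs$read_count)))
  }
  invisible(x)
}

#' Contig spectrum of an assembly
#'
#' The contig spectrum is the multiset of read counts per contig, the raw
#' surrogate for the viral population's abundance structure. Unassembled
#' singleton reads are counted as contigs of weight 1 unless
#' `include_singletons = FALSE`.
#'
#' @param result an `assembly_result`.
#' @param include_singletons count unassembled reads as weight-1 contigs
#'   (default `TRUE`).
#' @return a `contig_spectrum`: a named integer vector of read counts
#'   sorted in decreasing order (names are contig ids and, for singletons,
#'   read ids), with attribute `n_reads` equal to the total reads
#'   represented.
#' @export
contig_spectrum <- function(result, include_singletons = TRUE) {
  stopifnot(inherits(result, "assembly_result"))
  counts <- setNames(result$contigs$read_count, result$contigs$id)
  if (include_singletons && nrow(result$singletons) > 0) {
    counts <- c(counts, setNames(rep(1L, nrow(result$singletons)),
                                 result$singletons$read_id))
  }
  counts <- counts[order(-counts, names(counts))]
  structure(as.integer(counts), names = names(counts),
            n_reads = sum(counts), class = "contig_spectrum")
}

#' Sequences of the units of a contig spectrum
#'
#' Returns the consensus sequence of every assembled contig and (optionally)
#' the sequence of every unassembled singleton read, named consistently with
#' [contig_spectrum()], for use as similarity-search input.
#'
#' @inheritParams contig_spectrum
#' @return a named character vector.
#' @export
contig_sequences <- function(result, include_singletons = TRUE) {
  stopifnot(inherits(result, "assembly_result"))
  out <- setNames(result$contigs$sequence, result$contigs$id)
  if (include_singletons && nrow(result$singletons) > 0) {
    out <- c(out, setNames(result$singletons$sequence,
                           result$singletons$read_id))
  }
  out
}

#' Read-to-unit assignments of an assembly
#'
#' Maps each read to the spectrum unit that carries it: the contig it was
#' assembled into, or itself if it remained a singleton. Used for
#' rarefaction and for truth-table clustering oracles.
#'
#' @param result an `assembly_result`.
#' @return a named character vector: read id -> unit id.
#' @export
read_assignments <- function(result) {
  stopifnot(inherits(result, "assembly_result"))
  unit <- character(0)
  if (length(result$members) > 0) {
    unit <- setNames(rep(names(result$members),
                         lengths(result$members)),
                     unlist(result$members, use.names = FALSE))
  }
  if (nrow(result$singletons) > 0) {
    unit <- c(unit, setNames(result$singletons$read_id,
                             result$singletons$read_id))
  }
  unit
}

#' Map reads to a reference genome
#'
#' A read maps when its best ungapped local alignment (either strand)
#' covers at least `min_frac` of the read length at identity at least
#' `min_identity`.
#'
#' @param reads reads as accepted by [assemble()].
#' @param reference a single reference sequence (character) or one element
#'   of a `genome_pool`.
#' @param min_identity minimum alignment identity (default 0.98).
#' @param min_frac minimum aligned fraction of the read (default 0.50).
#' @return a list with `mapped` (named logical per read),
#'   `mapped_fraction`, `coverage` (integer per-position depth over the
#'   reference; length equals the reference length) and `mean_coverage`.
#' @export
map_reads_to_reference <- function(reads, reference, min_identity = 0.98,
                                   min_frac = 0.50) {
  x <- .extract_reads(reads)
  ref <- as.character(reference)[1]
  if (is.na(ref) || nchar(ref) == 0) stop("reference must be non-empty")
  if (length(x) == 0) {
    return(list(mapped = setNames(logical(0), character(0)),
                mapped_fraction = NaN,
                coverage = integer(nchar(ref)), mean_coverage = 0))
  }
  res <- cpp_map_reads(unname(x), ref, min_identity, min_frac, 13L, 30L)
  mapped <- setNames(res$mapped, names(x))
  list(mapped = mapped, mapped_fraction = mean(mapped),
       coverage = res$coverage, mean_coverage = mean(res$coverage))
}
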