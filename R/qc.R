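#' Filter virome reads before assembly
#'
#' Applies the deterministic read-level filters used on semiconductor
#' virome reads: removal of reads with substantial length variation
#' (shorter than `min_len` or longer than `max_len` nt), low-complexity
#' reads containing a homopolymer run longer than `max_homopolymer` bases
#' (a run of `max_homopolymer + 1` or more identical characters), and reads
#' with ambiguous (non-ACGT) characters. Platform-specific quality trimming
#' is intentionally not reproduced; these filters are its deterministic
#' replacement.
#'
#' Removals are categorized by the first failing rule in the order
#' length, then homopolymer, then ambiguity, so the category counts sum to
#' the number removed. The retained set itself does not depend on rule
#' order.
#'
#' @param reads a `simulated_virome`, a data.frame with columns `id` and
#'   `sequence`, or a (optionally named) character vector of sequences.
#' @param min_len,max_len retained length bounds in nt (defaults 50, 300).
#' @param max_homopolymer longest allowed homopolymer run (default 7, i.e.
#'   runs of >= 8 identical bases are removed).
#' @param allow_ambiguous keep reads containing non-ACGT characters
#'   (default `FALSE`).
#' @return a list with `reads` (retained reads, same representation as the
#'   input) and `report`, a `qc_report` with fields `input_count`,
#'   `removed_short`, `removed_long`, `removed_homopolymer`,
#'   `removed_ambiguous` and `retained_count`.
#' @export
#' @examples
#' filter_reads(c(a = strrep("ACGT", 50), b = strrep("A", 60)))$report
filter_reads <- function(reads, min_len = 50, max_len = 300,
                         max_homopolymer = 7, allow_ambiguous = FALSE) {
  if (min_len <= 0 || max_len <= 0 || max_homopolymer <= 0) {
    stop("thresholds must be positive")
  }
  virome <- inherits(reads, "simulated_virome")
  df <- is.data.frame(reads) || virome
  seqs <- if (virome) reads$reads$sequence
          else if (is.data.frame(reads)) reads$sequence
          else as.character(reads)

  len <- nchar(seqs)
  short <- len < min_len
  long <- !short & len > max_len
  homop <- grepl(sprintf("(.)\\1{%d,}", max_homopolymer), seqs)
  homop <- homop & !short & !long
  amb <- if (allow_ambiguous) rep(FALSE, length(seqs))
         else grepl("[^ACGT]", seqs) & !short & !long & !homop
  keep <- !(short | long | homop | amb)

  report <- structure(list(
    input_count = length(seqs),
    removed_short = sum(short),
    removed_long = sum(long),
    removed_homopolymer = sum(homop),
    removed_ambiguous = sum(amb),
    retained_count = sum(keep)), class = "qc_report")

  retained <- if (virome) {
    out <- reads
    out$reads <- reads$reads[keep, , drop = FALSE]
    rownames(out$reads) <- NULL
    tab <- table(factor(out$reads$genotype,
                        levels = names(reads$truth_spectrum)))
    out$truth_spectrum <- setNames(as.integer(tab),
                                   names(reads$truth_spectrum))
    out
  } else if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    reads[keep]
  }
  list(reads = retained, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d reads in, %d retained (%d short, %d long, %d homopolymer, %d ambiguous removed)\n",
    x$input_count, x$retained_count, x$removed_short, x$removed_long,
    x$removed_homopolymer, x$removed_ambiguous))
  invisible(x)
}
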