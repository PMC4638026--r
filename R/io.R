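# Sequence and table I/O. FASTA/FASTQ go through Biostrings; tables are
# plain TSV; summaries are JSON via jsonlite.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector (first whitespace-delimited token of each
#'   header as the name).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write sequences to FASTQ with constant quality
#'
#' Simulated reads carry no per-base quality model, so a constant Phred
#' quality (default 30, character `?`) is emitted.
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param quality constant Phred quality (default 30).
#' @export
write_fastq <- function(seqs, path, quality = 30) {
  qc <- rawToChar(as.raw(quality + 33L))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(qc, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Write a simulated virome to disk
#'
#' Emits reads as FASTA (or FASTQ when `fastq = TRUE`) and the ground-truth
#' table as TSV with columns `read_id`, `genotype_id`, `start` (0-based),
#' `strand`.
#'
#' @param virome a `simulated_virome`.
#' @param prefix output path prefix; writes `<prefix>.fasta` (or `.fastq`)
#'   and `<prefix>.truth.tsv`.
#' @param fastq write FASTQ instead of FASTA.
#' @return invisibly, the paths written.
#' @export
write_virome <- function(virome, prefix, fastq = FALSE) {
  stopifnot(inherits(virome, "simulated_virome"))
  seqs <- setNames(virome$reads$sequence, virome$reads$id)
  seq_path <- paste0(prefix, if (fastq) ".fastq" else ".fasta")
  if (fastq) write_fastq(seqs, seq_path) else write_fasta(seqs, seq_path)
  truth_path <- paste0(prefix, ".truth.tsv")
  utils::write.table(
    data.frame(read_id = virome$reads$id, genotype_id = virome$reads$genotype,
               start = virome$reads$start, strand = virome$reads$strand),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(seq_path, truth_path))
}

#' Write an abundance profile as JSON
#'
#' @param profile an `abundance_profile`.
#' @param path output JSON file.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "abundance_profile"))
  jsonlite::write_json(
    list(genotype_ids = profile$genotype_ids,
         proportions = profile$proportions,
         target_evenness = profile$target_evenness,
         achieved_evenness = profile$achieved_evenness,
         S = profile$S, r = profile$r),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a contig spectrum (raw or corrected) as TSV
#'
#' @param spectrum a `contig_spectrum` or `corrected_spectrum`.
#' @param path output TSV file.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(id = names(spectrum), read_count = as.integer(spectrum)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write similarity hits in 12-column tabular format
#'
#' @param hits a hit table from [contig_similarity_search()].
#' @param path output TSV file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
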