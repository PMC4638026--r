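.default_config <- function() {
  list(
    seed = 1L,
    # simulate (used when no input_fasta is given)
    n_genotypes = 10L, target_evenness = 0.67, evenness_tolerance = 0.01,
    n_reads = 2000L, genome_length = c(10000, 10000), gc_content = 0.5,
    len_mean = 200, len_min = 150, len_max = 250, len_sd = 25,
    error_rate = 0, homopolymer_rate = 0, ambiguous_rate = 0,
    # ingest
    input_fasta = NULL,
    # qc
    qc_min_len = 50, qc_max_len = 300, qc_max_homopolymer = 7,
    qc_allow_ambiguous = FALSE,
    # assembly
    min_identity = 0.98, min_overlap_frac = 0.50, min_overlap_abs = 25,
    min_contig_len = 200,
    # clustering
    cluster_e_value = 1e-20, cluster_min_frac_shorter = 0.50,
    include_singletons = TRUE,
    # diversity
    rarefaction_depths = c(500, 1000, 2000, 5000, 10000, 20000),
    rarefaction_reps = 10,
    # output
    out_dir = NULL)
}

#' Build a validated pipeline configuration
#'
#' Merges user settings over the stage defaults; unknown keys are rejected
#' so typos cannot silently fall back to defaults. The configuration
#' round-trips through JSON.
#'
#' @param ... configuration entries overriding the defaults (see
#'   [run_pipeline()] for their meaning), or a single named list.
#' @return a `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(n_genotypes = 5, n_reads = 500, seed = 42)
pipeline_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]])) {
    dots <- dots[[1]]
  }
  defaults <- .default_config()
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # output location is not science
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg[order(names(cfg))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

#' Run the full virome diversity pipeline
#'
#' Executes the stages simulate (or ingest) -> QC -> assemble -> cluster ->
#' diversity in order, logging per-stage counts. With `input_fasta` set,
#' reads are loaded from FASTA instead of simulated (truth-based quantities
#' are then unavailable). Every artifact is stamped with the configuration
#' hash and seed so runs are reproducible from `(config, seed)` alone. When
#' `out_dir` is set, stage outputs are also written there (FASTA contigs,
#' TSV spectra and truth tables, JSON summaries).
#'
#' @param config a `pipeline_config` (or arguments for one).
#' @return a `pipeline_result` bundle: `config`, `config_hash`, `virome`
#'   (when simulated), `qc_report`, `assembly`, `spectrum`, `hits`,
#'   `corrected`, `diversity` (Shannon-form HVDI result), `rarefaction`,
#'   and `log` (per-stage counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config)
  }
  cfg <- config
  hash <- .config_hash(cfg)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }
  fail <- function(stage, msg) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, msg),
         call. = FALSE)
  }

  # --- simulate / ingest ---
  virome <- NULL
  if (is.null(cfg$input_fasta)) {
    pool <- generate_genome_pool(cfg$n_genotypes, cfg$genome_length,
                                 cfg$gc_content, seed = cfg$seed)
    profile <- construct_abundance_profile(
      cfg$n_genotypes, cfg$target_evenness, cfg$evenness_tolerance,
      seed = cfg$seed, genotype_ids = names(pool))
    virome <- sample_reads(pool, profile, cfg$n_reads,
                           len_mean = cfg$len_mean, len_min = cfg$len_min,
                           len_max = cfg$len_max, len_sd = cfg$len_sd,
                           error_rate = cfg$error_rate,
                           homopolymer_rate = cfg$homopolymer_rate,
                           ambiguous_rate = cfg$ambiguous_rate,
                           seed = cfg$seed)
    reads <- virome
    note("simulate", n_genomes = cfg$n_genotypes,
         achieved_evenness = profile$achieved_evenness,
         n_reads = nrow(virome$reads))
  } else {
    if (!file.exists(cfg$input_fasta)) {
      fail("ingest", paste("input FASTA not found:", cfg$input_fasta))
    }
    reads <- read_fasta(cfg$input_fasta)
    note("ingest", path = cfg$input_fasta, n_reads = length(reads))
  }

  # --- qc ---
  qc <- filter_reads(reads, min_len = cfg$qc_min_len,
                     max_len = cfg$qc_max_len,
                     max_homopolymer = cfg$qc_max_homopolymer,
                     allow_ambiguous = cfg$qc_allow_ambiguous)
  note("qc", retained = qc$report$retained_count,
       removed = qc$report$input_count - qc$report$retained_count)

  # --- assemble ---
  asm <- assemble(qc$reads, min_identity = cfg$min_identity,
                  min_overlap_frac = cfg$min_overlap_frac,
                  min_overlap_abs = cfg$min_overlap_abs,
                  min_contig_len = cfg$min_contig_len)
  spectrum <- contig_spectrum(asm,
                              include_singletons = cfg$include_singletons)
  note("assemble", contigs = nrow(asm$contigs),
       singletons = nrow(asm$singletons))

  # --- cluster ---
  seqs <- contig_sequences(asm,
                           include_singletons = cfg$include_singletons)
  hits <- if (length(seqs) > 0) {
    contig_similarity_search(seqs, seqs,
                             e_value_max = cfg$cluster_e_value,
                             min_frac_shorter = cfg$cluster_min_frac_shorter)
  } else {
    fail("cluster", "no spectrum units to cluster")
  }
  corrected <- correct_contig_spectrum(spectrum, hits)
  note("cluster", hits = nrow(hits), genotypes = length(corrected))

  # --- diversity ---
  div <- hvdi(corrected, "shannon")
  mem <- attr(corrected, "membership")
  assign_map <- read_assignments(asm)
  assign_map <- setNames(unname(mem[assign_map]), names(assign_map))
  rare <- rarefaction_curve(assign_map, depths = cfg$rarefaction_depths,
                            reps_per_depth = cfg$rarefaction_reps,
                            seed = cfg$seed)
  note("diversity", H = div$H, S_obs = div$S_obs, chao1 = div$chao1)

  result <- structure(list(
    config = cfg, config_hash = hash, seed = cfg$seed, virome = virome,
    qc_report = qc$report, assembly = asm, spectrum = spectrum,
    hits = hits, corrected = corrected, diversity = div,
    rarefaction = rare, log = log), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(config_hash = hash, seed = cfg$seed)
    if (!is.null(virome)) write_virome(virome, file.path(cfg$out_dir, "reads"))
    if (nrow(asm$contigs) > 0) {
      write_fasta(setNames(asm$contigs$sequence, asm$contigs$id),
                  file.path(cfg$out_dir, "contigs.fasta"))
    }
    write_spectrum_tsv(spectrum, file.path(cfg$out_dir, "spectrum.tsv"))
    write_spectrum_tsv(corrected,
                       file.path(cfg$out_dir, "corrected_spectrum.tsv"))
    write_hits_tsv(hits, file.path(cfg$out_dir, "hits.tsv"))
    jsonlite::write_json(
      c(stamp, list(qc = unclass(qc$report),
                    diversity = unclass(div), log = log)),
      file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
    utils::write.table(rare, file.path(cfg$out_dir, "rarefaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (seed %s, config %s)\n", format(x$seed),
              substr(x$config_hash, 1, 8)))
  for (stage in names(x$log)) {
    vals <- x$log[[stage]]
    cat(sprintf("  %-9s %s\n", stage,
                paste(names(vals), vapply(vals, format, character(1)),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Generate the deterministic fixture set used by the test suite
#'
#' Writes, under `out_dir`: a 5-genome pool (`pool.fasta`); error-free reads
#' tiling the first genome on both strands (`tiled_reads.fasta` +
#' `tiled_reads.truth.tsv`); a contig set containing a known duplicate pair
#' (`contigs_dup.fasta`); three virome pairs whose genome pools share 0, 50
#' and 100 percent of their genomes (`share<p>_{a,b}.fasta` + truth); and a
#' five-time-point persistence series with a persistent genome subset
#' (`timepoint<k>.fasta` + `persistence_labels.tsv`). Identical seeds yield
#' byte-identical files.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a manifest data.frame of the files written.
#' @export
generate_fixture_set <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  pool <- generate_genome_pool(5, c(5000, 5000), seed = seed)
  paths <- c(paths, write_fasta(pool, file.path(out_dir, "pool.fasta")))

  # error-free 200-nt reads tiling genome 1 every 50 nt, alternating strand
  g <- pool[[1]]
  starts <- seq(0, nchar(g) - 200, by = 50)
  tiles <- substring(g, starts + 1, starts + 200)
  strands <- rep(c("+", "-"), length.out = length(starts))
  tiles[strands == "-"] <- .revcomp(tiles[strands == "-"])
  names(tiles) <- sprintf("tile_%04d", seq_along(tiles))
  paths <- c(paths, write_fasta(tiles, file.path(out_dir,
                                                 "tiled_reads.fasta")))
  truth <- data.frame(read_id = names(tiles), genotype_id = names(pool)[1],
                      start = starts, strand = strands)
  tp <- file.path(out_dir, "tiled_reads.truth.tsv")
  utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tp)

  # contig set with a known duplicate pair: contig_2 is a copy of a slice
  # of contig_1; contig_3 is unrelated
  contigs <- c(contig_1 = substring(pool[[2]], 1, 1500),
               contig_2 = substring(pool[[2]], 301, 1100),
               contig_3 = substring(pool[[3]], 1, 1200))
  paths <- c(paths, write_fasta(contigs,
                                file.path(out_dir, "contigs_dup.fasta")))

  # virome pairs sharing 0 / 50 / 100 percent of source genomes
  big <- generate_genome_pool(12, c(5000, 5000), seed = derive_seed(seed, 1))
  share <- list(share0 = list(a = 1:4, b = 5:8),
                share50 = list(a = 1:4, b = c(3:4, 9:10)),
                share100 = list(a = 1:4, b = 1:4))
  for (nm in names(share)) {
    for (side in c("a", "b")) {
      gs <- share[[nm]][[side]]
      sub <- structure(big[gs], seed = seed, max_shared_kmer_fraction = 0,
                       class = "genome_pool")
      prof <- construct_abundance_profile(length(gs), 1,
                                          genotype_ids = names(sub))
      vir <- sample_reads(sub, prof, 2500,
                          seed = derive_seed(seed, 2) +
                            match(nm, names(share)) * 10 +
                            match(side, c("a", "b")))
      paths <- c(paths, write_virome(vir, file.path(out_dir,
                                                    paste0(nm, "_", side))))
    }
  }

  # persistence series: genomes 1-2 persist through all 5 time points,
  # genomes 3-6 each appear at a single time point
  labels <- data.frame(contig_id = character(0), sample = character(0))
  for (t in 1:5) {
    gs <- c(1, 2, 2 + t)
    segs <- setNames(substring(big[gs], 1, 2000),
                     sprintf("t%d_c%d", t, seq_along(gs)))
    paths <- c(paths, write_fasta(segs, file.path(out_dir,
                                                  sprintf("timepoint%d.fasta", t))))
    labels <- rbind(labels, data.frame(contig_id = names(segs),
                                       sample = sprintf("t%d", t)))
  }
  lp <- file.path(out_dir, "persistence_labels.tsv")
  utils::write.table(labels, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, lp)

  invisible(data.frame(path = paths, stringsAsFactors = FALSE))
}
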