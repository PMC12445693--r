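# One-command end-to-end run on simulated data: simulate -> alignments ->
# terminal calling -> trimming -> grouping -> annotation -> UTR analysis ->
# abundance. A single config object carries every stage's parameters,
# including the mapping/clustering/trimming constants used throughout the
# package; a manifest records parameters and output checksums so a rerun
# with the same seed is bit-identical.

#' Pipeline configuration
#'
#' Returns the full default configuration; supply overrides as named nested
#' lists. Unknown keys are rejected.
#'
#' @param ... named overrides, e.g. `terminals = list(window = 60)`.
#' @param seed integer seed for the simulation stage.
#' @return nested config list of class `flds_pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    sim = as.list(unclass(sim_config(seed = seed))),
    terminals = list(window = 50L, min_events = 3L, enrich = 5.0,
                     max_mismatch = 1L),
    grouping = list(W = 30L, min_id = 0.8, max_offset = 5L),
    annotate = list(min_aa = 60L, sd_motif = "AGGAGG"),
    utr = list(window = 100L, step = 10L, min_id = 0.68),
    abundance = list(min_identity = 0.97, max_indel = 3L,
                     cluster_id = 0.97, pool_below = 0.02),
    consensus = list(max_gap = 0.67, min_homogeneity = 0.05, reps = 40L)
  )
  overrides <- list(...)
  for (blk in names(overrides)) {
    if (!blk %in% names(defaults)) {
      abort(sprintf("unknown config block '%s'", blk))
    }
    if (is.list(overrides[[blk]])) {
      for (key in names(overrides[[blk]])) {
        if (!key %in% names(defaults[[blk]])) {
          abort(sprintf("unknown config key '%s$%s'", blk, key))
        }
        defaults[[blk]][[key]] <- overrides[[blk]][[key]]
      }
    } else {
      defaults[[blk]] <- overrides[[blk]]
    }
  }
  defaults$sim$seed <- defaults$seed
  class(defaults) <- "flds_pipeline_config"
  defaults
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate -> truth alignments -> terminal calling -> trimming ->
#' grouping -> annotation -> UTR analysis -> abundance, writes stage outputs
#' (FASTA/FASTQ/TSV/GFF3) and a manifest with parameters and md5 checksums
#' into `output_dir`, and returns all stage results. Rerunning with the same
#' seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir output directory (created if missing); NULL skips file
#'   output.
#' @return list of class `flds_run` with elements `genomes`, `sim`,
#'   `alignments`, `profiles`, `calls`, `trimmed`, `sets`, `orfs`,
#'   `stop_map`, `trinuc`, `abundance`, `manifest`.
#' @export
run_flds_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "flds_pipeline_config"))
  cfg <- do.call(sim_config, config$sim)

  genomes <- simulate_genomes(cfg)
  sim <- simulate_flds_reads(genomes, cfg)
  contigs <- make_contigs(genomes)
  aln <- truth_alignments(sim, genomes, contigs)

  tp <- config$terminals
  profiles <- detect_adaptor_junctions(aln, contigs, cfg$adaptor,
                                       max_mismatch = tp$max_mismatch)
  calls <- call_completeness(profiles, window = tp$window,
                             min_events = tp$min_events, enrich = tp$enrich)
  complete <- calls$contig_id[calls$status5 == "complete" &
                                calls$status3 == "complete"]
  trimmed <- trim_to_termini(contigs[contigs$id %in% complete, ],
                             calls[calls$contig_id %in% complete, ])

  gp <- config$grouping
  sigs <- terminal_signature(trimmed, W = gp$W)
  sets <- group_segments(sigs, min_id = gp$min_id, max_offset = gp$max_offset)

  ap <- config$annotate
  orfs <- annotate_segments(trimmed, min_aa = ap$min_aa, sd_motif = ap$sd_motif)

  smap <- stop_codon_map(trimmed)
  regions <- utr_cds_regions(genomes)
  trinuc <- trinuc_profile(regions)

  abp <- config$abundance
  lens <- setNames(nchar(contigs$seq), contigs$id)
  counts <- count_fragments(aln, NULL, lens,
                            min_identity = abp$min_identity,
                            max_indel = abp$max_indel)
  abund <- fpkm_table(counts, lens, total_cleaned_reads = nrow(sim$reads))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fldseg")),
    seed = config$seed,
    parameters = unclass(config),
    n_reads = nrow(sim$reads),
    n_contigs = nrow(contigs)
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_fastq(sim$reads, p("reads.fastq"))
    write_fasta(contigs, p("contigs.fasta"))
    readr::write_tsv(sim$truth |> select(-"seq"), p("truth.tsv"))
    readr::write_tsv(calls, p("terminals.tsv"))
    write_fasta(trimmed, p("trimmed.fasta"))
    readr::write_tsv(sets$membership, p("genomes.tsv"))
    write_gff(orfs, setNames(nchar(trimmed$seq), trimmed$id),
              p("annotations.gff3"))
    readr::write_tsv(tibble(id = orfs$orf_id, protein = orfs$protein),
                     p("proteins.tsv"))
    readr::write_tsv(as_tibble(smap), p("stops.tsv"))
    readr::write_tsv(as_tibble(trinuc), p("trinuc.tsv"))
    readr::write_tsv(abund, p("abundance.tsv"))
    files <- sort(list.files(output_dir, full.names = TRUE))
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    writeLines(yaml::as.yaml(manifest), p("manifest.yaml"))
  }

  out <- list(
    genomes = genomes, sim = sim, alignments = aln, profiles = profiles,
    calls = calls, trimmed = trimmed, sets = sets, orfs = orfs,
    stop_map = smap, trinuc = trinuc, abundance = abund, manifest = manifest
  )
  class(out) <- "flds_run"
  out
}

#' Extract UTR and CDS regions of simulated genomes for composition analysis
#'
#' Returns one region per long 5'UTR plus the RdRP and other CDS regions,
#' labelled for [trinuc_profile()].
#'
#' @param genomes an `flds_genomes` object.
#' @return region tibble `id`, `seq`, `kind`.
#' @export
utr_cds_regions <- function(genomes) {
  stopifnot(inherits(genomes, "flds_genomes"))
  segs <- genomes$segments
  tl <- genomes$config$terminal_len
  utrs <- segs |>
    filter(.data$role == "RNA1", .data$utr5_len >= 200L) |>
    mutate(
      id = paste0(.data$segment_id, ":utr5"),
      seq = substr(.data$seq, tl + 1L, tl + .data$utr5_len),
      kind = "utr"
    ) |>
    select("id", "seq", "kind")
  cds <- genomes$orfs |>
    left_join(segs |> select("segment_id", seg = "seq"), by = "segment_id") |>
    mutate(
      id = paste0(.data$segment_id, ":", .data$role, ":", .data$start),
      seq = substr(.data$seg, .data$start + 1L, .data$end),
      kind = ifelse(.data$role == "rdrp", "cds_rdrp", "cds_other")
    ) |>
    select("id", "seq", "kind")
  bind_rows(utrs, cds)
}
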