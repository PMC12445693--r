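# Readers/writers for the standard formats the pipeline touches. Sequences
# are plain tibbles (id, seq, description); alignments are one row per mapped
# SAM record. Heavy lifting is delegated to Biostrings / Rsamtools /
# GenomicAlignments; this file only adapts their containers to the tabular
# record model used throughout the package.

#' Read a FASTA file into a sequence tibble
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id` (first header token), `seq` (uppercase
#'   nucleotides over A/C/G/T/N) and `description` (header remainder, possibly
#'   empty). Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("FASTA parse error in %s: %s", path, conditionMessage(e)))
  )
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    abort(sprintf("FASTA record with empty header in %s", path))
  }
  out <- tibble(
    id = sub("\\s.*$", "", headers),
    seq = str_to_upper(as.character(set)),
    description = trimws(sub("^\\S+\\s*", "", headers))
  )
  validate_seq_tbl(out, arg = path)
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with `id`, `seq` and optionally `description`.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  validate_seq_tbl(seqs)
  set <- Biostrings::BStringSet(seqs$seq)
  desc <- if ("description" %in% names(seqs)) seqs$description else
    rep("", nrow(seqs))
  names(set) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path path to a FASTQ file.
#' @return tibble with columns `id`, `seq`, `qual` (per-base quality string of
#'   equal length).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(as.character(set)),
    qual = unname(as.character(S4Vectors::mcols(set)$qualities))
  )
  bad <- which(nchar(out$qual) != nchar(out$seq))
  if (length(bad)) {
    abort(sprintf("read '%s': quality and sequence lengths differ", out$id[bad[1]]))
  }
  out
}

#' Write a read tibble to FASTQ
#'
#' Reads without a `qual` column (or with `NA`) get a flat "I" quality string.
#'
#' @param reads tibble with `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$seq)), qual)
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  Biostrings::writeXStringSet(
    set, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' Read mapped records from a SAM file into an alignment tibble
#'
#' Converts each mapped SAM record to the package's alignment record:
#' 0-based half-open reference coordinates, soft-clipped prefix/suffix
#' sequences, indel event count, and alignment identity. Identity is
#' `matched / (aligned read bases including insertions)`, derived from the NM
#' tag when present, else from the MD tag, else `NA` (unknown). Unmapped
#' records are skipped; their count is attached as attribute
#' `n_unmapped_skipped` and reported with a message.
#'
#' @param path path to a SAM file with an `@SQ`-bearing header.
#' @return tibble with columns `read_id`, `ref_id`, `ref_start`, `ref_end`,
#'   `strand` ("+"/"-"), `identity`, `indel_count`, `clipped_prefix`,
#'   `clipped_suffix`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  header <- readLines(path, n = 1000L)
  if (!any(startsWith(header, "@SQ"))) {
    abort(sprintf("SAM file %s has no @SQ header lines (reference lengths unknown)", path))
  }
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
    error = function(e) abort(sprintf("SAM parse error in %s: %s", path, conditionMessage(e)))
  )
  on.exit(unlink(bam), add = TRUE)
  param_all <- Rsamtools::ScanBamParam(what = "flag")
  n_total <- length(Rsamtools::scanBam(bam, param = param_all)[[1]]$flag)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_skipped <- n_total - length(rec$qname)
  if (n_skipped > 0) {
    inform(sprintf("read_sam: skipped %d unmapped record(s)", n_skipped))
  }
  if (length(rec$qname) == 0) {
    out <- tibble(
      read_id = character(), ref_id = character(),
      ref_start = integer(), ref_end = integer(), strand = character(),
      identity = double(), indel_count = integer(),
      clipped_prefix = character(), clipped_suffix = character()
    )
    attr(out, "n_unmapped_skipped") <- n_skipped
    return(out)
  }

  cigar <- rec$cigar
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  seq_chr <- as.character(rec$seq)

  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qry_width <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE
  )
  clip5 <- map2_int_(ops, lens, function(o, l) {
    lead <- cumsum(o %in% c("S", "H"))
    soft <- o == "S" & lead == seq_along(o)
    sum(l[soft])
  })
  clip3 <- map2_int_(ops, lens, function(o, l) {
    ro <- rev(o); rl <- rev(l)
    lead <- cumsum(ro %in% c("S", "H"))
    soft <- ro == "S" & lead == seq_along(ro)
    sum(rl[soft])
  })
  indel_events <- map2_int_(ops, lens, function(o, l) sum(o %in% c("I", "D")))
  ins_bases <- map2_int_(ops, lens, function(o, l) sum(l[o == "I"]))
  del_bases <- map2_int_(ops, lens, function(o, l) sum(l[o == "D"]))
  m_bases <- qry_width - ins_bases # M/=/X read bases

  nm <- rec$tag$NM
  md <- rec$tag$MD
  mismatches <- rep(NA_integer_, length(cigar))
  if (!is.null(nm)) {
    mismatches <- as.integer(nm) - ins_bases - del_bases
  }
  if (!is.null(md)) {
    use_md <- is.na(mismatches) & !is.na(md)
    if (any(use_md)) {
      mismatches[use_md] <- vapply(md[use_md], md_mismatch_count, integer(1))
    }
  }
  identity <- (m_bases - mismatches) / (m_bases + ins_bases)
  identity[!is.na(identity) & identity < 0] <- 0

  out <- tibble(
    read_id = rec$qname,
    ref_id = as.character(rec$rname),
    ref_start = rec$pos - 1L,
    ref_end = rec$pos - 1L + ref_width,
    strand = ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+"),
    identity = identity,
    indel_count = indel_events,
    clipped_prefix = substr(seq_chr, 1L, clip5),
    clipped_suffix = substr(seq_chr, nchar(seq_chr) - clip3 + 1L, nchar(seq_chr))
  )
  out$clipped_suffix[clip3 == 0L] <- ""
  attr(out, "n_unmapped_skipped") <- n_skipped
  out
}

map2_int_ <- function(a, b, f) {
  as.integer(unlist(Map(f, a, b), use.names = FALSE))
}

# Number of substitutions encoded in an MD tag (letters outside ^-deletions).
md_mismatch_count <- function(md) {
  toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]|[0-9]+", md))[[1]]
  sum(grepl("^[A-Z]$", toks))
}

#' Write ORF annotations to a GFF3 file
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention. Shine-Dalgarno motif calls and transmembrane-scan
#' flags are emitted as attributes.
#'
#' @param annotations tibble with at least `segment_id`, `start`, `end`
#'   (0-based half-open), `strand`; optional `orf_id`, `sd_motif`,
#'   `sd_spacer`, `tm_segments` (list column of 2-column matrices or
#'   data frames), `tm_method`.
#' @param seq_lengths named integer vector of parent sequence lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotations, seq_lengths, path) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  need <- c("segment_id", "start", "end", "strand")
  if (!all(need %in% names(annotations))) {
    abort(sprintf("annotations must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(annotations$segment_id %in% names(seq_lengths))) {
    abort("annotation references a segment absent from seq_lengths")
  }
  lim <- unname(seq_lengths[annotations$segment_id])
  if (any(annotations$start < 0 | annotations$end > lim | annotations$start >= annotations$end)) {
    abort("annotation coordinates fall outside the parent sequence")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$segment_id,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand,
    seqlengths = seq_lengths
  )
  S4Vectors::mcols(gr)$source <- "fldseg"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- annotations$orf_id %||%
    sprintf("%s.orf%02d", annotations$segment_id, seq_len(nrow(annotations)))
  if ("sd_motif" %in% names(annotations)) {
    S4Vectors::mcols(gr)$sd_motif <- ifelse(is.na(annotations$sd_motif), "none", annotations$sd_motif)
    S4Vectors::mcols(gr)$sd_spacer <- annotations$sd_spacer
  }
  if ("tm_segments" %in% names(annotations)) {
    S4Vectors::mcols(gr)$tm_segments <- vapply(annotations$tm_segments, function(tm) {
      if (is.null(tm) || NROW(tm) == 0) return("none")
      paste(sprintf("%d-%d", tm[[1]], tm[[2]]), collapse = ",")
    }, character(1))
    S4Vectors::mcols(gr)$tm_method <- annotations$tm_method %||% "hydropathy_surrogate"
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
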