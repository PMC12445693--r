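# RdRP-contig clustering, mapped-fragment quantification under the 0.97
# identity / 3 indel filter, and FPKM-based community composition with the
# 2% pooling rule for minor taxa.

#' Greedy incremental clustering of contigs at an identity threshold
#'
#' Contigs are sorted by length (descending) and each is assigned to the
#' first representative reaching `min_id` global identity (matches divided by
#' the shorter sequence length) over at least `min_cov` of the shorter
#' sequence; otherwise it founds a new cluster. A shared-k-mer prefilter
#' skips hopeless pairs; identity comes from an ends-free pairwise alignment
#' ([Biostrings::pairwiseAlignment()]). Deterministic.
#'
#' @param contigs sequence tibble (`id`, `seq`).
#' @param min_id identity threshold (fraction of the shorter length).
#' @param min_cov minimum aligned coverage of the shorter sequence.
#' @param word_size k-mer length of the prefilter.
#' @return object of class `flds_clusters`: list with `clusters` (tibble
#'   `representative_id`, `member_ids` list, `n_members`) and `membership`
#'   (tibble `contig_id`, `representative_id`).
#' @export
greedy_cluster <- function(contigs, min_id = 0.97, min_cov = 0.8,
                           word_size = 8L) {
  validate_seq_tbl(contigs, "contigs")
  ord <- order(-nchar(contigs$seq), contigs$id)
  contigs <- contigs[ord, ]
  kmers <- function(s) {
    n <- nchar(s)
    if (n < word_size) return(character(0))
    unique(substring(s, 1:(n - word_size + 1), word_size:n))
  }
  kms <- lapply(contigs$seq, kmers)
  reps <- integer(0)
  assign <- integer(nrow(contigs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in seq_len(nrow(contigs))) {
    found <- 0L
    if (min_id <= 0 && length(reps)) found <- reps[1] # threshold dominance
    for (r in if (found) integer(0) else reps) {
      shared <- mean(kms[[i]] %in% kms[[r]])
      if (min_id > 0 && (!length(kms[[i]]) || shared < 0.3)) next
      aln <- Biostrings::pairwiseAlignment(
        contigs$seq[i], contigs$seq[r], type = "overlap",
        substitutionMatrix = submat, gapOpening = 4, gapExtension = 1
      )
      shorter <- min(nchar(contigs$seq[i]), nchar(contigs$seq[r]))
      ident <- Biostrings::nmatch(aln) / shorter
      span <- min(
        S4Vectors::width(Biostrings::pattern(aln)@range),
        S4Vectors::width(Biostrings::subject(aln)@range)
      )
      if (ident >= min_id && span / shorter >= min_cov) {
        found <- r
        break
      }
    }
    if (found > 0L) {
      assign[i] <- found
    } else {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  clusters <- list_rbind(map(reps, function(r) {
    mem <- contigs$id[assign == r]
    tibble(representative_id = contigs$id[r],
           member_ids = list(mem), n_members = length(mem))
  }))
  membership <- tibble(
    contig_id = contigs$id,
    representative_id = contigs$id[assign]
  )
  out <- list(clusters = clusters, membership = membership,
              identity_threshold = min_id)
  class(out) <- "flds_clusters"
  out
}

#' @export
print.flds_clusters <- function(x, ...) {
  cat(sprintf("<flds_clusters> %d cluster(s) over %d contig(s) at %.2f identity\n",
              nrow(x$clusters), nrow(x$membership), x$identity_threshold))
  print(x$clusters, ...)
  invisible(x)
}

#' Count mapped fragments per cluster representative
#'
#' Alignments failing the mapping filter (identity below `min_identity` or
#' more than `max_indel` indel events) are discarded. A read pair counts once
#' (fragment semantics: the `/1`/`/2` suffix is stripped from read ids).
#' Multi-mapped fragments go to their best-identity hit, ties broken to the
#' longest representative, then alphabetically.
#'
#' @param alignments alignment tibble.
#' @param clusters `flds_clusters` from [greedy_cluster()] (or NULL to treat
#'   every contig as its own representative).
#' @param contig_lengths named vector of contig lengths (nt).
#' @param min_identity minimum mapped identity.
#' @param max_indel maximum mapped indel events.
#' @return tibble `representative_id`, `mapped_fragments`.
#' @export
count_fragments <- function(alignments, clusters = NULL, contig_lengths,
                            min_identity = 0.97, max_indel = 3L) {
  aln <- alignments |>
    filter(!is.na(.data$identity),
           .data$identity >= min_identity,
           .data$indel_count <= max_indel)
  if (!is.null(clusters)) {
    aln <- aln |>
      left_join(clusters$membership, by = c(ref_id = "contig_id"))
    if (any(is.na(aln$representative_id))) {
      abort("alignment references a contig absent from the clustering")
    }
  } else {
    aln$representative_id <- aln$ref_id
  }
  aln$fragment_id <- sub("/[12]$", "", aln$read_id)
  aln$rep_len <- unname(contig_lengths[aln$representative_id])
  best <- aln |>
    arrange(.data$fragment_id, dplyr::desc(.data$identity),
            dplyr::desc(.data$rep_len), .data$representative_id) |>
    distinct(.data$fragment_id, .keep_all = TRUE)
  best |>
    dplyr::count(.data$representative_id, name = "mapped_fragments")
}

#' FPKM table
#'
#' FPKM = mapped fragments / (contig length in kb x cleaned-up reads in
#' millions). The relative share column is FPKM normalized to sum to 1.
#'
#' @param counts tibble `representative_id` (or `contig_id`),
#'   `mapped_fragments`.
#' @param lengths named vector of contig lengths in nt.
#' @param total_cleaned_reads library size (cleaned-up reads).
#' @return tibble `contig_id`, `mapped_fragments`, `length_kb`, `fpkm`,
#'   `relative_share`.
#' @export
fpkm_table <- function(counts, lengths, total_cleaned_reads) {
  if (total_cleaned_reads <= 0) abort("total_cleaned_reads must be > 0")
  idcol <- intersect(c("representative_id", "contig_id"), names(counts))[1]
  if (is.na(idcol)) abort("counts must carry representative_id or contig_id")
  len <- unname(lengths[counts[[idcol]]])
  if (any(is.na(len))) abort("every counted contig needs a length")
  if (any(len <= 0)) abort("zero-length contig")
  fpkm <- counts$mapped_fragments / ((len / 1000) * (total_cleaned_reads / 1e6))
  tibble(
    contig_id = counts[[idcol]],
    mapped_fragments = counts$mapped_fragments,
    length_kb = len / 1000,
    fpkm = fpkm,
    relative_share = if (sum(fpkm) > 0) fpkm / sum(fpkm) else fpkm
  )
}

#' Per-taxon community composition with minor-taxon pooling
#'
#' Taxa holding less than `pool_below` of total abundance are pooled into
#' "other dsRNA" / "other ssRNA" by nucleic-acid class; unclassified contigs
#' are reported as "others". Shares sum to 1.
#'
#' @param abund FPKM tibble from [fpkm_table()].
#' @param taxon_map tibble `contig_id`, `taxon_label`, `nucleic_class`
#'   (one of "dsRNA", "ssRNA", "unclassified").
#' @param pool_below pooling threshold on the per-taxon share.
#' @return tibble `taxon`, `share`, sorted by share.
#' @export
composition_summary <- function(abund, taxon_map, pool_below = 0.02) {
  if (!all(abund$contig_id %in% taxon_map$contig_id)) {
    abort("taxon_map must cover every contig (use 'unclassified' if unknown)")
  }
  ok <- c("dsRNA", "ssRNA", "unclassified")
  if (!all(taxon_map$nucleic_class %in% ok)) {
    abort(sprintf("nucleic_class must be one of %s", paste(ok, collapse = ", ")))
  }
  per_taxon <- abund |>
    left_join(taxon_map, by = "contig_id") |>
    group_by(.data$taxon_label, .data$nucleic_class) |>
    summarise(fpkm = sum(.data$fpkm), .groups = "drop") |>
    mutate(share = .data$fpkm / sum(.data$fpkm))
  per_taxon$taxon <- dplyr::case_when(
    per_taxon$nucleic_class == "unclassified" ~ "others",
    per_taxon$share < pool_below & per_taxon$nucleic_class == "dsRNA" ~ "other dsRNA",
    per_taxon$share < pool_below & per_taxon$nucleic_class == "ssRNA" ~ "other ssRNA",
    .default = per_taxon$taxon_label
  )
  per_taxon |>
    group_by(.data$taxon) |>
    summarise(share = sum(.data$share), .groups = "drop") |>
    arrange(dplyr::desc(.data$share))
}
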