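# Grouping of full-length segments into multipartite genome sets via
# conserved terminal sequences: cognate segments of one genome share their
# 5' and 3' terminal windows, unrelated genomes agree only at the ~25%
# random-nucleotide level, so an identity threshold separates them cleanly.

#' Extract terminal signatures
#'
#' @param contigs sequence tibble (`id`, `seq`).
#' @param W terminal window length (nt).
#' @return tibble `contig_id`, `t5` (first W nt), `t3` (last W nt), `W`.
#' @export
terminal_signature <- function(contigs, W = 30L) {
  validate_seq_tbl(contigs, "contigs")
  len <- nchar(contigs$seq)
  bad <- which(len < 2L * W)
  if (length(bad)) {
    abort(sprintf("contig '%s' shorter than 2 x W = %d", contigs$id[bad[1]], 2L * W))
  }
  tibble(
    contig_id = contigs$id,
    t5 = substr(contigs$seq, 1L, W),
    t3 = substr(contigs$seq, len - W + 1L, len),
    W = as.integer(W)
  )
}

# Best ungapped identity between two equal-length strings over relative
# offsets in [-max_offset, max_offset]; overhang excluded from the denominator.
best_offset_identity <- function(x, y, max_offset = 5L) {
  stopifnot(nchar(y) == nchar(x))
  best_offset_identity_raw(charToRaw(x), charToRaw(y), max_offset)
}

best_offset_identity_raw <- function(rx, ry, max_offset) {
  W <- length(rx)
  max_offset <- min(max_offset, W - 1L)
  best <- 0
  for (o in -max_offset:max_offset) {
    m <- if (o >= 0) {
      mean(rx[(1 + o):W] == ry[1:(W - o)])
    } else {
      mean(rx[1:(W + o)] == ry[(1 - o):W])
    }
    if (m > best) best <- m
  }
  best
}

#' Terminal identity between two signatures
#'
#' Best ungapped percent identity over relative offsets in
#' `[-max_offset, max_offset]`, computed separately for the 5' and 3'
#' terminal windows.
#'
#' @param a,b one-row tibbles from [terminal_signature()] (equal `W`).
#' @param max_offset maximum relative shift (nt).
#' @return tibble with `id5`, `id3` fractions.
#' @export
terminal_identity <- function(a, b, max_offset = 5L) {
  stopifnot(a$W == b$W)
  tibble(
    id5 = best_offset_identity(a$t5, b$t5, max_offset),
    id3 = best_offset_identity(a$t3, b$t3, max_offset)
  )
}

#' Group segments into multipartite genome sets by conserved termini
#'
#' Single-linkage clustering on the relation "5' identity >= min_id AND 3'
#' identity >= min_id"; each connected component becomes a genome set,
#' singletons become one-segment sets. Consensus terminals are per-position
#' majority over members (ties alphabetical). The partition is invariant
#' under permutation of the input.
#'
#' @param signatures tibble from [terminal_signature()].
#' @param min_id identity threshold on both termini.
#' @param max_offset maximum relative shift (nt) in the identity scan.
#' @return object of class `flds_genome_sets`: list with `sets` (tibble
#'   `genome_id`, `member_contigs` list, `n_segments`, `consensus_t5`,
#'   `consensus_t3`), `membership` (tibble `contig_id`, `genome_id`) and
#'   `pairs` (the pairwise identities).
#' @export
group_segments <- function(signatures, min_id = 0.8, max_offset = 5L) {
  stopifnot(nrow(signatures) >= 1L)
  n <- nrow(signatures)
  raw5 <- lapply(signatures$t5, charToRaw)
  raw3 <- lapply(signatures$t3, charToRaw)
  pair_rows <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        id5 <- best_offset_identity_raw(raw5[[i]], raw5[[j]], max_offset)
        id3 <- best_offset_identity_raw(raw3[[i]], raw3[[j]], max_offset)
        pair_rows[[length(pair_rows) + 1]] <- tibble(
          contig_a = signatures$contig_id[i], contig_b = signatures$contig_id[j],
          id5 = id5, id3 = id3, linked = id5 >= min_id && id3 >= min_id
        )
      }
    }
  }
  pairs <- if (length(pair_rows)) list_rbind(pair_rows) else
    tibble(contig_a = character(), contig_b = character(),
           id5 = double(), id3 = double(), linked = logical())

  g <- igraph::graph_from_data_frame(
    pairs[pairs$linked, c("contig_a", "contig_b")],
    directed = FALSE,
    vertices = data.frame(name = signatures$contig_id)
  )
  comp <- igraph::components(g)$membership
  # stable ids: order components by their alphabetically first member
  first_member <- vapply(split(names(comp), comp),
                         function(x) sort(x)[1], character(1))
  ord <- order(first_member)
  remap <- setNames(seq_along(ord), names(first_member)[ord])
  comp_id <- remap[as.character(comp)]

  members <- split(names(comp), comp_id)
  sets <- list_rbind(map(seq_along(members), function(k) {
    mem <- sort(members[[k]])
    idx <- match(mem, signatures$contig_id)
    tibble(
      genome_id = sprintf("GS%02d", k),
      member_contigs = list(mem),
      n_segments = length(mem),
      consensus_t5 = majority_consensus(signatures$t5[idx]),
      consensus_t3 = majority_consensus(signatures$t3[idx])
    )
  }))
  membership <- sets |>
    select("genome_id", "member_contigs") |>
    tidyr::unnest_longer("member_contigs") |>
    rename(contig_id = "member_contigs") |>
    select("contig_id", "genome_id")
  out <- list(sets = sets, membership = membership, pairs = pairs,
              min_id = min_id)
  class(out) <- "flds_genome_sets"
  out
}

# Per-position majority over equal-length strings; ties alphabetical.
majority_consensus <- function(strings) {
  if (length(strings) == 1) return(strings)
  m <- do.call(rbind, strsplit(strings, ""))
  paste(apply(m, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    cands <- names(tb)[tb == tb[1]]
    sort(cands)[1]
  }), collapse = "")
}

#' @export
print.flds_genome_sets <- function(x, ...) {
  cat(sprintf("<flds_genome_sets> %d set(s) over %d segment(s), min_id = %.2f\n",
              nrow(x$sets), nrow(x$membership), x$min_id))
  print(x$sets, ...)
  invisible(x)
}
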