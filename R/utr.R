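# Untranslated-region characterization: six-frame stop-codon maps,
# trinucleotide composition contrasts between noncoding and coding regions,
# and ungapped cross-genome conserved-region links. Stop codons in all six
# frames plus a composition clearly distinct from coding regions are the
# diagnostic signature of a genuinely noncoding long 5'UTR.

#' Six-frame stop-codon map
#'
#' Exhaustive scan of all six translation frames. Positions are 0-based
#' forward coordinates of the codon's first forward-strand base, including
#' for reverse frames (single coordinate system for plotting).
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @return tibble of class `flds_stop_map`: `segment_id`, `strand`, `frame`
#'   (0..2 within strand), `pos`.
#' @export
stop_codon_map <- function(seqs) {
  validate_seq_tbl(seqs)
  rows <- map(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    L <- nchar(s)
    if (L < 3) {
      return(tibble(segment_id = character(), strand = character(),
                    frame = integer(), pos = integer()))
    }
    tri <- substring(s, 1:(L - 2), 3:L)
    fwd <- which(tri %in% STOP_CODONS) - 1L
    rev <- which(tri %in% REV_STOP_TRINUCS) - 1L
    bind_rows(
      tibble(segment_id = seqs$id[i], strand = "+", frame = fwd %% 3L, pos = fwd),
      tibble(segment_id = seqs$id[i], strand = "-",
             frame = (L - rev - 3L) %% 3L, pos = rev)
    )
  })
  res <- list_rbind(rows)
  class(res) <- c("flds_stop_map", class(res))
  res
}

#' Trinucleotide composition profiles of regions
#'
#' Overlapping 3-mer frequencies per region (64 trinucleotides; windows
#' containing N are excluded from numerator and denominator). Counting is
#' done with [Biostrings::trinucleotideFrequency()].
#'
#' @param regions tibble with `id`, `seq` and optionally `kind` (e.g. "utr",
#'   "cds_rdrp", "cds_capsid", "other").
#' @return long tibble of class `flds_trinuc`: `region_id`, `kind`,
#'   `trinuc`, `freq` (64 rows per region, frequencies summing to 1).
#' @export
trinuc_profile <- function(regions) {
  validate_seq_tbl(regions, "regions")
  if (any(nchar(regions$seq) < 3)) {
    abort("every region must be at least 3 nt for a trinucleotide profile")
  }
  kind <- if ("kind" %in% names(regions)) regions$kind else "other"
  counts <- Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(regions$seq)
  )
  freq <- counts / rowSums(counts)
  kind <- rep(kind, length.out = nrow(regions))
  res <- tibble(
    region_id = rep(regions$id, each = 64L),
    kind = rep(kind, each = 64L),
    trinuc = rep(colnames(counts), times = nrow(regions)),
    freq = as.vector(t(freq))
  )
  class(res) <- c("flds_trinuc", class(res))
  res
}

#' Euclidean distances between trinucleotide profiles
#'
#' @param profiles long profile tibble from [trinuc_profile()].
#' @return tibble `region_a`, `region_b`, `kind_a`, `kind_b`, `distance`
#'   (Euclidean over the 64-vectors), one row per unordered pair.
#' @export
composition_distance <- function(profiles) {
  wide <- profiles |>
    select("region_id", "trinuc", "freq") |>
    tidyr::pivot_wider(names_from = "trinuc", values_from = "freq")
  kinds <- profiles |> distinct(.data$region_id, .data$kind)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$region_id
  d <- as.matrix(dist(m, method = "euclidean"))
  n <- nrow(m)
  if (n < 2) abort("need at least two profiles")
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(
    region_a = rownames(m)[idx[, 1]],
    region_b = rownames(m)[idx[, 2]],
    kind_a = kinds$kind[match(rownames(m)[idx[, 1]], kinds$region_id)],
    kind_b = kinds$kind[match(rownames(m)[idx[, 2]], kinds$region_id)],
    distance = d[idx]
  )
}

#' Find conserved regions between sequences by ungapped window comparison
#'
#' For every sequence pair, windows of `window` nt placed every `step` nt in
#' both sequences are compared ungapped; window pairs with identity above
#' `min_id` lying on the same diagonal are merged into maximal links and the
#' link identity is recomputed over the merged span.
#'
#' @param seqs sequence tibble (`id`, `seq`), at least two rows.
#' @param window window length (nt).
#' @param step window placement step (nt).
#' @param min_id identity threshold (fraction); links require identity
#'   strictly above it.
#' @return tibble `seq_a`, `seq_b`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `identity`.
#' @export
find_conserved_links <- function(seqs, window = 100L, step = 10L,
                                 min_id = 0.68) {
  validate_seq_tbl(seqs)
  if (nrow(seqs) < 2) abort("need at least two sequences")
  if (window > min(nchar(seqs$seq))) {
    abort("window longer than the shortest sequence")
  }
  out <- list()
  for (i in 1:(nrow(seqs) - 1)) {
    for (j in (i + 1):nrow(seqs)) {
      out[[length(out) + 1]] <- pair_links(
        seqs$id[i], seqs$seq[i], seqs$id[j], seqs$seq[j],
        window, step, min_id
      )
    }
  }
  res <- list_rbind(out)
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(seq_a = character(), seq_b = character(),
                  a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(),
                  identity = double()))
  }
  arrange(res, .data$seq_a, .data$seq_b, .data$a_start)
}

# Diagonal-sweep window comparison for one pair.
pair_links <- function(ida, sa, idb, sb, window, step, min_id) {
  ra <- charToRaw(sa); rb <- charToRaw(sb)
  la <- length(ra); lb <- length(rb)
  qs <- seq(0L, la - window, by = step)   # query window starts (0-based)
  ps <- seq(0L, lb - window, by = step)
  hits <- list()
  for (d in seq(min(qs) - max(ps), max(qs) - min(ps), by = step)) {
    # overlap of a-coords for this diagonal (a = b + d)
    lo <- max(0L, d); hi <- min(la, lb + d)
    if (hi - lo < window) next
    eq <- ra[(lo + 1):hi] == rb[(lo - d + 1):(hi - d)]
    cs <- c(0L, cumsum(eq))
    q_here <- qs[qs >= lo & qs + window <= hi & (qs - d) %in% ps]
    if (!length(q_here)) next
    off <- q_here - lo
    idw <- (cs[off + window + 1L] - cs[off + 1L]) / window
    pass <- idw > min_id
    if (!any(pass)) next
    qp <- q_here[pass]
    # merge consecutive passing windows on this diagonal
    grp <- cumsum(c(TRUE, diff(qp) > step))
    for (g in split(qp, grp)) {
      a0 <- g[1]; a1 <- g[length(g)] + window
      o0 <- a0 - lo; o1 <- a1 - lo
      ident <- (cs[o1 + 1L] - cs[o0 + 1L]) / (a1 - a0)
      hits[[length(hits) + 1]] <- tibble(
        seq_a = ida, seq_b = idb,
        a_start = a0, a_end = a1,
        b_start = a0 - d, b_end = a1 - d,
        identity = ident
      )
    }
  }
  if (length(hits)) list_rbind(hits) else NULL
}
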