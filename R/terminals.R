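# Terminal-sequence determination from adaptor-bearing read alignments.
# Criterion (i): adaptor-carrying reads align at both termini of a segment;
# criterion (ii): their frequency at the termini clearly exceeds the internal
# fragmentation background in the central region. Junctions are
# strand-resolved and pooled: an adaptor at the minus-strand 3' end evidences
# the plus-strand 5' terminus (dsRNA symmetry), which the clipped-prefix /
# clipped-suffix rules below encode.

#' Accumulate adaptor-junction profiles per contig
#'
#' A read whose soft-clipped suffix begins with the adaptor (at most
#' `max_mismatch` mismatches over the compared overlap) contributes one
#' 3'-junction event at `ref_end - 1`; a read whose soft-clipped prefix ends
#' with the reverse-complemented adaptor contributes one 5'-junction event at
#' `ref_start`. Coverage is accumulated from all alignments.
#'
#' @param alignments alignment tibble (see [read_sam()] / [truth_alignments()]).
#' @param contigs sequence tibble (`id`, `seq`) the alignments refer to.
#' @param adaptor adaptor sequence (length >= 10).
#' @param max_mismatch mismatches tolerated in the adaptor comparison.
#' @param min_overlap minimum compared overlap between clip and adaptor.
#' @return tibble of class `flds_terminal_profile`: one row per contig with
#'   `contig_id`, `length` and list columns `j5`, `j3`, `coverage`
#'   (integer arrays of length `length`, index i = position i-1).
#' @export
detect_adaptor_junctions <- function(alignments, contigs, adaptor,
                                     max_mismatch = 1L, min_overlap = 10L) {
  if (nchar(adaptor) < 10L) {
    abort("adaptor shorter than 10 nt: junction matching would be unreliable")
  }
  validate_seq_tbl(contigs, "contigs")
  if (!all(alignments$ref_id %in% contigs$id)) {
    abort("alignment references a contig absent from `contigs`")
  }
  rc <- revcomp(adaptor)
  alen <- nchar(adaptor)

  # adaptor at clipped suffix -> 3' junction at ref_end - 1
  csfx <- alignments$clipped_suffix
  ov3 <- pmin(nchar(csfx), alen)
  cand3 <- which(ov3 >= min_overlap)
  hit3 <- cand3[vapply(cand3, function(k) {
    count_mismatches(substr(csfx[k], 1L, ov3[k]),
                     substr(adaptor, 1L, ov3[k])) <= max_mismatch
  }, logical(1))]

  # reverse-complemented adaptor at clipped prefix tail -> 5' junction at ref_start
  cpfx <- alignments$clipped_prefix
  np <- nchar(cpfx)
  ov5 <- pmin(np, alen)
  cand5 <- which(ov5 >= min_overlap)
  hit5 <- cand5[vapply(cand5, function(k) {
    count_mismatches(substr(cpfx[k], np[k] - ov5[k] + 1L, np[k]),
                     substr(rc, alen - ov5[k] + 1L, alen)) <= max_mismatch
  }, logical(1))]

  out <- map(seq_len(nrow(contigs)), function(i) {
    cid <- contigs$id[i]
    L <- nchar(contigs$seq[i])
    rows <- which(alignments$ref_id == cid)
    j5 <- integer(L); j3 <- integer(L); cov <- integer(L)
    h5 <- intersect(rows, hit5)
    if (length(h5)) {
      t5 <- tabulate(alignments$ref_start[h5] + 1L, nbins = L)
      j5 <- j5 + t5
    }
    h3 <- intersect(rows, hit3)
    if (length(h3)) {
      t3 <- tabulate(alignments$ref_end[h3], nbins = L)
      j3 <- j3 + t3
    }
    if (length(rows)) {
      s <- tabulate(alignments$ref_start[rows] + 1L, nbins = L)
      e <- tabulate(alignments$ref_end[rows] + 1L, nbins = L + 1L)
      cov <- as.integer(cumsum(s - e[seq_len(L)]))
    }
    tibble(contig_id = cid, length = L, j5 = list(j5), j3 = list(j3),
           coverage = list(cov))
  })
  res <- list_rbind(out)
  class(res) <- c("flds_terminal_profile", class(res))
  res
}

#' Call terminal completeness from a junction profile
#'
#' The terminal junction count is summed over the first (`j5`) / last (`j3`)
#' `window` positions. The background rate is the junction-event count in the
#' central half of the contig per window-sized bin; when the central region
#' is event-free the rate floor is the equivalent of a single event spread
#' over the central half. A terminus is `complete` when its count reaches
#' `min_events` and exceeds `enrich` times the background; `ambiguous` when
#' the count is reached but the enrichment is not; `incomplete` otherwise.
#' The peak is the argmax position within the terminal window, ties broken
#' toward the contig extremity.
#'
#' @param profile an `flds_terminal_profile`.
#' @param window terminal window (nt).
#' @param min_events minimum junction events at a terminus.
#' @param enrich required enrichment over the central background.
#' @return tibble of class `flds_completeness`: `contig_id`, `status5`,
#'   `status3`, `peak5_pos`, `peak3_pos` (0-based), `enrichment5`,
#'   `enrichment3`, `n5_events`, `n3_events`, `background`.
#' @export
call_completeness <- function(profile, window = 50L, min_events = 3L,
                              enrich = 5.0) {
  stopifnot(inherits(profile, "flds_terminal_profile") ||
              all(c("contig_id", "j5", "j3", "coverage") %in% names(profile)))
  rows <- map(seq_len(nrow(profile)), function(i) {
    L <- profile$length[i]
    if (L <= 4L * window) {
      abort(sprintf("contig '%s' shorter than 4 x window; cannot separate termini from background",
                    profile$contig_id[i]))
    }
    j5 <- profile$j5[[i]]; j3 <- profile$j3[[i]]
    if (all(profile$coverage[[i]] == 0L)) {
      abort(sprintf("no alignments cover contig '%s'", profile$contig_id[i]))
    }
    t5 <- sum(j5[seq_len(window)])
    t3 <- sum(j3[(L - window + 1L):L])
    mid <- (floor(L / 4) + 1L):floor(3 * L / 4)
    mid_events <- sum(j5[mid]) + sum(j3[mid])
    n_bins <- length(mid) / window
    bg <- mid_events / n_bins
    floor_bg <- window / length(mid)           # one event spread over the middle
    denom <- max(bg, floor_bg)
    enr5 <- min(t5 / denom, 1e6)
    enr3 <- min(t3 / denom, 1e6)
    status <- function(cnt, enr) {
      if (cnt >= min_events && enr >= enrich) "complete"
      else if (cnt >= min_events) "ambiguous"
      else "incomplete"
    }
    peak5 <- if (t5 > 0) which.max(j5[seq_len(window)]) - 1L else NA_integer_
    p3win <- j3[(L - window + 1L):L]
    peak3 <- if (t3 > 0) {
      L - window + (window + 1L - which.max(rev(p3win))) - 1L
    } else NA_integer_
    tibble(
      contig_id = profile$contig_id[i],
      status5 = status(t5, enr5), status3 = status(t3, enr3),
      peak5_pos = peak5, peak3_pos = peak3,
      enrichment5 = enr5, enrichment3 = enr3,
      n5_events = t5, n3_events = t3,
      background = bg
    )
  })
  res <- list_rbind(rows)
  class(res) <- c("flds_completeness", class(res))
  res
}

#' Trim contigs to their called termini
#'
#' Emits the full-length segment between the called 5' and 3' junction peaks.
#' Refuses contigs whose termini are not both complete.
#'
#' @param contigs sequence tibble (`id`, `seq`).
#' @param calls completeness tibble from [call_completeness()].
#' @return sequence tibble restricted to `[peak5_pos, peak3_pos + 1)`.
#' @export
trim_to_termini <- function(contigs, calls) {
  validate_seq_tbl(contigs, "contigs")
  calls <- calls[match(contigs$id, calls$contig_id), ]
  if (any(is.na(calls$contig_id))) {
    abort("every contig needs a completeness call")
  }
  bad <- which(calls$status5 != "complete" | calls$status3 != "complete")
  if (length(bad)) {
    abort(sprintf("contig '%s' does not have two complete termini; refusing to trim",
                  contigs$id[bad[1]]))
  }
  contigs$seq <- substr(contigs$seq, calls$peak5_pos + 1L, calls$peak3_pos + 1L)
  if ("length" %in% names(contigs)) contigs$length <- nchar(contigs$seq)
  contigs
}
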