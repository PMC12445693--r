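# ORF calling with bacterial-type ribosome-binding-site (Shine-Dalgarno)
# detection and a Kyte-Doolittle hydropathy scan standing in for
# transmembrane-domain prediction. The scan is a hydropathy surrogate and is
# flagged as such in all outputs (`tm_method = "hydropathy_surrogate"`); it is
# not equivalent to an HMM-based TM predictor.

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Core six-frame stop-to-stop scanner on a single sequence string, working
# on integer trinucleotide codes (A,C,G,T -> 0..3; code = 16 b1 + 4 b2 + b3;
# windows containing N never match). Both strands come from one forward
# pass: the reverse-strand codon occupying forward positions [p, p+3) is the
# reverse complement of the forward trinucleotide at p.
# Returns a data frame with 0-based half-open forward coordinates.
scan_orfs_string <- function(seq, min_aa = 60L, starts = c("ATG", "GTG", "TTG"),
                             strand = "both") {
  L <- nchar(seq)
  empty <- list(start = integer(), end = integer(), strand = character())
  if (L < 3L) return(empty)
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  b <- lut[utf8ToInt(seq)]
  codes <- 16L * b[1:(L - 2)] + 4L * b[2:(L - 1)] + b[3:L]
  code_of <- function(x) {
    v <- lut[utf8ToInt(x)]
    16L * v[1] + 4L * v[2] + v[3]
  }
  rc_code <- function(cd) {
    # reverse complement of a trinucleotide code
    b1 <- cd %/% 16L; b2 <- (cd %/% 4L) %% 4L; b3 <- cd %% 4L
    16L * (3L - b3) + 4L * (3L - b2) + (3L - b1)
  }
  stop_codes <- vapply(STOP_CODONS, code_of, integer(1))
  start_codes <- vapply(starts, code_of, integer(1))
  mask <- function(cds) {
    m <- logical(64L)
    m[cds + 1L] <- TRUE
    m
  }
  codes1 <- codes + 1L
  codes1[is.na(codes1)] <- 65L # N windows never match
  lookup <- function(m) which(c(m, FALSE)[codes1])

  s_out <- integer(0); e_out <- integer(0); str_out <- character(0)
  if (strand %in% c("both", "+")) {
    hits <- orf_walk(lookup(mask(stop_codes)) - 1L,
                     lookup(mask(start_codes)) - 1L, min_aa)
    s_out <- hits$s; e_out <- hits$e
    str_out <- rep("+", length(hits$s))
  }
  if (strand %in% c("both", "-")) {
    # reverse coordinates: r = L - p - 3 for a codon at forward p
    rstops <- sort(L - (lookup(mask(rc_code(stop_codes))) - 1L) - 3L)
    rstarts <- sort(L - (lookup(mask(rc_code(start_codes))) - 1L) - 3L)
    hits <- orf_walk(rstops, rstarts, min_aa)
    s_out <- c(s_out, L - hits$e); e_out <- c(e_out, L - hits$s)
    str_out <- c(str_out, rep("-", length(hits$s)))
  }
  ord <- order(s_out, e_out)
  list(start = s_out[ord], end = e_out[ord], strand = str_out[ord])
}

# Stop-to-stop walk in one strand's own coordinates: for each stop, the most
# upstream start after the previous in-frame stop; keep ORFs of min_aa.
orf_walk <- function(stop_pos, start_pos, min_aa) {
  res <- list()
  for (f in 0:2) {
    st <- stop_pos[stop_pos %% 3L == f]
    ca <- start_pos[start_pos %% 3L == f]
    if (length(st) == 0 || length(ca) == 0) next
    lo <- c(-3L, head(st, -1L)) + 3L
    idx <- findInterval(lo - 1L, ca) + 1L
    ok <- idx <= length(ca)
    s0 <- rep(NA_integer_, length(st))
    s0[ok] <- ca[idx[ok]]
    keep <- !is.na(s0) & s0 < st & (st - s0) >= 3L * min_aa
    if (any(keep)) {
      res[[length(res) + 1L]] <- list(s = s0[keep], e = st[keep] + 3L)
    }
  }
  list(s = unlist(lapply(res, `[[`, "s")), e = unlist(lapply(res, `[[`, "e")))
}

#' Find ORFs on both strands of each segment
#'
#' Deterministic stop-to-stop scan: in every frame, maximal open reading
#' frames are reported from the most upstream permitted start codon;
#' overlapping same-frame calls collapse to the longest by construction.
#' Coordinates are 0-based half-open on the forward strand; `end` includes
#' the stop codon. Proteins are translated with genetic code 11.
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param min_aa minimum protein length (aa, excluding the stop).
#' @param starts permitted start codons.
#' @param strand "both", "+" or "-".
#' @return tibble `segment_id`, `orf_id`, `start`, `end`, `strand`, `protein`.
#' @export
find_orfs <- function(seqs, min_aa = 60L, starts = c("ATG", "GTG", "TTG"),
                      strand = "both") {
  validate_seq_tbl(seqs)
  rows <- map(seq_len(nrow(seqs)), function(i) {
    hits <- scan_orfs_string(seqs$seq[i], min_aa = min_aa, starts = starts,
                             strand = strand)
    if (length(hits$start) == 0) return(NULL)
    tibble(
      segment_id = seqs$id[i],
      start = as.integer(hits$start),
      end = as.integer(hits$end),
      strand = hits$strand,
      protein = vapply(seq_along(hits$start), function(k) {
        translate_orf(seqs$seq[i], hits$start[k], hits$end[k], hits$strand[k])
      }, character(1))
    )
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(segment_id = character(), orf_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  protein = character()))
  }
  out |>
    group_by(.data$segment_id) |>
    mutate(orf_id = sprintf("%s.orf%02d", .data$segment_id, row_number())) |>
    ungroup() |>
    select("segment_id", "orf_id", "start", "end", "strand", "protein")
}

#' Detect Shine-Dalgarno motifs upstream of ORF starts
#'
#' Scans the window `[start - (max_spacer + motif length), start - min_spacer)`
#' on the coding strand for the longest contiguous exact match to any
#' substring of the SD consensus of length `>= min_match`. The best hit is the
#' longest match, ties broken toward the optimal 8-nt spacer. The spacer is
#' the distance (nt) between the motif 3' end and the start codon.
#'
#' @param seqs sequence tibble the ORFs were called on.
#' @param orfs ORF tibble from [find_orfs()].
#' @param motif SD consensus.
#' @param min_match minimum contiguous match length.
#' @param spacer_range allowed spacer range (nt), inclusive.
#' @return `orfs` with `sd_motif` (NA when absent) and `sd_spacer` columns.
#' @export
detect_sd <- function(seqs, orfs, motif = "AGGAGG", min_match = 4L,
                      spacer_range = c(3L, 15L)) {
  validate_seq_tbl(seqs)
  sp_min <- spacer_range[1]; sp_max <- spacer_range[2]
  mlen <- nchar(motif)
  res <- map(seq_len(nrow(orfs)), function(i) {
    seq <- seqs$seq[match(orfs$segment_id[i], seqs$id)]
    L <- nchar(seq)
    if (orfs$strand[i] == "+") {
      cseq <- seq
      cstart <- orfs$start[i]
    } else {
      cseq <- revcomp(seq)
      cstart <- L - orfs$end[i]
    }
    win_lo <- max(0L, cstart - (sp_max + mlen))
    win_hi <- cstart - sp_min
    if (win_hi <= win_lo) return(tibble(sd_motif = NA_character_, sd_spacer = NA_integer_))
    win <- substr(cseq, win_lo + 1L, win_hi)
    best <- NULL
    for (l in seq(mlen, min_match)) {
      for (off in 0:(mlen - l)) {
        sub <- substr(motif, off + 1L, off + l)
        hits <- gregexpr(sub, win, fixed = TRUE)[[1]]
        if (hits[1] == -1) next
        for (q in hits) {
          end_coord <- win_lo + (q - 1L) + l      # coding coord just past motif
          spacer <- cstart - end_coord
          if (spacer < sp_min || spacer > sp_max) next
          cand <- list(motif = sub, spacer = spacer, len = l)
          if (is.null(best) ||
              cand$len > best$len ||
              (cand$len == best$len && abs(cand$spacer - 8L) < abs(best$spacer - 8L)) ||
              (cand$len == best$len && abs(cand$spacer - 8L) == abs(best$spacer - 8L) &&
               cand$spacer < best$spacer)) {
            best <- cand
          }
        }
      }
      if (!is.null(best)) break  # longest length class found
    }
    if (is.null(best)) {
      tibble(sd_motif = NA_character_, sd_spacer = NA_integer_)
    } else {
      tibble(sd_motif = best$motif, sd_spacer = as.integer(best$spacer))
    }
  })
  bind_cols(orfs, list_rbind(res))
}

#' Kyte-Doolittle hydropathy scan for putative transmembrane segments
#'
#' Mean hydropathy over sliding windows; maximal runs of windows at or above
#' the threshold are reported as TM segments (0-based half-open aa
#' coordinates). A hydropathy surrogate, not an HMM TM predictor.
#'
#' @param protein amino-acid string.
#' @param window window length (aa).
#' @param threshold mean-hydropathy threshold.
#' @return tibble `aa_start`, `aa_end` (possibly empty).
#' @export
hydropathy_tm_scan <- function(protein, window = 19L, threshold = 1.6) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < window) return(tibble(aa_start = integer(), aa_end = integer()))
  h <- unname(KD_SCALE[aa])
  h[is.na(h)] <- 0 # unknown residues neutral
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- means >= threshold
  if (!any(hit)) return(tibble(aa_start = integer(), aa_end = integer()))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(
    aa_start = as.integer(starts[keep] - 1L),
    aa_end = as.integer(ends[keep] - 1L + window)
  )
}

#' Add TM-scan flags to an ORF table
#'
#' @param orfs ORF tibble with a `protein` column.
#' @inheritParams hydropathy_tm_scan
#' @return `orfs` with list column `tm_segments` and a `tm_method` column.
#' @export
tm_scan <- function(orfs, window = 19L, threshold = 1.6) {
  orfs$tm_segments <- map(orfs$protein, hydropathy_tm_scan,
                          window = window, threshold = threshold)
  orfs$tm_method <- "hydropathy_surrogate"
  orfs
}

#' Annotate segments: ORFs + SD motifs + TM flags
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param min_aa minimum protein length (aa).
#' @param sd_motif SD consensus for [detect_sd()].
#' @param ... further arguments to [find_orfs()].
#' @return annotated ORF tibble.
#' @export
annotate_segments <- function(seqs, min_aa = 60L, sd_motif = "AGGAGG", ...) {
  orfs <- find_orfs(seqs, min_aa = min_aa, ...)
  orfs <- detect_sd(seqs, orfs, motif = sd_motif)
  tm_scan(orfs)
}

#' ORF protein-length summary for deposited genome segments
#'
#' Annotates a FASTA of deposited segments and reports the protein-length
#' extremes and the per-segment longest products, for comparison against
#' published values. The deposited sequences themselves are not bundled with
#' the package; supply a FASTA downloaded from the public archive.
#'
#' @param fasta_path path to the deposited segment FASTA.
#' @param min_aa minimum protein length for the scan.
#' @return list with `orfs` (annotated tibble), `min_aa_len`, `max_aa_len`.
#' @export
check_deposited_orf_lengths <- function(fasta_path, min_aa = 60L) {
  seqs <- read_fasta(fasta_path)
  orfs <- find_orfs(seqs, min_aa = min_aa)
  plen <- nchar(orfs$protein)
  list(
    orfs = orfs,
    min_aa_len = min(plen),
    max_aa_len = max(plen)
  )
}
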