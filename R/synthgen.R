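# Synthetic multipartite dsRNA virus genomes and FLDS-style reads with known
# ground truth. The generator emulates the statistical structure the pipeline
# assumes: bisegmented genomes whose two segments share conserved 5'/3'
# terminal sequences; dsRNA fragmented to ~1.5 kb with an adaptor ligated to
# every fragment 3' end (on both strands), so that true genome termini are
# marked by adaptor-bearing reads at elevated frequency; coding regions built
# by biased codon sampling; long noncoding 5'UTRs built by an order-2
# trinucleotide-biased Markov chain with composition distinct from coding.

STOP_CODONS <- c("TAA", "TAG", "TGA")
REV_STOP_TRINUCS <- c("TTA", "CTA", "TCA") # forward-strand images of reverse stops

#' Simulation configuration for the FLDS generator
#'
#' Defaults are the study conditions the rest of the package is validated
#' against: 10 bisegmented genomes, ~1.5 kb fragments, 300 nt reads, 50x
#' coverage, 0.2% substitution error, 1.5 kb biased 5'UTRs on a fraction of
#' RNA1 segments.
#'
#' @param n_genomes number of bisegmented genomes.
#' @param segment_len_range numeric length-2, min/max segment length (nt).
#' @param fragment_len_mean,fragment_len_sd,fragment_len_min physical
#'   fragmentation length model (nt): Normal(mean, sd) truncated below at
#'   `fragment_len_min` and above at the segment length.
#' @param read_len read length (nt).
#' @param coverage total fold coverage (both strands pooled).
#' @param adaptor adaptor sequence ligated to fragment 3' ends.
#' @param terminal_len length (nt) of the conserved terminal sequences shared
#'   by the two segments of a genome.
#' @param utr5_len length (nt) of the long noncoding 5'UTR on RNA1.
#' @param utr_frac fraction of genomes whose RNA1 carries the long 5'UTR.
#' @param utr_trinuc_bias named numeric(64) over trinucleotides, summing to 1;
#'   composition target of noncoding regions.
#' @param error_rate per-base substitution probability on reads.
#' @param n_orfs_rna2_range integer length-2, ORFs per RNA2 segment.
#' @param sd_frac fraction of ORFs preceded by a Shine-Dalgarno motif.
#' @param seed integer seed; every downstream draw derives from it.
#' @return a validated config list of class `flds_sim_config`.
#' @export
sim_config <- function(n_genomes = 10L,
                       segment_len_range = c(2500L, 6500L),
                       fragment_len_mean = 1500,
                       fragment_len_sd = 300,
                       fragment_len_min = 200,
                       read_len = 300L,
                       coverage = 50,
                       adaptor = "GTTCAGAGTTCTACAGTCCG",
                       terminal_len = 30L,
                       utr5_len = 1500L,
                       utr_frac = 0.6,
                       utr_trinuc_bias = default_utr_bias(),
                       error_rate = 0.002,
                       n_orfs_rna2_range = c(1L, 4L),
                       sd_frac = 0.9,
                       seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    segment_len_range = as.integer(segment_len_range),
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd,
    fragment_len_min = fragment_len_min,
    read_len = as.integer(read_len),
    coverage = coverage,
    adaptor = toupper(adaptor),
    terminal_len = as.integer(terminal_len),
    utr5_len = as.integer(utr5_len),
    utr_frac = utr_frac,
    utr_trinuc_bias = utr_trinuc_bias,
    error_rate = error_rate,
    n_orfs_rna2_range = as.integer(n_orfs_rna2_range),
    sd_frac = sd_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "flds_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genomes >= 1L, length(cfg$segment_len_range) == 2L)
  if (cfg$segment_len_range[1] > cfg$segment_len_range[2]) {
    abort("segment_len_range must be (min, max)")
  }
  for (p in c("utr_frac", "sd_frac", "error_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("%s must be in [0,1]", p))
  }
  if (!nzchar(cfg$adaptor)) abort("adaptor must be non-empty")
  if (grepl("[^ACGT]", cfg$adaptor)) abort("adaptor must be A/C/G/T only")
  b <- cfg$utr_trinuc_bias
  if (length(b) != 64 || is.null(names(b))) {
    abort("utr_trinuc_bias must be a named numeric(64) over trinucleotides")
  }
  if (any(b < 0) || abs(sum(b) - 1) > 1e-8) {
    abort("utr_trinuc_bias must be nonnegative and sum to 1")
  }
  if (cfg$coverage <= 0) abort("coverage must be > 0")
  invisible(cfg)
}

all_trinucs <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

#' Default noncoding trinucleotide bias
#'
#' AT-rich with boosted stop-codon trinucleotides (both strands), so that
#' simulated UTRs are stop-dense in all six frames and compositionally
#' distinct from codon-sampled coding sequence.
#'
#' @return named numeric(64) summing to 1.
#' @export
default_utr_bias <- function() {
  tn <- sort(all_trinucs())
  at <- vapply(strsplit(tn, ""), function(x) sum(x %in% c("A", "T")), integer(1))
  w <- 2.2^at
  boost <- tn %in% c(STOP_CODONS, REV_STOP_TRINUCS)
  w[boost] <- w[boost] * 1.8
  setNames(w / sum(w), tn)
}

# Fixed nonuniform codon usage over the 61 sense codons. TTA/CTA/TCA are
# favored so reverse-strand reading frames of coding regions are stop-dense,
# keeping spurious reverse ORFs rare before the repair pass.
sense_codon_usage <- function() {
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  gc <- vapply(strsplit(sense, ""), function(x) sum(x %in% c("G", "C")), integer(1))
  w <- 1.25^gc
  w[sense == "TTA"] <- 6
  w[sense == "CTA"] <- 3.5
  w[sense == "TCA"] <- 4
  setNames(w / sum(w), sense)
}

# Order-2 Markov chain sampler targeting a trinucleotide composition.
make_utr_sampler <- function(bias) {
  tn <- names(bias)
  ctx <- substr(tn, 1, 2)
  nxt <- substr(tn, 3, 3)
  contexts <- unique(ctx)
  trans <- lapply(setNames(contexts, contexts), function(cc) {
    w <- bias[ctx == cc]
    p <- setNames(as.numeric(w), nxt[ctx == cc])
    p[BASES] / sum(p)
  })
  start_p <- bias / sum(bias)
  function(n) {
    if (n < 3) {
      return(paste(sample(BASES, n, replace = TRUE), collapse = ""))
    }
    out <- character(n)
    first <- sample(tn, 1, prob = start_p)
    out[1:3] <- strsplit(first, "")[[1]]
    for (i in 4:n) {
      cc <- paste0(out[i - 2], out[i - 1])
      out[i] <- sample(BASES, 1, prob = trans[[cc]])
    }
    paste(out, collapse = "")
  }
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# 20-nt region immediately upstream of an ORF start: [pad6][motif or pad][spacer8],
# spacer ends with an in-frame TAA so the ORF scanner's most-upstream start is
# the true start. When has_sd is FALSE the region is rejection-sampled to be
# free of >=4-nt matches to AGGAGG.
sd_region <- function(has_sd) {
  if (has_sd) {
    paste0(random_dna(6), "AGGAGG", random_dna(5), "TAA")
  } else {
    repeat {
      r <- paste0(random_dna(17), "TAA")
      if (!grepl("AGGA|GGAG|GAGG", r)) return(r)
    }
  }
}

SD_REGION_LEN <- 20L

sample_coding <- function(plen, usage) {
  start <- sample(c("ATG", "GTG", "TTG"), 1, prob = c(0.8, 0.15, 0.05))
  body <- sample(names(usage), plen - 1L, replace = TRUE, prob = usage)
  stop <- sample(STOP_CODONS, 1)
  paste0(start, paste(body, collapse = ""), stop)
}

#' Simulate bisegmented dsRNA virus genomes with known annotation truth
#'
#' Each genome has two segments (RNA1 with one long RdRP-like ORF, RNA2 with
#' 1-4 ORFs) sharing per-genome 5' and 3' terminal sequences. Terminal
#' sequences of different genomes are drawn independently. A configurable
#' fraction of RNA1 segments carries a long noncoding 5'UTR sampled from the
#' configured trinucleotide bias. Segments are post-processed so that the
#' ORFs recoverable by [find_orfs()] at its defaults are exactly the truth
#' set. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return object of class `flds_genomes`: list with tibbles `segments`
#'   (genome_id, segment_id, role, seq, length, terminal5, terminal3,
#'   utr5_len), `orfs` (segment_id, start, end, strand, role, has_sd,
#'   protein) and the `config`.
#' @export
simulate_genomes <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, simulate_genomes_impl(cfg))
}

simulate_genomes_impl <- function(cfg) {
  usage <- sense_codon_usage()
  utr_draw <- make_utr_sampler(cfg$utr_trinuc_bias)
  tl <- cfg$terminal_len
  n_long <- round(cfg$utr_frac * cfg$n_genomes)
  seg_rows <- list()
  orf_rows <- list()

  for (g in seq_len(cfg$n_genomes)) {
    gid <- sprintf("G%02d", g)
    term5 <- random_dna(tl)
    term3 <- random_dna(tl)
    long_utr <- g <= n_long

    # --- RNA1: [term5][utr5][sd region][rdrp ORF][ncr3][term3]
    utr1_len <- if (long_utr) cfg$utr5_len else 60L
    ncr3_len <- 50L
    target <- round(runif(1, cfg$segment_len_range[1], cfg$segment_len_range[2]))
    fixed <- 2L * tl + utr1_len + SD_REGION_LEN + ncr3_len
    orf_nt <- 3L * ((target - fixed) %/% 3L)
    plen <- orf_nt / 3L - 1L
    if (plen < 150L) {
      abort("segment_len_range too small to host requested ORFs (RNA1 RdRP)")
    }
    has_sd1 <- runif(1) < cfg$sd_frac
    parts <- c(term5, utr_draw(utr1_len), sd_region(has_sd1),
               sample_coding(plen, usage), utr_draw(ncr3_len), term3)
    seq1 <- paste(parts, collapse = "")
    start1 <- tl + utr1_len + SD_REGION_LEN
    sid1 <- paste0(gid, "_RNA1")
    orf1 <- tibble(
      segment_id = sid1, start = start1, end = start1 + orf_nt,
      strand = "+", role = "rdrp", has_sd = has_sd1
    )
    res1 <- finalize_segment(seq1, orf1, tl)
    seg_rows[[length(seg_rows) + 1]] <- tibble(
      genome_id = gid, segment_id = sid1, role = "RNA1", seq = res1$seq,
      length = nchar(res1$seq), terminal5 = term5, terminal3 = term3,
      utr5_len = utr1_len
    )
    orf_rows[[length(orf_rows) + 1]] <- res1$orfs |> mutate(genome_id = gid)

    # --- RNA2: [term5][utr][sd+orf] x k with spacers [ncr3][term3]
    n_orfs <- sample(seq(cfg$n_orfs_rna2_range[1], cfg$n_orfs_rna2_range[2]), 1)
    utr2_len <- 40L
    gap_len <- 15L
    target2 <- round(runif(1, cfg$segment_len_range[1], cfg$segment_len_range[2]))
    fixed2 <- 2L * tl + utr2_len + n_orfs * SD_REGION_LEN +
      (n_orfs - 1L) * gap_len + ncr3_len
    budget <- target2 - fixed2
    min_plen <- 80L
    base_nt <- n_orfs * 3L * (min_plen + 1L)
    while (budget < base_nt && n_orfs > 1L) {
      n_orfs <- n_orfs - 1L
      fixed2 <- 2L * tl + utr2_len + n_orfs * SD_REGION_LEN +
        (n_orfs - 1L) * gap_len + ncr3_len
      budget <- target2 - fixed2
      base_nt <- n_orfs * 3L * (min_plen + 1L)
    }
    if (budget < base_nt) {
      abort("segment_len_range too small to host requested ORFs (RNA2)")
    }
    extra <- budget - base_nt
    prop <- runif(n_orfs)
    extra_i <- 3L * (floor(extra * prop / sum(prop)) %/% 3L)
    plens <- as.integer(min_plen + extra_i / 3L)
    has_sd2 <- runif(n_orfs) < cfg$sd_frac
    sid2 <- paste0(gid, "_RNA2")
    parts <- c(term5, utr_draw(utr2_len))
    pos <- tl + utr2_len
    orfs2 <- list()
    for (k in seq_len(n_orfs)) {
      parts <- c(parts, sd_region(has_sd2[k]))
      pos <- pos + SD_REGION_LEN
      orf_nt_k <- 3L * (plens[k] + 1L)
      parts <- c(parts, sample_coding(plens[k], usage))
      orfs2[[k]] <- tibble(
        segment_id = sid2, start = pos, end = pos + orf_nt_k,
        strand = "+", role = "other", has_sd = has_sd2[k]
      )
      pos <- pos + orf_nt_k
      if (k < n_orfs) {
        parts <- c(parts, utr_draw(gap_len))
        pos <- pos + gap_len
      }
    }
    parts <- c(parts, utr_draw(ncr3_len), term3)
    seq2 <- paste(parts, collapse = "")
    res2 <- finalize_segment(seq2, list_rbind(orfs2), tl)
    seg_rows[[length(seg_rows) + 1]] <- tibble(
      genome_id = gid, segment_id = sid2, role = "RNA2", seq = res2$seq,
      length = nchar(res2$seq), terminal5 = term5, terminal3 = term3,
      utr5_len = utr2_len
    )
    orf_rows[[length(orf_rows) + 1]] <- res2$orfs |> mutate(genome_id = gid)
  }

  out <- list(
    segments = list_rbind(seg_rows),
    orfs = list_rbind(orf_rows) |>
      select("genome_id", "segment_id", "start", "end", "strand", "role",
             "has_sd", "protein"),
    config = cfg
  )
  class(out) <- "flds_genomes"
  out
}

# Repair pass: mutate codons inside spurious ORFs (either strand) until the
# ORF scanner at its defaults recovers exactly the truth set, then scrub
# accidental SD-like matches upstream of has_sd = FALSE ORFs and recompute
# protein truth from the final sequence.
finalize_segment <- function(seq, orfs, terminal_len, min_aa = 60L) {
  L <- nchar(seq)
  protected <- rep(FALSE, L)
  protected[c(seq_len(terminal_len), (L - terminal_len + 1):L)] <- TRUE
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    protected[(s - SD_REGION_LEN + 1):(s + 3)] <- TRUE   # SD window + start codon
    protected[(e - 2):e] <- TRUE                          # stop codon
  }

  key_t <- paste(orfs$start, orfs$end, orfs$strand)
  for (iter in 1:50) {
    found <- scan_orfs_string(seq, min_aa = min_aa)
    key_f <- paste(found$start, found$end, found$strand)
    if (!all(key_t %in% key_f)) {
      abort("synthgen internal error: a truth ORF is not recoverable")
    }
    sp <- which(!(key_f %in% key_t))
    if (length(sp) == 0) break
    for (k in sp) {
      seq <- break_orf(seq,
                       list(start = found$start[k], end = found$end[k],
                            strand = found$strand[k]),
                       orfs, protected)
    }
  }
  found <- scan_orfs_string(seq, min_aa = min_aa)
  if (length(found$start) != nrow(orfs)) {
    abort("synthgen internal error: spurious ORFs survived repair")
  }

  # scrub accidental SD-like matches upstream of no-SD ORFs
  for (i in seq_len(nrow(orfs))) {
    if (orfs$has_sd[i]) next
    for (tries in 1:20) {
      win_lo <- max(0L, orfs$start[i] - (15L + 6L))
      win <- substr(seq, win_lo + 1L, orfs$start[i] - 3L)
      m <- regexpr("AGGA|GGAG|GAGG|AGGAG|GGAGG|AGGAGG", win)
      if (m < 0) break
      hit <- win_lo + as.integer(m)            # 1-based position of match start
      # mutate one base of the match, staying clear of the in-frame TAA
      target <- min(hit + 1L, orfs$start[i] - 3L)
      substr(seq, target, target) <- "C"
    }
  }

  orfs$protein <- vapply(seq_len(nrow(orfs)), function(i) {
    translate_orf(seq, orfs$start[i], orfs$end[i], orfs$strand[i])
  }, character(1))
  list(seq = seq, orfs = orfs)
}

# Insert a stop codon mid-ORF to destroy a spurious ORF without disturbing
# truth ORFs or protected regions.
break_orf <- function(seq, spur, orfs, protected) {
  n_codons <- (spur$end - spur$start) / 3L
  mid <- seq(5L, max(5L, n_codons - 6L))
  if (n_codons <= 11L) mid <- seq(1L, n_codons - 2L)
  # try positions from the middle outwards so the two remnants are short
  mid <- mid[order(abs(mid - n_codons / 2))]
  stops <- if (spur$strand == "+") STOP_CODONS else REV_STOP_TRINUCS
  for (ci in mid) {
    p <- spur$start + 3L * ci          # 0-based forward coord of codon start
    if (any(protected[(p + 1):(p + 3)])) next
    for (st in stops) {
      cand <- seq
      substr(cand, p + 1L, p + 3L) <- st
      if (local_mutation_safe(seq, cand, p) && truth_frames_ok(cand, orfs, p)) {
        return(cand)
      }
    }
  }
  abort("synthgen internal error: could not repair a spurious ORF")
}

# Forward-strand images of reverse-strand start codons (revcomp of ATG/GTG/TTG).
REV_START_TRINUCS <- c("CAT", "CAC", "CAA")

# A mutated triplet touches the five trinucleotide windows starting at
# p-2 .. p+2. The mutation is locally safe when it destroys no stop and
# creates no start in any frame of either strand: then the only change to
# the six-frame ORF decomposition is the intended split (new stops only
# shrink intervals, destroyed starts only shrink ORFs). This keeps the
# repair loop monotone without rescanning the whole segment.
local_mutation_safe <- function(before, after, p) {
  L <- nchar(before)
  starts_fwd <- c("ATG", "GTG", "TTG")
  for (w in max(0L, p - 2L):min(L - 3L, p + 2L)) {
    tb <- substr(before, w + 1L, w + 3L)
    ta <- substr(after, w + 1L, w + 3L)
    if (tb == ta) next
    if ((tb %in% STOP_CODONS && !(ta %in% STOP_CODONS)) ||
        (tb %in% REV_STOP_TRINUCS && !(ta %in% REV_STOP_TRINUCS))) {
      return(FALSE)
    }
    if ((!(tb %in% starts_fwd) && ta %in% starts_fwd) ||
        (!(tb %in% REV_START_TRINUCS) && ta %in% REV_START_TRINUCS)) {
      return(FALSE)
    }
  }
  TRUE
}

# Check that the (at most two) truth-ORF codons overlapping a mutated
# triplet did not become stops.
truth_frames_ok <- function(seq, orfs, p) {
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    if (p + 3L <= s || p >= e) next
    ci <- unique(pmax(0L, pmin(((c(p, p + 2L) - s) %/% 3L), (e - s) %/% 3L - 1L)))
    for (k in ci) {
      codon <- substr(seq, s + 3L * k + 1L, s + 3L * k + 3L)
      if ((orfs$strand[i] == "+" && codon %in% STOP_CODONS && s + 3L * k + 3L < e) ||
          (orfs$strand[i] == "-" && codon %in% REV_STOP_TRINUCS && s + 3L * k > s)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

translate_orf <- function(seq, start, end, strand) {
  nt <- substr(seq, start + 1L, end)
  if (strand == "-") nt <- revcomp(nt)
  nt <- substr(nt, 1L, nchar(nt) - 3L) # drop stop
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aa <- unname(genetic_code_11()[codons])
  aa[is.na(aa)] <- "X" # codons with N
  paste(aa, collapse = "")
}

#' Truncate contig ends (negative controls for completeness calling)
#'
#' @param seqs sequence tibble (`id`, `seq`, ...).
#' @param n5,n3 nucleotides to remove from the 5' and 3' ends (recycled).
#' @return the tibble with truncated `seq` and updated length columns if
#'   present.
#' @export
truncate_contig <- function(seqs, n5 = 0L, n3 = 0L) {
  validate_seq_tbl(seqs)
  n5 <- as.integer(rep_len(n5, nrow(seqs)))
  n3 <- as.integer(rep_len(n3, nrow(seqs)))
  len <- nchar(seqs$seq)
  if (any(n5 < 0 | n3 < 0)) abort("n5/n3 must be nonnegative")
  bad <- which(n5 + n3 >= len)
  if (length(bad)) {
    abort(sprintf("over-truncation of '%s': n5 + n3 >= length", seqs$id[bad[1]]))
  }
  seqs$seq <- substr(seqs$seq, n5 + 1L, len - n3)
  if ("length" %in% names(seqs)) seqs$length <- nchar(seqs$seq)
  seqs
}

#' Simulate FLDS reads from simulated genomes
#'
#' Both strands of each segment are fragmented at random breakpoints
#' (Normal(`fragment_len_mean`, `fragment_len_sd`) truncated below at
#' `fragment_len_min`); every fragment 3' end receives the adaptor; single-end
#' reads of `read_len` are sampled from both fragment ends, so a read crossing
#' a fragment 3' junction carries genomic suffix + adaptor prefix. Per-read
#' ground truth records the mapped interval, adaptor carriage, the forward
#' coordinate of the fragment 3' junction and whether it falls on a true
#' genome terminus. Substitution errors are applied at `error_rate`.
#' Deterministic given `cfg$seed`.
#'
#' @param genomes an `flds_genomes` object.
#' @param cfg the [sim_config()] (typically the one inside `genomes`).
#' @return object of class `flds_sim`: list with tibbles `reads` (id, seq,
#'   qual) and `truth` (read_id, genome_id, segment_id, strand, ref_start,
#'   ref_end, adaptor_len, junction_pos, true_terminus, n_errors), plus
#'   `config`.
#' @export
simulate_flds_reads <- function(genomes, cfg = genomes$config) {
  stopifnot(inherits(genomes, "flds_genomes"))
  validate_sim_config(cfg)
  if (!nzchar(cfg$adaptor)) abort("adaptor must be non-empty")
  with_seed((cfg$seed + 1000003L) %% .Machine$integer.max,
            simulate_reads_impl(genomes, cfg))
}

simulate_reads_impl <- function(genomes, cfg) {
  segs <- genomes$segments
  adaptor <- cfg$adaptor
  alen <- nchar(adaptor)
  rl <- cfg$read_len
  rows <- list()
  n_short <- 0L

  for (i in seq_len(nrow(segs))) {
    sid <- segs$segment_id[i]
    gid <- segs$genome_id[i]
    L <- segs$length[i]
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") segs$seq[i] else revcomp(segs$seq[i])
      target_bases <- cfg$coverage / 2 * L
      got <- 0
      a <- numeric(0); b <- numeric(0); ad <- integer(0); jb <- numeric(0)
      guard <- 0L
      while (got < target_bases && guard < 10000L) {
        guard <- guard + 1L
        lens <- pmax(cfg$fragment_len_min,
                     round(rnorm(ceiling(L / cfg$fragment_len_min) + 2,
                                 cfg$fragment_len_mean, cfg$fragment_len_sd)))
        ends <- cumsum(lens)
        k <- which(ends >= L)[1]
        ends <- c(ends[seq_len(k - 1)], L)
        starts <- c(0, ends[-length(ends)])
        flen <- ends - starts
        # 5'-end reads (no adaptor) and 3'-end reads crossing the junction
        g5 <- pmin(flen, rl)
        g3 <- pmin(flen, rl - alen)
        n_short <- n_short + sum(g5 < rl)
        a <- c(a, starts, ends - g3)
        b <- c(b, starts + g5, ends)
        ad <- c(ad, rep(0L, length(starts)), rep(alen, length(ends)))
        jb <- c(jb, rep(NA_real_, length(starts)), ends)
        got <- got + sum(g5) + sum(g3 + alen)
      }
      gseq <- substring(sseq, a + 1, b)
      rseq <- ifelse(ad > 0L, paste0(gseq, adaptor), gseq)
      fs <- if (strand == "+") a else L - b
      fe <- if (strand == "+") b else L - a
      jpos <- if (strand == "+") jb - 1 else L - jb
      rows[[length(rows) + 1]] <- tibble(
        genome_id = gid, segment_id = sid, strand = strand,
        ref_start = as.integer(fs), ref_end = as.integer(fe),
        adaptor_len = ad,
        junction_pos = as.integer(jpos),
        true_terminus = !is.na(jb) & jb == L,
        seq = rseq
      )
    }
  }
  truth <- list_rbind(rows)
  truth$read_id <- sprintf(
    "%s:%s:%06d", truth$segment_id,
    ifelse(truth$strand == "+", "f", "r"),
    stats::ave(seq_len(nrow(truth)), truth$segment_id, truth$strand, FUN = seq_along)
  )
  if (n_short > 0) {
    inform(sprintf(
      "simulate_flds_reads: %d fragment(s) shorter than read_len emitted as short reads",
      n_short
    ))
  }

  # substitution errors
  sq <- truth$seq
  nchr <- nchar(sq)
  nerr <- rbinom(length(sq), nchr, cfg$error_rate)
  for (j in which(nerr > 0)) {
    s <- sq[j]
    for (p in sample.int(nchr[j], nerr[j])) {
      substr(s, p, p) <- sample(setdiff(BASES, substr(s, p, p)), 1)
    }
    sq[j] <- s
  }
  truth$seq <- sq
  truth$n_errors <- nerr

  reads <- tibble(
    id = truth$read_id,
    seq = truth$seq,
    qual = strrep("I", nchar(truth$seq))
  )
  truth <- truth |>
    select("read_id", "genome_id", "segment_id", "strand", "ref_start",
           "ref_end", "adaptor_len", "junction_pos", "true_terminus",
           "n_errors", "seq")
  out <- list(reads = reads, truth = truth, config = cfg)
  class(out) <- "flds_sim"
  out
}

#' Build contigs from simulated segments
#'
#' Error-free copies of the simulated segments stand in for assembly output;
#' optional truncations create known-incomplete contigs as negative controls.
#'
#' @param genomes an `flds_genomes` object.
#' @param truncations optional tibble (`segment_id`, `n5`, `n3`).
#' @return sequence tibble with `id`, `seq`, `segment_id`, `n5`, `n3`.
#' @export
make_contigs <- function(genomes, truncations = NULL) {
  stopifnot(inherits(genomes, "flds_genomes"))
  out <- genomes$segments |>
    mutate(id = .data$segment_id, n5 = 0L, n3 = 0L) |>
    select("id", "seq", "segment_id", "n5", "n3")
  if (!is.null(truncations)) {
    for (i in seq_len(nrow(truncations))) {
      j <- match(truncations$segment_id[i], out$segment_id)
      if (is.na(j)) abort(sprintf("unknown segment '%s'", truncations$segment_id[i]))
      out$n5[j] <- as.integer(truncations$n5[i])
      out$n3[j] <- as.integer(truncations$n3[i])
      out$seq[j] <- truncate_contig(
        tibble(id = out$id[j], seq = out$seq[j]), out$n5[j], out$n3[j]
      )$seq
    }
  }
  out
}

#' Project simulated reads onto contigs as alignment records
#'
#' Converts the generator's per-read ground truth into the package's
#' alignment-record tibble against a set of contigs (possibly truncated
#' copies of the true segments). Read portions falling outside a contig
#' become soft-clipped sequence, exactly as an aligner would report them;
#' adaptor bases are always clipped. This is a simulation component with
#' perfect knowledge of read provenance, not a sequence aligner.
#'
#' @param sim an `flds_sim` object.
#' @param genomes the `flds_genomes` the reads came from.
#' @param contigs contig tibble from [make_contigs()]; defaults to
#'   untruncated segments.
#' @return alignment tibble (`read_id`, `ref_id`, `ref_start`, `ref_end`,
#'   `strand`, `identity`, `indel_count`, `clipped_prefix`, `clipped_suffix`).
#' @export
truth_alignments <- function(sim, genomes, contigs = make_contigs(genomes)) {
  stopifnot(inherits(sim, "flds_sim"))
  tr <- sim$truth
  ci <- match(tr$segment_id, contigs$segment_id)
  keep <- !is.na(ci)
  tr <- tr[keep, ]
  ci <- ci[keep]
  n5 <- contigs$n5[ci]
  clen <- nchar(contigs$seq[ci])
  s <- tr$ref_start - n5
  e <- tr$ref_end - n5
  cs <- pmax(s, 0L)
  ce <- pmin(e, clen)
  ok <- ce > cs
  tr <- tr[ok, ]; ci <- ci[ok]; n5 <- n5[ok]
  cs <- cs[ok]; ce <- ce[ok]

  # reference-oriented read sequence and index of its genomic block start
  minus <- tr$strand == "-"
  rseq <- tr$seq
  rseq[minus] <- revcomp(rseq[minus])
  g0 <- ifelse(minus, tr$adaptor_len, 0L)
  a_idx <- g0 + (cs + n5 - tr$ref_start)      # 0-based index into rseq
  w <- ce - cs
  aligned <- substr(rseq, a_idx + 1L, a_idx + w)
  refsub <- substring(contigs$seq[ci], cs + 1L, ce)
  mism <- numeric(length(aligned))
  chk <- which(tr$n_errors > 0) # error-free reads match their source exactly
  mism[chk] <- vapply(chk,
                      function(k) count_mismatches(aligned[k], refsub[k]),
                      numeric(1))
  tibble(
    read_id = tr$read_id,
    ref_id = contigs$id[ci],
    ref_start = cs,
    ref_end = ce,
    strand = tr$strand,
    identity = (w - mism) / w,
    indel_count = 0L,
    clipped_prefix = substr(rseq, 1L, a_idx),
    clipped_suffix = substr(rseq, a_idx + w + 1L, nchar(rseq))
  )
}
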