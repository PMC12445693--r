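# Shared fixtures: tiny sequence builders, a minimal SAM writer, and the
# brute-force CIGAR walker used as the coordinate oracle.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exactly k substitutions, never back to the original base
mutate_seq <- function(s, k) {
  pos <- sample(nchar(s), k)
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1)
  }
  s
}

seq_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(id = names(x), seq = unname(x))
}

write_min_sam <- function(path, refs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos1, cigar, seq, nm = NULL) {
  tags <- if (!is.null(nm)) sprintf("NM:i:%d", nm) else ""
  line <- paste(qname, flag, rname, pos1, 60, cigar, "*", 0, 0, seq, "*",
                sep = "\t")
  if (nzchar(tags)) line <- paste(line, tags, sep = "\t") else line
}

# Brute-force CIGAR walker: consumes ops one letter at a time and counts
# reference bases. Independent of the GenomicAlignments-based conversion.
cigar_ref_width_oracle <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  w <- 0L
  for (tk in toks) {
    n <- as.integer(sub("[A-Z=]$", "", tk))
    op <- sub("^[0-9]+", "", tk)
    if (op %in% c("M", "D", "N", "=", "X")) w <- w + n
  }
  w
}

# random valid CIGAR: optional leading/trailing soft clip around M/I/D blocks
random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- sample(c("M", "I", "D"), n_ops, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  ops[1] <- "M"; ops[n_ops] <- "M"
  lens <- sample(1:30, n_ops, replace = TRUE)
  body <- paste0(lens, ops, collapse = "")
  pre <- if (runif(1) < 0.4) paste0(sample(1:10, 1), "S") else ""
  suf <- if (runif(1) < 0.4) paste0(sample(1:10, 1), "S") else ""
  cig <- paste0(pre, body, suf)
  qlen <- sum(lens[ops %in% c("M", "I")]) +
    sum(as.integer(sub("S", "", c(pre, suf)[nzchar(c(pre, suf))])))
  list(cigar = cig, qlen = qlen)
}

# hand-built terminal profile for direct completeness-calling tests
make_profile <- function(contig_id, L, j5 = integer(L), j3 = integer(L),
                         coverage = rep(10L, L)) {
  out <- tibble::tibble(contig_id = contig_id, length = L,
                        j5 = list(j5), j3 = list(j3), coverage = list(coverage))
  class(out) <- c("flds_terminal_profile", class(out))
  out
}

# small simulation shared by several tests
small_sim <- function(seed, n_genomes = 3, coverage = 50,
                      error_rate = 0.002, ...) {
  cfg <- sim_config(n_genomes = n_genomes, coverage = coverage,
                    error_rate = error_rate, seed = seed, ...)
  genomes <- simulate_genomes(cfg)
  sim <- suppressMessages(simulate_flds_reads(genomes, cfg))
  list(cfg = cfg, genomes = genomes, sim = sim)
}
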