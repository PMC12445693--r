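# Generator contracts: determinism, terminal sharing, composition targets,
# fragmentation/adaptor geometry, and the negative-control truncation tool.

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genomes = 2, seed = 7)
  g1 <- simulate_genomes(cfg)
  g2 <- simulate_genomes(cfg)
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$orfs, g2$orfs)
  s1 <- suppressMessages(simulate_flds_reads(g1, cfg))
  s2 <- suppressMessages(simulate_flds_reads(g2, cfg))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("both segments of a genome share their terminal sequences exactly", {
  g <- simulate_genomes(sim_config(n_genomes = 4, seed = 3))
  s <- g$segments
  tl <- g$config$terminal_len
  expect_equal(substr(s$seq, 1, tl), s$terminal5)
  expect_equal(substr(s$seq, s$length - tl + 1, s$length), s$terminal3)
  # RNA1 and RNA2 prefixes agree within each genome
  for (gid in unique(s$genome_id)) {
    pair <- s[s$genome_id == gid, ]
    expect_equal(substr(pair$seq[1], 1, tl), substr(pair$seq[2], 1, tl))
  }
  # termini of different genomes are unrelated (not identical)
  expect_equal(anyDuplicated(s$terminal5[!duplicated(s$genome_id)]), 0L)
})

test_that("UTR composition follows the configured trinucleotide bias", {
  # bias concentrated on AAA; oracle = stationary distribution of the
  # order-2 chain (16 dinucleotide states), computed by linear algebra
  bias <- setNames(rep(0.1 / 63, 64), sort(fldseg:::all_trinucs()))
  bias["AAA"] <- 0.9
  bias <- bias / sum(bias)
  cfg <- sim_config(n_genomes = 1, utr_frac = 1, utr5_len = 3000L,
                    segment_len_range = c(5500L, 6500L),
                    utr_trinuc_bias = bias, seed = 21)
  g <- simulate_genomes(cfg)
  utr <- substr(g$segments$seq[1], cfg$terminal_len + 1,
                cfg$terminal_len + cfg$utr5_len)
  obs <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(utr),
                                            as.prob = TRUE)[["AAA"]]

  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  P <- matrix(0, 16, 16, dimnames = list(dinucs, dinucs))
  for (d in dinucs) {
    w <- bias[paste0(d, bases)]
    p <- w / sum(w)
    for (k in seq_along(bases)) {
      P[d, paste0(substr(d, 2, 2), bases[k])] <- p[k]
    }
  }
  ev <- eigen(t(P))
  pi_ <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_ <- pi_ / sum(pi_)
  p_aaa <- pi_[match("AA", dinucs)] * bias["AAA"] / sum(bias[paste0("AA", bases)])
  se <- sqrt(p_aaa * (1 - p_aaa) / cfg$utr5_len)
  expect_lt(abs(obs - p_aaa), 5 * se + 0.01)
})

test_that("fragmentation covers segments at the requested depth with adaptor junctions", {
  x <- small_sim(seed = 31, n_genomes = 2, error_rate = 0)
  total_bases <- sum(nchar(x$sim$reads$seq))
  total_len <- sum(x$genomes$segments$length)
  expect_lt(abs(total_bases / total_len - x$cfg$coverage) / x$cfg$coverage, 0.1)

  # every adaptor-bearing read ends with the adaptor (reads are error-free)
  tr <- x$sim$truth
  withad <- tr[tr$adaptor_len > 0, ]
  expect_true(all(endsWith(withad$seq, x$cfg$adaptor)))
  # a read at the + strand true terminus covers the last segment position
  plus_term <- withad[withad$true_terminus & withad$strand == "+", ][1, ]
  expect_equal(plus_term$ref_end,
               x$genomes$segments$length[
                 match(plus_term$segment_id, x$genomes$segments$segment_id)])
})

test_that("every true terminus collects junction reads at moderate coverage", {
  hits <- vapply(1:20, function(sd) {
    x <- small_sim(seed = 1000 + sd, n_genomes = 1, coverage = 20)
    tr <- x$sim$truth
    term <- tr[tr$true_terminus, ]
    # both strands of both segments -> 4 true termini
    all(table(factor(paste(term$segment_id, term$strand),
                     levels = unique(paste(tr$segment_id, tr$strand)))) >= 1)
  }, logical(1))
  expect_true(all(hits))
})

test_that("empty adaptor and invalid configs are rejected", {
  expect_error(sim_config(adaptor = ""), "adaptor")
  expect_error(sim_config(error_rate = 1.5), "error_rate")
  expect_error(sim_config(utr_trinuc_bias = rep(1 / 64, 64)), "named")
  g <- simulate_genomes(sim_config(n_genomes = 1, seed = 2))
  cfg_bad <- sim_config(n_genomes = 1, seed = 2)
  cfg_bad$adaptor <- ""
  expect_error(simulate_flds_reads(g, cfg_bad), "adaptor")
})

test_that("segment length range too small for the ORFs is an error", {
  expect_error(
    simulate_genomes(sim_config(n_genomes = 1, segment_len_range = c(1700L, 1750L),
                                seed = 1)),
    "too small"
  )
})

test_that("truncate_contig removes exact end lengths and refuses over-truncation", {
  tbl <- seq_tbl(c(x = "ACGTACGT"))
  expect_equal(truncate_contig(tbl, 2, 2)$seq, "GTAC")
  expect_equal(truncate_contig(tbl, 0, 0)$seq, "ACGTACGT")
  long <- seq_tbl(c(y = "ACGTACGTAC"))
  expect_error(truncate_contig(long, 6, 5), "over-truncation")
})

test_that("simulated coding and noncoding regions separate in trinucleotide space", {
  # composition contrast: UTR-vs-CDS distances exceed CDS-vs-CDS distances
  x <- small_sim(seed = 77, n_genomes = 3)
  pr <- trinuc_profile(utr_cds_regions(x$genomes))
  d <- composition_distance(pr)
  uc <- d$distance[xor(d$kind_a == "utr", d$kind_b == "utr")]
  cc <- d$distance[d$kind_a != "utr" & d$kind_b != "utr"]
  expect_gt(mean(uc), mean(cc))
  expect_gt(min(uc), max(cc))
})
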