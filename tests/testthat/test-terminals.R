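# Adaptor-junction detection and completeness calling.

adapt <- "GTTCAGAGTTCTACAGTCCG"

test_that("clipped adaptor sequence creates junction events at the right positions", {
  contigs <- seq_tbl(c(c1 = rand_dna(400)))
  aln <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    ref_id = "c1",
    ref_start = c(0L, 0L, 100L, 50L),
    ref_end = c(90L, 90L, 200L, 150L),
    strand = c("+", "+", "-", "+"),
    identity = 1, indel_count = 0L,
    clipped_prefix = c("", "", revcomp(adapt), ""),
    clipped_suffix = c(adapt, mutate_seq(adapt, 1), "", "CCCCCCCCCCCC")
  )
  prof <- detect_adaptor_junctions(aln, contigs, adapt, max_mismatch = 1)
  expect_equal(prof$j3[[1]][90], 2L)           # position 89 (0-based)
  expect_equal(prof$j5[[1]][101], 1L)          # position 100
  expect_equal(sum(prof$j3[[1]]), 2L)
  expect_equal(sum(prof$j5[[1]]), 1L)
  # with max_mismatch = 0 the mismatching copy is not counted
  prof0 <- detect_adaptor_junctions(aln, contigs, adapt, max_mismatch = 0)
  expect_equal(sum(prof0$j3[[1]]), 1L)
  # coverage accumulates over aligned spans
  expect_equal(prof$coverage[[1]][1], 2L)
  expect_equal(prof$coverage[[1]][140], 2L)
})

test_that("short adaptors are rejected", {
  contigs <- seq_tbl(c(c1 = rand_dna(300)))
  aln <- tibble::tibble(read_id = "a", ref_id = "c1", ref_start = 0L,
                        ref_end = 100L, strand = "+", identity = 1,
                        indel_count = 0L, clipped_prefix = "", clipped_suffix = "")
  expect_error(detect_adaptor_junctions(aln, contigs, "ACGTACG"), "10")
})

test_that("completeness statuses follow counts and enrichment", {
  L <- 1000L
  j5 <- integer(L); j5[1] <- 20L
  prof <- make_profile("c", L, j5 = j5)
  call <- call_completeness(prof)
  expect_equal(call$status5, "complete")
  expect_equal(call$peak5_pos, 0L)
  expect_gt(call$enrichment5, 5)
  expect_equal(call$status3, "incomplete")
  expect_true(is.na(call$peak3_pos))

  # uniform junctions (internal fragmentation only) -> both termini incomplete
  set.seed(5)
  j5u <- tabulate(sample(L, 40, replace = TRUE), nbins = L)
  j3u <- tabulate(sample(L, 40, replace = TRUE), nbins = L)
  unif <- call_completeness(make_profile("u", L, j5 = j5u, j3 = j3u))
  expect_false(unif$status5 == "complete")
  expect_false(unif$status3 == "complete")

  # all-zero coverage errors
  expect_error(call_completeness(make_profile("z", L, coverage = integer(L))),
               "no alignments")
  # contig too short for the window logic
  expect_error(call_completeness(make_profile("s", 150L)), "window")
})

test_that("terminal peaks land on the contig ends in simulation", {
  x <- small_sim(seed = 41, n_genomes = 3)
  contigs <- make_contigs(x$genomes)
  aln <- truth_alignments(x$sim, x$genomes, contigs)
  prof <- detect_adaptor_junctions(aln, contigs, x$cfg$adaptor)
  calls <- call_completeness(prof)
  expect_true(all(calls$status5 == "complete"))
  expect_true(all(calls$status3 == "complete"))
  expect_true(all(calls$peak5_pos == 0L))
  expect_equal(calls$peak3_pos, prof$length - 1L)
})

test_that("truncated contig ends lose their terminal call", {
  ok5 <- logical(0); ok3 <- logical(0)
  for (sd in 1:10) {
    x <- small_sim(seed = 500 + sd, n_genomes = 2)
    rna1 <- x$genomes$segments$segment_id[x$genomes$segments$role == "RNA1"][1]
    contigs <- make_contigs(x$genomes,
                            tibble::tibble(segment_id = rna1, n5 = 200L, n3 = 0L))
    aln <- truth_alignments(x$sim, x$genomes, contigs)
    calls <- call_completeness(
      detect_adaptor_junctions(aln, contigs, x$cfg$adaptor))
    ok5 <- c(ok5, calls$status5[calls$contig_id == rna1] != "complete")
    ok3 <- c(ok3, calls$status3[calls$contig_id == rna1] == "complete")
  }
  expect_true(all(ok5)) # truncated 5' end never called complete
  expect_true(mean(ok3) >= 0.9) # intact 3' end keeps its call
})

test_that("raising the enrichment threshold never upgrades a call", {
  x <- small_sim(seed = 61, n_genomes = 2)
  contigs <- make_contigs(x$genomes)
  prof <- detect_adaptor_junctions(truth_alignments(x$sim, x$genomes, contigs),
                                   contigs, x$cfg$adaptor)
  rank <- c(incomplete = 0, ambiguous = 1, complete = 2)
  prev5 <- rep(2, nrow(prof)); prev3 <- rep(2, nrow(prof))
  for (e in c(1, 5, 50, 5000)) {
    calls <- call_completeness(prof, enrich = e)
    expect_true(all(rank[calls$status5] <= prev5))
    expect_true(all(rank[calls$status3] <= prev3))
    prev5 <- rank[calls$status5]; prev3 <- rank[calls$status3]
  }
})

test_that("junction totals are invariant under alignment order permutation", {
  x <- small_sim(seed = 71, n_genomes = 1)
  contigs <- make_contigs(x$genomes)
  aln <- truth_alignments(x$sim, x$genomes, contigs)
  p1 <- detect_adaptor_junctions(aln, contigs, x$cfg$adaptor)
  set.seed(1)
  p2 <- detect_adaptor_junctions(aln[sample(nrow(aln)), ], contigs, x$cfg$adaptor)
  expect_identical(p1$j5, p2$j5)
  expect_identical(p1$j3, p2$j3)
  expect_identical(p1$coverage, p2$coverage)
})

test_that("trimming requires two complete termini and cuts at the peaks", {
  contigs <- seq_tbl(c(c1 = rand_dna(600)))
  calls <- tibble::tibble(contig_id = "c1", status5 = "complete",
                          status3 = "complete", peak5_pos = 3L, peak3_pos = 598L)
  out <- trim_to_termini(contigs, calls)
  expect_equal(out$seq, substr(contigs$seq, 4, 599))
  calls$peak5_pos <- 0L; calls$peak3_pos <- 599L
  expect_equal(trim_to_termini(contigs, calls)$seq, contigs$seq)
  calls$status5 <- "incomplete"
  expect_error(trim_to_termini(contigs, calls), "refus")
})
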