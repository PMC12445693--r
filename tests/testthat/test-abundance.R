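# Clustering, mapped-fragment counting under the identity/indel filter,
# FPKM arithmetic and composition pooling.

test_that("identical contigs cluster together; threshold dominance holds", {
  s <- rand_dna(800)
  cl <- greedy_cluster(seq_tbl(c(a = s, b = s)))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_members, 2L)

  three <- seq_tbl(c(a = rand_dna(500), b = rand_dna(600), c = rand_dna(700)))
  expect_equal(nrow(greedy_cluster(three)$clusters), 3)
  expect_equal(nrow(greedy_cluster(three, min_id = 0)$clusters), 1)
})

test_that("mutants join or found clusters around the 97% threshold", {
  set.seed(53)
  parent <- rand_dna(1000)
  m99 <- mutate_seq(parent, 10) # identity exactly 0.99 by construction
  m95 <- mutate_seq(parent, 50) # identity exactly 0.95
  cl <- greedy_cluster(seq_tbl(c(parent = parent, m99 = m99, m95 = m95)),
                       min_id = 0.97)
  memb <- tidy(cl)
  rep_of <- function(x) memb$representative_id[memb$contig_id == x]
  expect_equal(rep_of("parent"), rep_of("m99"))
  expect_false(rep_of("m95") == rep_of("parent"))
  expect_equal(nrow(cl$clusters), 2)
})

test_that("fragment counting applies the identity and indel filters", {
  aln <- tibble::tibble(
    read_id = c("f1/1", "f1/2", "f2/1", "f3/1", "f4/1", "f4/1"),
    ref_id = c("c1", "c1", "c1", "c2", "c1", "c2"),
    ref_start = 0L, ref_end = 100L, strand = "+",
    identity = c(0.99, 0.99, 0.96, 0.98, 0.98, 0.999),
    indel_count = c(0L, 0L, 0L, 4L, 0L, 0L),
    clipped_prefix = "", clipped_suffix = ""
  )
  counts <- count_fragments(aln, NULL, c(c1 = 2000L, c2 = 1000L))
  # f1 pair counts once; f2 fails identity; f3 fails indels;
  # f4 multi-maps and goes to its best-identity hit (c2)
  expect_equal(counts$mapped_fragments[counts$representative_id == "c1"], 1L)
  expect_equal(counts$mapped_fragments[counts$representative_id == "c2"], 1L)
})

test_that("simulated read-back counts track generated read counts", {
  x <- small_sim(seed = 59, n_genomes = 3)
  contigs <- make_contigs(x$genomes)
  aln <- truth_alignments(x$sim, x$genomes, contigs)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  counts <- count_fragments(aln, NULL, lens)
  generated <- table(x$sim$truth$segment_id)
  for (sid in names(generated)) {
    got <- counts$mapped_fragments[counts$representative_id == sid]
    expect_lt(abs(got - generated[[sid]]) / generated[[sid]], 0.05)
  }
})

test_that("FPKM arithmetic is exact and scale-invariant", {
  tbl <- fpkm_table(tibble::tibble(contig_id = "c1", mapped_fragments = 200L),
                    c(c1 = 2000L), 2e6)
  expect_identical(tbl$fpkm, 50.0)

  counts <- tibble::tibble(contig_id = c("a", "b", "z"),
                           mapped_fragments = c(100L, 400L, 0L))
  lens <- c(a = 1000L, b = 4000L, z = 500L)
  t1 <- fpkm_table(counts, lens, 1e6)
  expect_equal(t1$fpkm[t1$contig_id == "z"], 0)
  # doubling the library size halves every FPKM, shares unchanged
  t2 <- fpkm_table(counts, lens, 2e6)
  expect_equal(t2$fpkm, t1$fpkm / 2)
  expect_equal(t2$relative_share, t1$relative_share)
  # multiplying counts and library size by c leaves FPKM unchanged
  counts4 <- dplyr::mutate(counts, mapped_fragments = mapped_fragments * 4L)
  t4 <- fpkm_table(counts4, lens, 4e6)
  expect_equal(t4$fpkm, t1$fpkm)
  expect_equal(sum(t1$relative_share), 1, tolerance = 1e-9)

  expect_error(fpkm_table(counts, c(a = 0L, b = 1L, z = 1L), 1e6), "zero-length")
  expect_error(fpkm_table(counts, lens, 0), "total_cleaned_reads")
})

test_that("composition pooling follows the 2% rule and sums to one", {
  ab <- fpkm_table(tibble::tibble(contig_id = "c1", mapped_fragments = 10L),
                   c(c1 = 1000L), 1e6)
  tm1 <- tibble::tibble(contig_id = "c1", taxon_label = "A", nucleic_class = "dsRNA")
  solo <- composition_summary(ab, tm1)
  expect_equal(solo$share, 1.0)

  ab <- tibble::tibble(contig_id = c("c1", "c2", "c3", "c4"),
                       mapped_fragments = 1L, length_kb = 1,
                       fpkm = c(50, 46, 1, 3), relative_share = c(.5, .46, .01, .03))
  tm <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4"),
    taxon_label = c("Cystoviridae", "Picobirnaviridae", "Minor", "Unk"),
    nucleic_class = c("dsRNA", "dsRNA", "dsRNA", "unclassified")
  )
  comp <- composition_summary(ab, tm)
  expect_true("other dsRNA" %in% comp$taxon)   # the 1% dsRNA taxon pooled
  expect_true("others" %in% comp$taxon)        # unclassified
  expect_false("Minor" %in% comp$taxon)
  expect_equal(sum(comp$share), 1, tolerance = 1e-9)

  # ssRNA minors pool into their own category
  tm$nucleic_class[3] <- "ssRNA"
  expect_true("other ssRNA" %in% composition_summary(ab, tm)$taxon)
})

test_that("mixture proportions are recovered and sharpen with coverage", {
  shares_at <- function(coverage, seed) {
    cfg <- sim_config(n_genomes = 3, coverage = coverage, seed = seed)
    g <- simulate_genomes(cfg)
    sim <- suppressMessages(simulate_flds_reads(g, cfg))
    # thin genomes 2 and 3 to create a 1 : 0.6 : 0.4 input mixture
    keep <- runif(nrow(sim$truth)) < c(1, 0.6, 0.4)[
      as.integer(factor(sim$truth$genome_id))]
    sim$truth <- sim$truth[keep, ]
    contigs <- make_contigs(g)
    aln <- truth_alignments(sim, g, contigs)
    lens <- setNames(nchar(contigs$seq), contigs$id)
    ab <- fpkm_table(count_fragments(aln, NULL, lens), lens, sum(keep))
    gid <- sub("_RNA[12]$", "", ab$contig_id)
    tapply(ab$relative_share, gid, sum)[c("G01", "G02", "G03")]
  }
  set.seed(61)
  truthp <- c(1, 0.6, 0.4) / 2
  lo <- shares_at(10, 67)
  hi <- shares_at(100, 67)
  expect_equal(order(hi), order(truthp))
  expect_equal(order(lo), order(truthp))
  expect_lte(max(abs(hi - truthp)), max(abs(lo - truthp)) + 0.02)
})
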