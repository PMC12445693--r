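# Consensus expansion, column statistics, trimming, representative selection.

fam_tbl <- function(family_id, rows) {
  tibble::tibble(family_id = family_id,
                 row_id = paste0(family_id, "_", seq_along(rows)),
                 aln = rows)
}

random_aa_aln <- function(n_rows, n_cols, gap_p = 0.1) {
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  p <- c(rep((1 - gap_p) / 20, 20), gap_p)
  vapply(seq_len(n_rows), function(i) {
    paste(sample(aa, n_cols, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

test_that("family consensus takes the majority with sentinel gappy columns", {
  fam <- fam_tbl("f", c("AAG", "A-G", "G-G"))
  # col1 {A,A,G} -> A; col2 {A,-,-} gap 2/3 -> sentinel; col3 -> G
  cons <- family_consensus(fam)
  expect_equal(cons$consensus, "A.G")
  expect_equal(cons$emitted, "AG")

  tie <- family_consensus(fam_tbl("t", c("A", "A", "G", "G")))
  expect_equal(tie$consensus, "A")
})

test_that("expand_master emits family columns under consensus residues and gaps elsewhere", {
  famA <- fam_tbl("A", c("MKV", "MRV"))
  famB <- fam_tbl("B", c("WY", "WY"))
  consA <- family_consensus(famA)$emitted  # "MKV" (tie K/R -> K)
  consB <- family_consensus(famB)$emitted  # "WY"
  master <- tibble::tibble(family_id = c("A", "B"),
                           row_id = c("A", "B"),
                           aln = c("MKW-", "W-Y-"))
  expect_error(expand_master(master, list(A = famA, B = famB)), "consensus.*A|A.*consensus")
  master$aln <- c(paste0(consA, "-"), paste0("-", substr(consB, 1, 1), "-",
                                             substr(consB, 2, 2)))
  exp <- expand_master(master, list(A = famA, B = famB))
  expect_equal(nrow(exp), 4)
  expect_equal(unique(nchar(exp$aln)), 4L)
  # family A occupies master columns 1-3; its column 4 is all gaps
  expect_equal(exp$aln[exp$row_id == "A_1"], "MKV-")
  expect_equal(exp$aln[exp$row_id == "A_2"], "MRV-")
  # family B: master gaps at columns 1 and 3 -> gaps for all B rows there
  expect_equal(exp$aln[exp$row_id == "B_1"], "-W-Y")
  expect_equal(exp$aln[exp$row_id == "B_2"], "-W-Y")
})

test_that("round-trip: family rows extracted from the expansion reproduce the originals", {
  set.seed(83)
  for (case in 1:15) {
    fams <- list()
    consensi <- character(0)
    for (f in c("f1", "f2", "f3")) {
      fam <- fam_tbl(f, random_aa_aln(sample(2:5, 1), sample(4:10, 1)))
      fams[[f]] <- fam
      consensi[f] <- family_consensus(fam)$emitted
    }
    # build a random master by interleaving gaps
    master_rows <- vapply(names(fams), function(f) {
      chars <- strsplit(consensi[f], "")[[1]]
      out <- character(0)
      for (ch in chars) out <- c(out, if (runif(1) < 0.3) "-", ch)
      paste(out, collapse = "")
    }, character(1))
    W <- max(nchar(master_rows))
    master <- tibble::tibble(
      family_id = names(fams), row_id = names(fams),
      aln = paste0(master_rows, strrep("-", W - nchar(master_rows)))
    )
    exp <- expand_master(master, fams)
    for (f in names(fams)) {
      rows <- exp$aln[exp$family_id == f]
      # drop all-gap columns of the family slice
      m <- do.call(rbind, strsplit(rows, ""))
      keep <- colSums(m != "-") > 0
      got <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
      keep_cols <- family_consensus(fams[[f]])$keep
      orig <- vapply(strsplit(fams[[f]]$aln, ""), function(ch) {
        ch <- ch[keep_cols]
        paste(ch[rep(TRUE, length(ch))], collapse = "")
      }, character(1))
      # non-sentinel columns that are all-gap in the original also vanish
      mo <- do.call(rbind, strsplit(orig, ""))
      keep2 <- colSums(mo != "-") > 0
      orig <- apply(mo[, keep2, drop = FALSE], 1, paste, collapse = "")
      expect_equal(got, unname(orig))
    }
    # residue conservation: per-family non-gap residue multisets survive
    for (f in names(fams)) {
      keep_cols <- family_consensus(fams[[f]])$keep
      mo <- do.call(rbind, strsplit(fams[[f]]$aln, ""))[, keep_cols, drop = FALSE]
      before <- sort(mo[mo != "-"])
      me <- do.call(rbind, strsplit(exp$aln[exp$family_id == f], ""))
      after <- sort(me[me != "-"])
      expect_equal(after, before)
    }
  }
})

test_that("column homogeneity equals the brute-force pairwise identity", {
  stats <- column_stats(fam_tbl("x", c(rep("A", 5), rep("C", 5))))
  expect_equal(stats$homogeneity, 20 / 45)
  expect_equal(stats$gap_fraction, 0)

  expect_equal(column_stats(fam_tbl("y", rep("A", 7)))$homogeneity, 1.0)
  expect_equal(column_stats(fam_tbl("z",
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))$homogeneity, 0.0)

  # oracle: enumerate all residue pairs of 1000 random columns
  set.seed(89)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (trial in 1:1000) {
    n <- sample(2:12, 1)
    col <- sample(aa, n, replace = TRUE, prob = c(rep(0.045, 20), 0.1))
    stats <- column_stats(tibble::tibble(family_id = "o",
                                         row_id = as.character(seq_len(n)),
                                         aln = col))
    ng <- col[col != "-"]
    hom <- if (length(ng) < 2) 1.0 else {
      eq <- 0; tot <- 0
      for (i in 1:(length(ng) - 1)) for (j in (i + 1):length(ng)) {
        tot <- tot + 1
        if (ng[i] == ng[j]) eq <- eq + 1
      }
      eq / tot
    }
    expect_identical(stats$homogeneity, hom)
    expect_identical(stats$gap_fraction, mean(col == "-"))
  }
})

test_that("columns are trimmed by gap fraction or homogeneity, idempotently", {
  rows <- character(10)
  # col1: 7/10 gaps (0.70) -> removed; col2: 6/10 gaps (0.60) kept;
  # col3: conserved; col4: 10 distinct residues -> homogeneity 0 -> removed
  aa <- strsplit("ACDEFGHIKL", "")[[1]]
  for (i in 1:10) {
    rows[i] <- paste0(ifelse(i <= 7, "-", "W"), ifelse(i <= 6, "-", "Y"),
                      "M", aa[i])
  }
  aln <- tibble::tibble(family_id = "f", row_id = as.character(1:10), aln = rows)
  tr <- trim_columns(aln)
  expect_equal(tr$columns$removed, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unique(nchar(tr$alignment$aln)), 2L)
  expect_equal(tr$columns$new_index, c(NA, 1L, 2L, NA))

  # idempotent
  tr2 <- trim_columns(tr$alignment)
  expect_equal(sum(tr2$columns$removed), 0)
  expect_equal(tr2$alignment$aln, tr$alignment$aln)

  # a fully conserved alignment loses nothing
  cons <- tibble::tibble(family_id = "c", row_id = as.character(1:4),
                         aln = rep("MKWY", 4))
  expect_equal(sum(trim_columns(cons)$columns$removed), 0)
})

test_that("trimming keeps planted conserved cores and drops random flanks", {
  set.seed(97)
  core_len <- 40; flank <- 30
  fams <- list()
  for (f in paste0("f", 1:5)) {
    core <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         core_len, replace = TRUE), collapse = "")
    rows <- vapply(1:8, function(i) {
      paste0(random_aa_aln(1, flank, gap_p = 0.85), core)
    }, character(1))
    fams[[f]] <- fam_tbl(f, rows)
  }
  merged <- dplyr::bind_rows(fams)
  # stack families as one alignment: all equal width already
  tr <- trim_columns(merged)
  core_cols <- (flank + 1):(flank + core_len)
  flank_cols <- 1:flank
  expect_gte(mean(!tr$columns$removed[core_cols]), 0.95)
  expect_lte(mean(!tr$columns$removed[flank_cols]), 0.05)
})

test_that("diverse-representative selection spans planted haplogroups", {
  fam <- fam_tbl("f", c("MKY", "MKY", "MKY"))
  expect_equal(nrow(select_diverse(fam, k = 5)), 3)     # <= k -> all rows
  two <- select_diverse(fam, k = 2)
  expect_equal(two$row_id, c("f_1", "f_2"))             # deterministic ties

  set.seed(101)
  groups <- replicate(5, random_aa_aln(1, 40, gap_p = 0))
  rows <- character(0)
  labels <- integer(0)
  for (gi in 1:5) {
    for (r in 1:20) {
      s <- groups[gi]
      for (p in sample(40, 2)) substr(s, p, p) <- sample(strsplit("ACDEFGHIKL", "")[[1]], 1)
      rows <- c(rows, s)
      labels <- c(labels, gi)
    }
  }
  fam <- fam_tbl("h", rows)
  sel <- select_diverse(fam, k = 5)
  picked <- labels[match(sel$row_id, fam$row_id)]
  expect_setequal(picked, 1:5)                           # one per haplogroup
})
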