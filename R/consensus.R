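# Consensus-expansion alignment preparation: family-level protein alignments
# are summarized by consensus sequences, the consensi are aligned into a
# master alignment (externally, e.g. with MUSCLE), each consensus residue is
# expanded back to its full family column to form one complete alignment,
# and columns are trimmed by gap fraction and homogeneity before tree
# inference. Alignments are tibbles with one row per sequence
# (`family_id`, `row_id`, `aln`), gap character "-".

GAP <- "-"
SENTINEL <- "."

validate_alignment_tbl <- function(tbl, arg = "alignment") {
  need <- c("family_id", "row_id", "aln")
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    abort(sprintf("`%s` must have columns %s", arg, paste(need, collapse = ", ")))
  }
  for (f in unique(tbl$family_id)) {
    w <- nchar(tbl$aln[tbl$family_id == f])
    if (length(unique(w)) != 1) {
      abort(sprintf("rows of family '%s' differ in alignment length", f))
    }
  }
  invisible(tbl)
}

#' Read an aligned FASTA into an alignment tibble
#'
#' @param path aligned FASTA (amino acids, gap "-").
#' @param family_id family label to attach.
#' @return tibble `family_id`, `row_id`, `aln`.
#' @export
read_alignment_fasta <- function(path, family_id = basename(path)) {
  set <- Biostrings::readBStringSet(path)
  tibble(
    family_id = family_id,
    row_id = sub("\\s.*$", "", names(set)),
    aln = toupper(as.character(set))
  )
}

#' Write an alignment tibble to aligned FASTA
#'
#' @param tbl alignment tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(tbl, path) {
  set <- Biostrings::BStringSet(tbl$aln)
  names(set) <- tbl$row_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Family consensus with sentinel columns
#'
#' Per column, the most frequent non-gap residue (ties alphabetical).
#' Columns with gap fraction above 0.5 become sentinel positions, which are
#' excluded from the consensus emitted to the master aligner.
#'
#' @param fam alignment tibble of one family (>= 2 rows).
#' @return list with `consensus` (full length, sentinel "."), `emitted`
#'   (sentinels removed), `keep` (logical per column).
#' @export
family_consensus <- function(fam) {
  validate_alignment_tbl(fam, "fam")
  if (nrow(fam) < 2) abort("family_consensus needs at least 2 rows")
  m <- do.call(rbind, strsplit(fam$aln, ""))
  cons <- apply(m, 2, function(col) {
    ng <- col[col != GAP]
    if (length(ng) / length(col) < 0.5) return(SENTINEL)
    tb <- sort(table(ng), decreasing = TRUE)
    sort(names(tb)[tb == tb[1]])[1]
  })
  keep <- cons != SENTINEL
  list(
    consensus = paste(cons, collapse = ""),
    emitted = paste(cons[keep], collapse = ""),
    keep = keep
  )
}

#' Expand a master consensus alignment to the full family rows
#'
#' For master column j of family f: a consensus residue emits the family's
#' original alignment column, a gap emits gaps for all family rows. Row
#' order is families in master order, then family-internal order. The
#' ungapped content of each master row must equal the family's emitted
#' consensus.
#'
#' @param master alignment tibble of aligned consensus rows, one per family
#'   (`family_id`, `row_id`, `aln`).
#' @param fams named list of family alignment tibbles (names = family ids),
#'   or one tibble with a `family_id` column.
#' @return expanded alignment tibble of class `flds_expanded`
#'   (`family_id`, `row_id`, `aln`), all rows of master length.
#' @export
expand_master <- function(master, fams) {
  if (is.data.frame(fams)) {
    fams <- split(fams, fams$family_id)
  }
  Lm <- unique(nchar(master$aln))
  if (length(Lm) != 1) abort("master rows differ in length")
  out <- list()
  for (i in seq_len(nrow(master))) {
    fid <- master$family_id[i]
    fam <- fams[[fid]]
    if (is.null(fam)) abort(sprintf("no family alignment for '%s'", fid))
    cons <- family_consensus(fam)
    mrow <- strsplit(master$aln[i], "")[[1]]
    ungapped <- paste(mrow[mrow != GAP], collapse = "")
    if (ungapped != cons$emitted) {
      k <- which(strsplit(ungapped, "")[[1]] != strsplit(cons$emitted, "")[[1]])[1]
      abort(sprintf(
        "master row for family '%s' does not match its emitted consensus (first mismatch at consensus position %s)",
        fid, ifelse(is.na(k), "length", k)
      ))
    }
    fm <- do.call(rbind, strsplit(fam$aln, ""))
    ns_cols <- which(cons$keep)
    exp <- matrix(GAP, nrow = nrow(fm), ncol = Lm)
    pos <- which(mrow != GAP)
    exp[, pos] <- fm[, ns_cols, drop = FALSE]
    out[[length(out) + 1]] <- tibble(
      family_id = fid,
      row_id = fam$row_id,
      aln = apply(exp, 1, paste, collapse = "")
    )
  }
  res <- list_rbind(out)
  class(res) <- c("flds_expanded", class(res))
  res
}

#' Per-column gap fraction and homogeneity of an alignment
#'
#' Homogeneity is the mean pairwise identity among the non-gap residues of a
#' column; columns with fewer than two non-gap residues are undefined and
#' reported as 1.0 (never triggering removal).
#'
#' @param alignment alignment tibble (any `family_id` mix).
#' @return tibble `column_index` (1-based), `gap_fraction`, `homogeneity`.
#' @export
column_stats <- function(alignment) {
  if (nrow(alignment) == 0) abort("empty alignment")
  m <- do.call(rbind, strsplit(alignment$aln, ""))
  n <- nrow(m)
  stats <- apply(m, 2, function(col) {
    gaps <- sum(col == GAP)
    ng <- col[col != GAP]
    k <- length(ng)
    hom <- if (k < 2) 1.0 else {
      tb <- table(ng)
      sum(tb * (tb - 1) / 2) / (k * (k - 1) / 2)
    }
    c(gaps / n, hom)
  })
  tibble(
    column_index = seq_len(ncol(m)),
    gap_fraction = stats[1, ],
    homogeneity = stats[2, ]
  )
}

#' Trim alignment columns by gap fraction and homogeneity
#'
#' A column is removed when its gap fraction exceeds `max_gap` OR its
#' homogeneity is below `min_homogeneity` (two independent filters).
#' Idempotent: trimming a trimmed alignment removes nothing further.
#'
#' @param alignment alignment tibble (e.g. from [expand_master()]).
#' @param max_gap gap-fraction removal threshold (exclusive).
#' @param min_homogeneity homogeneity removal threshold (exclusive).
#' @return object of class `flds_trimmed`: list with `alignment` (trimmed
#'   tibble) and `columns` (per-column report with `removed` flag and
#'   old-to-new index mapping).
#' @export
trim_columns <- function(alignment, max_gap = 0.67, min_homogeneity = 0.05) {
  st <- column_stats(alignment)
  st$removed <- st$gap_fraction > max_gap | st$homogeneity < min_homogeneity
  st$new_index <- NA_integer_
  st$new_index[!st$removed] <- seq_len(sum(!st$removed))
  keep <- which(!st$removed)
  trimmed <- alignment
  trimmed$aln <- vapply(strsplit(alignment$aln, ""), function(ch) {
    paste(ch[keep], collapse = "")
  }, character(1))
  out <- list(alignment = trimmed, columns = st,
              max_gap = max_gap, min_homogeneity = min_homogeneity)
  class(out) <- "flds_trimmed"
  out
}

#' @export
print.flds_trimmed <- function(x, ...) {
  cat(sprintf(
    "<flds_trimmed> %d/%d column(s) kept (max_gap = %.2f, min_homogeneity = %.2f)\n",
    sum(!x$columns$removed), nrow(x$columns), x$max_gap, x$min_homogeneity
  ))
  invisible(x)
}

# Pairwise identity of two aligned rows: matches over columns where both are
# non-gap; 0 when no such column.
aligned_pair_identity <- function(a, b) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  both <- ra != GAP & rb != GAP
  if (!any(both)) return(0)
  mean(ra[both] == rb[both])
}

#' Select up to k most diverse rows of a family alignment
#'
#' Greedy maxi-min selection under pairwise aligned identity: start from the
#' pair with the lowest identity, then repeatedly add the row minimizing its
#' maximum identity to the chosen set. Ties break by row order.
#'
#' @param fam alignment tibble of one family.
#' @param k maximum number of representatives.
#' @return subset of `fam` (original row order preserved).
#' @export
select_diverse <- function(fam, k = 40L) {
  validate_alignment_tbl(fam, "fam")
  n <- nrow(fam)
  if (n <= k) return(fam)
  idm <- matrix(1, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- aligned_pair_identity(fam$aln[i], fam$aln[j])
    }
  }
  diag(idm) <- Inf
  first <- which(idm == min(idm), arr.ind = TRUE)
  first <- first[order(first[, 1], first[, 2]), , drop = FALSE][1, ]
  chosen <- sort(unname(first))
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    maxid <- vapply(rest, function(r) max(idm[r, chosen]), numeric(1))
    chosen <- c(chosen, rest[which.min(maxid)])
  }
  fam[sort(chosen), ]
}
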