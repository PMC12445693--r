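# Internal helpers shared across modules. All coordinates in the package are
# 0-based half-open; conversion to 1-based happens only at GFF/report output.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a vector of nucleotide strings
#'
#' Strict complement over A/C/G/T/N; anything else is an error.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  if (any(grepl("[^ACGTNacgtn]", x))) {
    abort("revcomp: sequence contains characters outside A/C/G/T/N")
  }
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x), function(s) {
    rawToChar(rev(charToRaw(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Count mismatching characters between two equal-length strings.
count_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    abort("count_mismatches: strings differ in length")
  }
  sum(ra != rb)
}

# Validate a sequence table (id, seq[, description]) against the shared
# record contract: unique ids, non-empty uppercase A/C/G/T/N, no whitespace.
validate_seq_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (anyDuplicated(seqs$id)) {
    dup <- seqs$id[duplicated(seqs$id)][1]
    abort(sprintf("duplicate sequence id '%s' in `%s`", dup, arg))
  }
  bad <- which(!nzchar(seqs$seq))
  if (length(bad)) {
    abort(sprintf("empty sequence for id '%s'", seqs$id[bad[1]]))
  }
  bad <- which(grepl("[^ACGTN]", seqs$seq))
  if (length(bad)) {
    abort(sprintf(
      "sequence '%s' contains characters outside A/C/G/T/N (is it uppercase DNA?)",
      seqs$id[bad[1]]
    ))
  }
  invisible(seqs)
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Ungapped identity between two equal-length strings (fraction of equal
# positions). N counts as a mismatch unless both are N.
ungapped_identity <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  if (length(ra) == 0) return(NA_real_)
  mean(ra == rb)
}
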