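# broom-style tidy()/glance() methods for the package's result objects.

#' @exportS3Method generics::tidy
tidy.flds_genome_sets <- function(x, ...) {
  x$membership |>
    left_join(x$sets |> select("genome_id", "n_segments", "consensus_t5",
                               "consensus_t3"),
              by = "genome_id")
}

#' @exportS3Method generics::glance
glance.flds_genome_sets <- function(x, ...) {
  tibble(
    n_sets = nrow(x$sets),
    n_segments = nrow(x$membership),
    n_multipartite = sum(x$sets$n_segments > 1),
    min_id = x$min_id
  )
}

#' @exportS3Method generics::tidy
tidy.flds_terminal_profile <- function(x, ...) {
  list_rbind(map(seq_len(nrow(x)), function(i) {
    tibble(
      contig_id = x$contig_id[i],
      pos = 0:(x$length[i] - 1L),
      j5 = x$j5[[i]],
      j3 = x$j3[[i]],
      coverage = x$coverage[[i]]
    )
  }))
}

#' @exportS3Method generics::glance
glance.flds_terminal_profile <- function(x, ...) {
  tibble(
    n_contigs = nrow(x),
    total_j5 = sum(map_dbl(x$j5, sum)),
    total_j3 = sum(map_dbl(x$j3, sum)),
    mean_coverage = mean(map_dbl(x$coverage, mean))
  )
}

#' @exportS3Method generics::tidy
tidy.flds_clusters <- function(x, ...) {
  x$membership
}

#' @exportS3Method generics::glance
glance.flds_clusters <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_contigs = nrow(x$membership),
    identity_threshold = x$identity_threshold
  )
}

#' @exportS3Method generics::tidy
tidy.flds_trimmed <- function(x, ...) {
  x$columns
}

#' @exportS3Method generics::glance
glance.flds_trimmed <- function(x, ...) {
  tibble(
    n_columns = nrow(x$columns),
    n_removed = sum(x$columns$removed),
    max_gap = x$max_gap,
    min_homogeneity = x$min_homogeneity
  )
}

#' @exportS3Method generics::tidy
tidy.flds_genomes <- function(x, ...) {
  x$segments |> select(-"seq")
}

#' @exportS3Method generics::glance
glance.flds_genomes <- function(x, ...) {
  tibble(
    n_genomes = length(unique(x$segments$genome_id)),
    n_segments = nrow(x$segments),
    n_orfs = nrow(x$orfs),
    mean_segment_len = mean(x$segments$length)
  )
}
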