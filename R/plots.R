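# ggplot2 displays for the main result types: junction pile-ups, six-frame
# stop-codon stripe maps, trinucleotide heatmaps, and stacked composition
# bars. Each returns a ggplot object the caller can theme further.

#' Plot adaptor-junction pile-ups along a contig
#'
#' @param profile an `flds_terminal_profile`.
#' @param contig_id contig to plot (default: first).
#' @return a ggplot.
#' @export
plot_terminal_profile <- function(profile, contig_id = profile$contig_id[1]) {
  i <- match(contig_id, profile$contig_id)
  if (is.na(i)) abort(sprintf("no profile for contig '%s'", contig_id))
  L <- profile$length[i]
  df <- bind_rows(
    tibble(pos = 0:(L - 1), count = profile$j5[[i]], terminus = "5' junctions"),
    tibble(pos = 0:(L - 1), count = profile$j3[[i]], terminus = "3' junctions")
  ) |> filter(.data$count > 0)
  cov <- tibble(pos = 0:(L - 1), coverage = profile$coverage[[i]])
  ggplot2::ggplot() +
    ggplot2::geom_area(
      data = cov,
      ggplot2::aes(x = .data$pos, y = .data$coverage / max(.data$coverage) *
                     max(c(df$count, 1))),
      fill = "grey85"
    ) +
    ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$pos, xend = .data$pos, y = 0, yend = .data$count,
                   colour = .data$terminus)
    ) +
    ggplot2::labs(x = "position (nt)", y = "adaptor-junction events",
                  title = contig_id,
                  subtitle = "grey: relative read coverage") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.flds_terminal_profile <- function(object, ...) {
  plot_terminal_profile(object, ...)
}

#' Stripe plot of stop codons in all six frames
#'
#' @param stop_map tibble from [stop_codon_map()].
#' @param segment_id segment to plot (default: first).
#' @return a ggplot.
#' @export
plot_stop_map <- function(stop_map, segment_id = stop_map$segment_id[1]) {
  df <- stop_map |>
    filter(.data$segment_id == !!segment_id) |>
    mutate(frame_label = paste0(.data$strand, .data$frame + 1L))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$pos, xend = .data$pos, y = 0, yend = 1)
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$frame_label)) +
    ggplot2::labs(x = "position (nt)", y = NULL, title = segment_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.flds_stop_map <- function(object, ...) {
  plot_stop_map(object, ...)
}

#' Trinucleotide-composition heatmap
#'
#' Rows (regions) are ordered by average-linkage hierarchical clustering of
#' their profiles.
#'
#' @param profiles long tibble from [trinuc_profile()].
#' @return a ggplot.
#' @export
plot_trinuc_heatmap <- function(profiles) {
  wide <- profiles |>
    select("region_id", "trinuc", "freq") |>
    tidyr::pivot_wider(names_from = "trinuc", values_from = "freq")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$region_id
  ord <- if (nrow(m) > 2) {
    stats::hclust(dist(m), method = "average")$order
  } else {
    seq_len(nrow(m))
  }
  df <- profiles |>
    mutate(region_id = factor(.data$region_id, levels = rownames(m)[ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trinuc, y = .data$region_id,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "frequency") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.flds_trinuc <- function(object, ...) {
  plot_trinuc_heatmap(object, ...)
}

#' Stacked-bar community composition
#'
#' @param composition tibble from [composition_summary()], optionally with a
#'   `sample` column for multi-sample bars.
#' @return a ggplot.
#' @export
plot_composition <- function(composition) {
  if (!"sample" %in% names(composition)) composition$sample <- "sample"
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$sample, y = .data$share,
                               fill = .data$taxon)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "relative abundance (FPKM share)") +
    ggplot2::theme_minimal()
}
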