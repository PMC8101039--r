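#' Plot linkage density and accuracy against genomic distance
#'
#' @param stats Output of [linkage_statistics()].
#' @return A ggplot: fraction of linked pairs, mean links per linked pair,
#'   and cis consistency per distance bin.
#' @export
plot_linkage_decay <- function(stats) {
  long <- stats |>
    mutate(distance = sqrt(.data$distance_lo * pmax(.data$distance_hi, 1))) |>
    tidyr::pivot_longer(c("frac_linked", "mean_links", "cis_fraction"),
                        names_to = "metric", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(labels = scales_comma) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "genomic distance (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE)

#' Penalty-score profiles of a phasing fit
#'
#' Shows the spin-flip penalty of every site and the switch penalty of
#' every boundary along the chromosome; low switch penalties mark likely
#' block breaks.
#'
#' @param object A `hap_fit`.
#' @param sites Optional site table to place scores at genomic positions.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hap_fit <- function(object, sites = NULL, ...) {
  x_of <- function(site) {
    if (is.null(sites)) site else sites$pos[site]
  }
  df <- bind_rows(
    tibble(x = x_of(object$spins$site),
           value = object$spins$flip_penalty, score = "spin-flip penalty"),
    tibble(x = x_of(object$boundaries$boundary),
           value = object$boundaries$switch_penalty,
           score = "switch penalty")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~score, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = if (is.null(sites)) "site index" else "position (bp)",
                  y = "penalty (energy units)") +
    ggplot2::theme_minimal()
}

#' Plot haplotype blocks along a chromosome
#'
#' One horizontal segment per block; when a truth haplotype is given,
#' blocks are shaded by intra-block accuracy (`max(f, 1 - f)`), making
#' switching errors visible as light blocks.
#'
#' @param blocks Per-site block table from [segment_blocks()].
#' @param sites Site table.
#' @param truth Optional truth haplotype (`site`, `spin`).
#' @param hide_short Drop blocks flagged short.
#' @return A ggplot.
#' @export
plot_blocks <- function(blocks, sites, truth = NULL, hide_short = TRUE) {
  b <- blocks
  if (hide_short && "short" %in% names(b)) b <- b[!b$short, ]
  spans <- b |>
    mutate(pos = sites$pos[.data$site],
           chrom = sites$chrom[.data$site]) |>
    group_by(.data$chrom, .data$block_id) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              .groups = "drop")
  if (!is.null(truth)) {
    spans <- left_join(spans, intra_block_accuracy(b, truth),
                       by = "block_id")
  } else {
    spans$accuracy <- NA_real_
  }
  spans$lane <- spans$block_id %% 2
  p <- ggplot2::ggplot(spans,
                       ggplot2::aes(x = .data$start, xend = .data$end,
                                    y = .data$lane, yend = .data$lane))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_segment(ggplot2::aes(colour = .data$accuracy),
                                   linewidth = 3) +
      ggplot2::scale_colour_gradient(low = "red", high = "grey30",
                                     limits = c(0.5, 1))
  } else {
    p <- p + ggplot2::geom_segment(linewidth = 3, colour = "grey30")
  }
  p + ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-1, 2)) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot haplotype-specific copy number
#'
#' @param bins Output of [copy_number()].
#' @return A ggplot with one point per bin and haplotype (A red, B blue).
#' @export
plot_copy_number <- function(bins) {
  long <- bins |>
    filter(.data$covered) |>
    tidyr::pivot_longer(c("cn_a", "cn_b"), names_to = "haplotype",
                        values_to = "cn") |>
    mutate(haplotype = ifelse(.data$haplotype == "cn_a", "A", "B"),
           mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$cn,
                                     colour = .data$haplotype)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(A = "#c23b22", B = "#2b6ca3")) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "haplotype copy number") +
    ggplot2::theme_minimal()
}

#' Plot a phased Hi-C contact map
#'
#' @param contacts Output of [phased_contacts()].
#' @return A ggplot tile map faceted by haplotype combination.
#' @export
plot_contacts <- function(contacts) {
  ggplot2::ggplot(contacts,
                  ggplot2::aes(x = .data$bin_i, y = .data$bin_j,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::facet_wrap(~combo) +
    ggplot2::labs(x = "bin (bp)", y = "bin (bp)") +
    ggplot2::theme_minimal()
}
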