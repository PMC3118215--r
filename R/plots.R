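#' Plot a P-score profile over a genomic region
#'
#' Per-probe P scores for one or more replicate tracks, with the peak-calling
#' threshold drawn as a dashed line and optional peak/region shading.
#'
#' @param pscores Long P-score tibble (from [pscore_tracks()]).
#' @param region One-row interval tibble to zoom to; `NULL` plots everything.
#' @param peaks Optional peak tibble to shade.
#' @param threshold P-score cut line (default 2).
#' @return A ggplot object.
#' @export
plot_pscore_profile <- function(pscores, region = NULL, peaks = NULL,
                                threshold = 2) {
  df <- pscores
  if (!is.null(region)) {
    df <- filter(df, .data$chrom == region$chrom[1],
                 .data$end > region$start[1], .data$start < region$end[1])
  }
  df$track <- if (all(c("tissue", "stage", "replicate") %in% names(df))) {
    paste(df$tissue, df$stage, df$replicate, sep = ":")
  } else "track"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data$pscore)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track)) +
    ggplot2::labs(x = "position (bp)", y = "P score (-log10 p)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    pk <- peaks
    if (!is.null(region)) {
      pk <- filter(pk, .data$chrom == region$chrom[1],
                   .data$end > region$start[1], .data$start < region$end[1])
    }
    if (nrow(pk)) {
      p <- p + ggplot2::geom_rect(
        data = pk,
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
        inherit.aes = FALSE)
    }
  }
  p
}

#' Plot a DMR summary table
#'
#' Stacked per-pattern location-category composition of a [tabulate_dmrs()]
#' table (pattern rows only).
#'
#' @param summary_table Output of [tabulate_dmrs()].
#' @return A ggplot object.
#' @export
plot_dmr_table <- function(summary_table) {
  pat <- filter(summary_table, .data$row_type == "pattern", .data$total > 0)
  long <- pat |>
    select("row", dplyr::starts_with("n_")) |>
    tidyr::pivot_longer(dplyr::starts_with("n_"), names_to = "category",
                        values_to = "n", names_prefix = "n_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DMR count", fill = "location") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` on a `medip_result` shows the T-DMR (or DS-DMR grand) summary
#' table composition.
#'
#' @param object A `medip_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot medip_result
autoplot.medip_result <- function(object, ...) {
  tab <- if (!is.null(object$tdmr)) object$tdmr$table else object$dsdmr$grand_table
  if (is.null(tab)) abort("nothing to plot: no DMR table computed")
  plot_dmr_table(tab)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
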