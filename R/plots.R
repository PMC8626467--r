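# Plot helpers. Minimal ggplot2 graphics for the main result types; all
# return ggplot objects so callers can restyle them.

#' Rainfall plot of inter-mutation distances
#'
#' log10 inter-mutation distance against genomic position per chromosome,
#' with detected kataegis foci highlighted.
#'
#' @param variants Variant tibble for one sample.
#' @param foci Optional [detect_kataegis()] table for the same sample.
#' @return A ggplot object.
#' @export
plot_rainfall <- function(variants, foci = NULL) {
  d <- variants |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(imd = .data$pos - dplyr::lag(.data$pos)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$imd), .data$imd >= 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = log10(.data$imd))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(x = "position (bp)", y = "log10 inter-mutation distance") +
    ggplot2::theme_minimal()
  if (!is.null(foci) && nrow(foci)) {
    p <- p + ggplot2::geom_rect(
      data = foci,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.2,
      inherit.aes = FALSE
    )
  }
  p
}

#' Copy-number frequency landscape plot
#'
#' Per-interval sample frequency of each CNA type along the genome, with
#' significant recurrent intervals highlighted when the table carries a
#' `significant` column.
#'
#' @param landscape Output of [frequency_landscape()] or
#'   [permutation_test()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  p <- ggplot2::ggplot(landscape) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end, y = .data$freq,
        yend = .data$freq, colour = .data$type
      ),
      linewidth = 1.2
    ) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(x = "position (bp)", y = "sample frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("significant" %in% names(landscape) && any(landscape$significant)) {
    p <- p + ggplot2::geom_point(
      data = landscape[landscape$significant, , drop = FALSE],
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$freq),
      shape = 8, size = 2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of event-timing posteriors
#'
#' One violin per event over the per-iteration relative-time draws, ordered
#' by mean relative time, with the WGD mean (when present) as a dashed
#' reference line.
#'
#' @param object A [estimate_timing()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.somevo_timing <- function(object, ...) {
  draws <- tibble::as_tibble(object$draws) |>
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "event_id", values_to = "rel_time"
    ) |>
    dplyr::mutate(event_id = factor(
      .data$event_id,
      levels = object$summary$event_id
    ))
  p <- ggplot2::ggplot(draws, ggplot2::aes(x = .data$event_id, y = .data$rel_time)) +
    ggplot2::geom_violin(fill = "grey80", colour = NA, scale = "width") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 1.5) +
    ggplot2::labs(x = NULL, y = "relative timing (0 = earliest)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("WGD" %in% object$summary$event_id) {
    wgd_t <- object$summary$mean_rel_time[object$summary$event_id == "WGD"]
    p <- p + ggplot2::geom_hline(yintercept = wgd_t, linetype = "dashed")
  }
  p
}
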