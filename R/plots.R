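#' Plot an HSMC's parameters
#'
#' Panels the occupancy distributions (zone length in metamers) and the
#' bud-fate and associated-flower emission distributions per state.
#'
#' @param object An `hsmc_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hsmc_model <- function(object, ...) {
  td <- tidy.hsmc_model(object)
  occ <- td[td$term == "occupancy", ]
  occ$duration <- as.integer(occ$category)
  occ <- occ[occ$estimate > 1e-6, ]
  emis <- td[td$term %in% c("fate", "flower"), ]
  occ$panel <- "occupancy (metamers)"
  emis$panel <- paste0(emis$term, " emissions")
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = occ,
      ggplot2::aes(x = .data$duration, y = .data$estimate)
    ) +
    ggplot2::geom_col(
      data = emis,
      ggplot2::aes(x = .data$category, y = .data$estimate)
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$state),
      cols = ggplot2::vars(.data$panel), scales = "free_x"
    ) +
    ggplot2::labs(x = NULL, y = "probability",
                  title = "Hidden semi-Markov chain parameters by state") +
    ggplot2::theme_minimal()
}

#' Plot restored zone segmentations along shoots
#'
#' Draws each shoot as a horizontal bar of metamers coloured by restored zone,
#' base (rank 1) to tip, ordered by shoot length.
#'
#' @param object A labelled `segmentation`.
#' @param max_shoots Cap on the number of shoots drawn (default 60).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.segmentation <- function(object, max_shoots = 60, ...) {
  if (!"zone" %in% names(object)) {
    abort("Segmentation has no `zone` column; run label_zones() first.")
  }
  totals <- object |>
    dplyr::group_by(.data$shoot_id) |>
    dplyr::summarise(total = sum(.data$length), .groups = "drop") |>
    dplyr::arrange(.data$total)
  keep <- utils::head(totals$shoot_id, max_shoots)
  d <- object[object$shoot_id %in% keep, ]
  d$shoot <- factor(d$shoot_id, levels = keep)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_rank - 0.5,
                   xend = .data$start_rank + .data$length - 0.5,
                   y = .data$shoot, yend = .data$shoot,
                   colour = .data$zone),
      linewidth = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(basal = "#8c6d31", median = "#d6616b", distal = "#6baed6"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "node rank (base to tip)", y = NULL,
                  title = "Optimal zone segmentation per shoot") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a parameter-recovery report
#'
#' Absolute estimation error per parameter against its tolerance, faceted by
#' parameter family, across the sample-size grid.
#'
#' @param object A `recovery_report` from [recovery_experiment()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$family <- sub("\\[.*$", "", d$parameter)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n), y = .data$abs_error)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_y") +
    ggplot2::labs(x = "simulated shoots", y = "absolute error",
                  title = "Parameter recovery by sample size") +
    ggplot2::theme_minimal()
}
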