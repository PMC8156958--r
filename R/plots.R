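# ggplot2 renderings of the main result types: contact chronograms,
# occupancy ribbons, competition traces and coordination bar charts.

#' Contact chronogram of ligand-residue timelines
#'
#' Residues on the ordinate, time on the abscissa, shaded where the ligand
#' is in contact -- the classic per-residue contact chronogram.
#'
#' @param timelines [contact_timeline()] tibble (one or more ligands).
#' @return A ggplot object.
#' @export
plot_chronogram <- function(timelines) {
  df <- timelines[timelines$contact, , drop = FALSE]
  ord <- unique(timelines$residue[order(res_key_number(timelines$residue))])
  df$residue <- factor(df$residue, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$residue)) +
    ggplot2::geom_tile(height = 0.8, width = max(timelines$time) /
                         max(length(unique(timelines$frame)), 1)) +
    ggplot2::facet_wrap(~ligand) +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Occupancy ribbons per ligand and site
#' @param occupancy Occupancy/trace tibble with `ligand`, `site`,
#'   `entry_time`/`start_time` and `exit_time`/`end_time` columns.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occupancy) {
  df <- occupancy
  if (!"entry_time" %in% names(df)) df$entry_time <- df$start_time
  if (!"exit_time" %in% names(df)) df$exit_time <- df$end_time
  ggplot2::ggplot(df, ggplot2::aes(y = .data$ligand, yend = .data$ligand,
                                   x = .data$entry_time,
                                   xend = .data$exit_time,
                                   colour = .data$site)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "time (ns)", y = NULL, colour = "site") +
    ggplot2::theme_minimal()
}

#' Two-species competition traces near the target atom
#' @param series_list List of [proximity_series()] tibbles.
#' @return A ggplot object showing distance traces and the threshold.
#' @export
plot_competition <- function(series_list) {
  df <- bind_rows(series_list)
  thr <- attr(series_list[[1]], "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$distance,
                                   colour = .data$ligand)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "time (ns)", y = "distance to target (Å)") +
    ggplot2::theme_minimal()
}

#' Coordination-probability bar chart
#' @param profile [coordination_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  df <- profile
  df$residue <- factor(df$residue,
                       levels = df$residue[order(res_key_number(df$residue))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$probability,
                                   fill = .data$high_propensity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contact probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.lox_report <- function(object, ...) {
  plot_occupancy(object$occupancy)
}
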