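# ggplot2 graphics for each result type.

#' Plot growth curves from a plate
#'
#' OD600 versus time, one line per well, coloured by phage (controls in
#' grey) and faceted by strain.
#'
#' @param plate A `plate_data` object.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  df <- dplyr::inner_join(plate$series, plate$map, by = "well") |>
    dplyr::mutate(phage = dplyr::coalesce(.data$phage, "control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$od600,
                                   group = .data$well,
                                   colour = .data$phage)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "time (h)", y = "OD600", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.host_range_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(call = factor(.data$call, levels = CALL_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phage, y = .data$strain,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(no_lysis = "grey85", reduced_growth = "#e8a33d",
                 lysis = "#2166ac"),
      na.value = "white", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call",
                  title = sprintf("%s host range", object$assay)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
autoplot.virulence_result <- function(object, ...) {
  df <- object$local_vi
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_moi, y = .data$vi)) +
    ggplot2::geom_area(fill = "#2166ac", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "log10(MOI)", y = "local virulence index vi",
                  subtitle = sprintf("vp = %.3f", object$vp)) +
    ggplot2::theme_minimal()
}

#' Plot a cocktail coverage-versus-depth table
#'
#' @param tbl Output of [coverage_table()].
#' @return A ggplot object.
#' @export
plot_coverage_depth <- function(tbl) {
  require_columns(tbl, c("k", "pct"), "coverage table")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$k, y = .data$pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = tbl$k) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "phages in cocktail (k)", y = "strains covered (%)") +
    ggplot2::theme_minimal()
}
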