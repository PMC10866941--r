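# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a growth record
#'
#' Cell counts by state over time (one line per state, replicates drawn as
#' thin lines when present).
#'
#' @param object A `growth_record` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_record <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::any_of(c("n_proliferative", "n_quiescent", "n_g0", "n_dying", "n_debris")),
    names_to = "state", values_to = "count"
  )
  long$state <- sub("^n_", "", long$state)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$day, y = .data$count, colour = .data$state
  ))
  if ("replicate" %in% names(long)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = interaction(.data$state, .data$replicate)),
      alpha = 0.4
    ) +
      ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.8)
  }
  p +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "days post-treatment", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibrated fate model
#'
#' The unaffected probability `p` against dose (log scale), with the raw
#' (pre-isotonic) values shown as points.
#'
#' @param object A `fate_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fate_model <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$concentration_uM)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_raw), shape = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (uM)",
      y = "per-cycle unaffected probability p",
      title = sprintf(
        "%s (lambda = %g, k = %.2f cycles)",
        object$drug, object$lambda, object$k
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an inhibition-ratio time series
#'
#' @param series Output of [assemble_inhibition_series()] (optionally with
#'   grouping columns such as `dose_a`/`dose_b` from a combination grid).
#' @return A ggplot object.
#' @export
plot_inhibition_series <- function(series) {
  grp <- intersect(c("dose_a", "dose_b", "condition"), names(series))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$day, y = .data$ratio))
  if (length(grp)) {
    series$label <- do.call(paste, c(series[grp], sep = " / "))
    p <- ggplot2::ggplot(series, ggplot2::aes(
      x = .data$day, y = .data$ratio, colour = .data$label
    ))
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$ratio - .data$sd, ymax = .data$ratio + .data$sd,
        fill = if (length(grp)) .data$label else NULL
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "days post-treatment", y = "treated / untreated area ratio",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the spatial state of a lattice
#'
#' @param object An `hdc_lattice`.
#' @param ... Unused.
#' @return A ggplot raster of cell states.
#' @export
autoplot.hdc_lattice <- function(object, ...) {
  st <- object$state
  df <- tibble::tibble(
    row = rep(seq_len(nrow(st)), ncol(st)),
    col = rep(seq_len(ncol(st)), each = nrow(st)),
    state = factor(
      names(cell_states())[match(as.vector(st), cell_states())],
      levels = names(cell_states())
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      empty = "white", proliferative = "#3366cc", quiescent = "#33a02c",
      g0_arrested = "#ffcc00", dying = "#e31a1c", debris = "black"
    ), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
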