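# ggplot2 displays for the main result types.

#' Plot a decay histogram
#'
#' Photon counts against arrival time on a log10 count scale.
#'
#' @param object A [decay_histogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.decay_histogram <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Arrival time (ns)", y = "Photon counts") +
    ggplot2::theme_minimal()
}

#' Plot a fit over its data
#'
#' Overlays the fitted expected curve on the observed histogram, with a
#' Pearson-residual panel underneath.
#'
#' @param object A `flim_fit`.
#' @param h The [decay_histogram()] that was fitted.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.flim_fit <- function(object, h, ...) {
  stopifnot(inherits(h, "decay_histogram"))
  mu <- object$amplitude *
    as.numeric(model_decay_curve(object$a1, object$tau_free,
                                 object$tau_bound, object$acq)) +
    object$background
  df <- tibble(time_ns = h$bin_times, counts = h$counts, fitted = mu)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$counts), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Arrival time (ns)", y = "Photon counts",
      subtitle = sprintf("a1 = %.3f, tau_bound = %.2f ns, tau_mean = %.2f ns, chi2_r = %.2f",
                         object$a1, object$tau_bound, object$tau_mean,
                         object$chi2_reduced)
    ) +
    ggplot2::theme_minimal()
}

#' Violin comparison of a per-cell quantity between groups
#'
#' The standard presentation of per-cell lifetime data: one violin per
#' group with the group mean drawn as a horizontal bar.
#'
#' @param records Per-cell tibble (rows from [fit_cells()]) with an added
#'   `group` column, or a named list of per-cell tibbles.
#' @param quantity One of `"tau_mean"`, `"a1_over_a2"`, `"tau_bound"`.
#' @return A ggplot.
#' @export
plot_group_violin <- function(records, quantity = c("tau_mean", "a1_over_a2",
                                                    "tau_bound")) {
  quantity <- match.arg(quantity)
  if (is.list(records) && !is.data.frame(records)) {
    records <- bind_rows(records, .id = "group")
  }
  if (!"group" %in% names(records)) {
    abort("`records` needs a `group` column (or pass a named list).",
          class = "flimredox_parameter_error")
  }
  df <- records |>
    dplyr::filter(.data$converged) |>
    mutate(value = switch(quantity,
                          tau_mean = .data$tau_mean,
                          a1_over_a2 = .data$a1 / .data$a2,
                          tau_bound = .data$tau_bound))
  ylab <- switch(quantity, tau_mean = "tau-mean (ns)",
                 a1_over_a2 = "a1/a2", tau_bound = "tau-bound (ns)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

#' Display a pseudocolor lifetime map
#'
#' @param object A `flim_segmentation`.
#' @param cells Per-cell tibble from [fit_cells()].
#' @param lut_range Lifetime color range (ns).
#' @param ... Ignored.
#' @return A ggplot rendering of [render_lifetime_map()].
#' @export
autoplot.flim_segmentation <- function(object, cells,
                                       lut_range = c(1.5, 4.0), ...) {
  img <- render_lifetime_map(cells, object, lut_range = lut_range)
  df <- expand.grid(y = seq_len(dim(img)[1]), x = seq_len(dim(img)[2]))
  df$col <- grDevices::rgb(img[cbind(df$y, df$x, 1)],
                           img[cbind(df$y, df$x, 2)],
                           img[cbind(df$y, df$x, 3)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
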