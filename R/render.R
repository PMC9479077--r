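#' Pseudocolor lifetime lookup table
#'
#' The fixed 256-entry blue-green-yellow-red ramp used for lifetime maps.
#'
#' @return A 256 x 3 matrix of RGB values in `[0, 1]`.
#' @export
lifetime_lut <- function() {
  cols <- grDevices::colorRampPalette(c("blue", "green", "yellow", "red"))(256)
  grDevices::col2rgb(cols) / 255
}

#' Render a pseudocolor lifetime map
#'
#' Colors each segmented cell's pixels by its fitted amplitude-weighted mean
#' lifetime, mapped linearly through [lifetime_lut()] over `lut_range`
#' (default 1.5-4.0 ns) and clamped at the ends; background pixels are
#' black.
#'
#' @param cells Per-cell tibble from [fit_cells()] (needs `cell_id` and
#'   `tau_mean`).
#' @param labels Integer label matrix from [segment_cells()].
#' @param lut_range `c(min, max)` lifetime range in ns; must be increasing.
#' @param path Optional PNG path to write.
#' @return An `height x width x 3` RGB array in `[0, 1]`, invisibly when
#'   `path` is given.
#' @export
render_lifetime_map <- function(cells, labels, lut_range = c(1.5, 4.0),
                                path = NULL) {
  if (length(lut_range) != 2L || !all(is.finite(lut_range)) ||
      lut_range[1] >= lut_range[2]) {
    abort("`lut_range` must be c(min, max) with min < max.",
          class = "flimredox_parameter_error")
  }
  if (inherits(labels, "flim_segmentation")) labels <- labels$labels
  lut <- lifetime_lut()
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    frac <- (cells$tau_mean[i] - lut_range[1]) / (lut_range[2] - lut_range[1])
    frac <- min(max(frac, 0), 1)
    entry <- 1L + as.integer(round(frac * 255))
    px <- which(labels == id)
    if (!length(px)) next
    rows <- (px - 1L) %% nrow(labels) + 1L
    cols <- (px - 1L) %/% nrow(labels) + 1L
    for (ch in 1:3) {
      img[cbind(rows, cols, ch)] <- lut[ch, entry]
    }
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}

#' Lifetime color of a single value
#'
#' The RGB triple [render_lifetime_map()] assigns to a given mean lifetime.
#'
#' @param tau_mean Lifetime in ns (vectorized).
#' @param lut_range As in [render_lifetime_map()].
#' @return A matrix with one RGB row (in `[0, 1]`) per input value.
#' @export
lifetime_color <- function(tau_mean, lut_range = c(1.5, 4.0)) {
  if (lut_range[1] >= lut_range[2]) {
    abort("`lut_range` must be c(min, max) with min < max.",
          class = "flimredox_parameter_error")
  }
  lut <- lifetime_lut()
  frac <- pmin(pmax((tau_mean - lut_range[1]) /
                      (lut_range[2] - lut_range[1]), 0), 1)
  entry <- 1L + as.integer(round(frac * 255))
  t(lut[, entry, drop = FALSE])
}
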