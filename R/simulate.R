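#' Construct a decay histogram
#'
#' A per-ROI pooled arrival-time histogram: the unit of analysis for fitting.
#'
#' @param counts Non-negative per-bin photon counts (length `acq$n_bins`).
#' @param acq The [acquisition_config()] the counts were recorded under.
#' @return An object of class `decay_histogram` with fields `counts`,
#'   `bin_times` (ns), `n_photons` and `acq`.
#' @export
decay_histogram <- function(counts, acq) {
  acq <- as_acquisition_config(acq)
  if (!is.numeric(counts) || length(counts) != acq$n_bins) {
    abort("`counts` must be numeric with one entry per time bin.",
          class = "flimredox_parameter_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite and non-negative.",
          class = "flimredox_parameter_error")
  }
  structure(
    list(counts = as.numeric(counts), bin_times = acq$bin_times,
         n_photons = sum(counts), acq = acq),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins, %g photons\n",
              length(x$counts), x$n_photons))
  invisible(x)
}

#' @export
as_tibble.decay_histogram <- function(x, ...) {
  tibble(time_ns = x$bin_times, counts = x$counts)
}

#' Simulate a shot-noise TCSPC histogram
#'
#' Draws per-bin counts as independent Poisson variates with mean
#' `n_photons * curve + background`, the standard shot-noise model for
#' photon-counting detection.
#'
#' @param curve Expected per-bin signal fractions from [model_decay_curve()]
#'   (or any non-negative vector summing to ~1).
#' @param n_photons Expected total signal photons (>= 0).
#' @param background Expected background counts per bin (scalar; e.g. the
#'   per-pixel rate times the number of pooled pixels).
#' @param seed Optional RNG seed for a reproducible draw.
#' @param acq Acquisition; defaults to the one attached to `curve`.
#' @return A [decay_histogram()].
#' @examples
#' curve <- model_decay_curve(0.69, 0.4, 3.02)
#' h <- simulate_histogram(curve, 5e4, background = 4, seed = 1)
#' h$n_photons
#' @export
simulate_histogram <- function(curve, n_photons, background = 0, seed = NULL,
                               acq = NULL) {
  acq <- as_acquisition_config(acq %||% attr(curve, "acq"))
  check_number(n_photons, "n_photons", lower = 0)
  check_number(background, "background", lower = 0)
  mu <- n_photons * as.numeric(curve) + background
  counts <- with_local_seed(seed, rpois(length(mu), mu))
  decay_histogram(counts, acq)
}

#' Field geometry for a simulated image
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_cells Number of cells to place (>= 0).
#' @param cell_radius_range `c(min, max)` semi-axis length in pixels; each
#'   cell is an ellipse with semi-axes drawn uniformly from this range and a
#'   uniform orientation.
#' @param max_attempts Rejection-sampling budget per cell before a placement
#'   error is raised.
#' @param margin Minimum clearance in pixels kept between neighbouring cell
#'   footprints, so that distinct cells never touch (8-connected components
#'   stay separate).
#' @return An object of class `field_layout`.
#' @export
field_layout <- function(image_shape = c(128L, 128L),
                         n_cells = 20L,
                         cell_radius_range = c(5, 9),
                         max_attempts = 2000L,
                         margin = 1.5) {
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    abort("`image_shape` must be c(height, width), each >= 8.",
          class = "flimredox_parameter_error")
  }
  check_number(n_cells, "n_cells", lower = 0)
  if (length(cell_radius_range) != 2L || cell_radius_range[1] <= 0 ||
      cell_radius_range[2] < cell_radius_range[1]) {
    abort("`cell_radius_range` must be c(min, max) with 0 < min <= max.",
          class = "flimredox_parameter_error")
  }
  check_number(margin, "margin", lower = 0)
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         cell_radius_range = cell_radius_range,
         max_attempts = as.integer(max_attempts), margin = margin),
    class = "field_layout"
  )
}

# Sample non-overlapping ellipse footprints inside the image. Returns a list
# with a per-cell tibble (centre, semi-axes, angle) and per-cell pixel index
# vectors plus elliptical-radius weights for the radial intensity profile.
place_cells <- function(layout) {
  h <- layout$image_shape[1]; w <- layout$image_shape[2]
  rmin <- layout$cell_radius_range[1]; rmax <- layout$cell_radius_range[2]
  cells <- vector("list", layout$n_cells)
  geoms <- vector("list", layout$n_cells)
  occupied <- matrix(FALSE, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_len(layout$n_cells)) {
    placed <- FALSE
    for (att in seq_len(layout$max_attempts)) {
      ra <- runif(1, rmin, rmax)
      rb <- runif(1, rmin, rmax)
      theta <- runif(1, 0, pi)
      mg <- layout$margin %||% 1.5
      rmax_i <- max(ra, rb) + mg
      cy <- runif(1, rmax_i + 1, h - rmax_i)
      cx <- runif(1, rmax_i + 1, w - rmax_i)
      ct <- cos(theta); st <- sin(theta)
      u <- ((xs - cx) * ct + (ys - cy) * st)
      v <- (-(xs - cx) * st + (ys - cy) * ct)
      r2 <- (u / ra)^2 + (v / rb)^2
      inside <- r2 <= 1
      # keep `margin` px of clearance: claim the dilated ellipse so that two
      # accepted footprints can never touch
      claim <- (u / (ra + mg))^2 + (v / (rb + mg))^2 <= 1
      if (!any(inside)) next
      if (any(occupied[claim])) next
      occupied[claim] <- TRUE
      idx <- which(inside)
      geoms[[i]] <- list(idx = idx, r2 = r2[idx])
      cells[[i]] <- tibble(cell_id = i, cy = cy, cx = cx,
                           semi_a = ra, semi_b = rb, angle = theta,
                           area = length(idx))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("Could not place cell %d without overlap after %d attempts; reduce n_cells or cell size.",
                    i, layout$max_attempts),
            class = "flimredox_placement_error")
    }
  }
  list(cells = if (layout$n_cells > 0) bind_rows(cells) else
         tibble(cell_id = integer(), cy = numeric(), cx = numeric(),
                semi_a = numeric(), semi_b = numeric(), angle = numeric(),
                area = integer()),
       geoms = geoms)
}

#' Simulate a FLIM field of yeast cells
#'
#' Renders a time-binned photon-count image stack (time-bin x y x x) of
#' elliptical yeast-cell footprints on a dark background, with known
#' ground-truth decay parameters per cell. Each cell draws its `(a1,
#' tau_bound)` from the preset's population distributions, its photons are
#' spread over its pixels with a radial (centre-bright) profile, per-pixel
#' per-bin counts are Poisson, and every pixel additionally receives uniform
#' background counts at the acquisition's `background_rate`.
#'
#' All randomness comes from one stream seeded by `seed`, drawn in a fixed
#' order (cell placement, then per-cell parameters, then photons), so a given
#' `(preset, layout, acq, seed)` always yields an identical stack.
#'
#' @param preset A [cell_preset()].
#' @param layout A [field_layout()].
#' @param acq An [acquisition_config()].
#' @param seed Integer RNG seed.
#' @return A list with `stack` (a `flim_stack`: integer array
#'   `[n_bins, height, width]` plus metadata) and `truth`, a tibble with one
#'   row per cell: `cell_id, cy, cx, area, a1_true, tau_bound_true,
#'   tau_mean_true`.
#' @examples
#' sim <- simulate_field(species_preset("kmarxianus"),
#'                       field_layout(n_cells = 3), seed = 1)
#' sim$truth
#' @export
simulate_field <- function(preset, layout = field_layout(),
                           acq = acquisition_config(), seed = 1L) {
  stopifnot(inherits(preset, "cell_preset"), inherits(layout, "field_layout"))
  acq <- as_acquisition_config(acq)
  h <- layout$image_shape[1]; w <- layout$image_shape[2]
  with_local_seed(seed, {
    placement <- place_cells(layout)
    params <- draw_cell_params(preset, layout$n_cells)
    counts <- array(0L, dim = c(acq$n_bins, h, w))
    # background first: uniform Poisson over every pixel and bin
    if (acq$background_rate > 0) {
      counts[] <- rpois(length(counts), acq$background_rate)
    }
    npx <- h * w
    for (i in seq_len(layout$n_cells)) {
      g <- placement$geoms[[i]]
      curve <- model_decay_curve(params$a1[i], preset$tau_free,
                                 params$tau_bound[i], acq)
      # centre-bright radial profile: weight 1 at the centre falling to ~0.3
      # at the membrane, normalized over the footprint
      wpx <- exp(-1.2 * g$r2)
      wpx <- wpx / sum(wpx)
      mu <- outer(as.numeric(curve), preset$photons_per_cell * wpx)
      draw <- rpois(length(mu), mu)
      # counts index: bin b, pixel p -> b + (p-1)*n_bins
      idx <- rep((g$idx - 1L) * acq$n_bins, each = acq$n_bins) +
        rep(seq_len(acq$n_bins), times = length(g$idx))
      counts[idx] <- counts[idx] + draw
    }
    truth <- tibble(
      cell_id = placement$cells$cell_id,
      cy = placement$cells$cy,
      cx = placement$cells$cx,
      area = placement$cells$area,
      a1_true = params$a1,
      tau_bound_true = params$tau_bound,
      tau_mean_true = params$tau_mean
    )
    stack <- structure(
      list(counts = counts, acq = acq, seed = as.integer(seed)),
      class = "flim_stack"
    )
    list(stack = stack, truth = truth)
  })
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_stack> %d bins x %d x %d px, %g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Simulate pooled per-ROI histograms from a preset
#'
#' Shortcut past the imaging stage: draws per-cell decay parameters from the
#' preset and generates one pooled TCSPC histogram per ROI, as if each cell's
#' photons had already been collected. Background is included at the
#' acquisition's per-pixel rate times a nominal pooled ROI size.
#'
#' @param preset A [cell_preset()].
#' @param n_roi Number of ROIs (cells) to simulate.
#' @param acq An [acquisition_config()].
#' @param roi_pixels Nominal pooled ROI size in pixels, setting the per-bin
#'   background mean to `background_rate * roi_pixels`.
#' @param seed Integer RNG seed.
#' @return A list with `histograms` (list of [decay_histogram()]) and
#'   `truth` (tibble of per-ROI `a1`, `tau_bound`, `tau_mean`).
#' @examples
#' sim <- simulate_roi_histograms(species_preset("kmarxianus"), 3, seed = 1)
#' sim$truth
#' @export
simulate_roi_histograms <- function(preset, n_roi,
                                    acq = acquisition_config(),
                                    roi_pixels = 200, seed = 1L) {
  stopifnot(inherits(preset, "cell_preset"))
  acq <- as_acquisition_config(acq)
  check_number(n_roi, "n_roi", lower = 0)
  bg <- acq$background_rate * roi_pixels
  with_local_seed(seed, {
    params <- draw_cell_params(preset, as.integer(n_roi))
    hists <- lapply(seq_len(nrow(params)), function(i) {
      curve <- model_decay_curve(params$a1[i], preset$tau_free,
                                 params$tau_bound[i], acq)
      simulate_histogram(curve, preset$photons_per_cell, background = bg,
                         acq = acq)
    })
    list(histograms = hists, truth = params)
  })
}

#' Total-intensity image of a FLIM stack
#'
#' @param stack A `flim_stack`.
#' @return A `height x width` matrix of photon counts summed over time bins.
#' @export
intensity_image <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  apply(stack$counts, c(2, 3), sum)
}
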