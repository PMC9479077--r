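#' TCSPC acquisition settings
#'
#' Bundles the time-resolution parameters of a simulated (or described)
#' time-correlated single-photon counting acquisition: the number and width of
#' the arrival-time bins, the laser repetition period, and a Gaussian model of
#' the instrument response function (IRF).
#'
#' The defaults describe a typical commercial two-photon TCSPC setup: an
#' 80 MHz laser (12.5 ns repetition period) histogrammed into 250 bins of
#' 50 ps, with a 150 ps FWHM Gaussian IRF peaking 1 ns into the window, and a
#' uniform dark/background level of 0.02 expected counts per bin per pixel.
#'
#' @param n_bins Integer number of arrival-time bins.
#' @param bin_width Width of one bin, in picoseconds.
#' @param period Laser repetition period, in nanoseconds. The histogram must
#'   fit inside one period: `n_bins * bin_width <= period * 1000`.
#' @param irf_center Position of the IRF peak within the window, in
#'   nanoseconds.
#' @param irf_fwhm Full width at half maximum of the Gaussian IRF, in
#'   picoseconds.
#' @param background_rate Expected background photons per bin per pixel
#'   (a dimensionless mean count).
#'
#' @return An object of class `acquisition_config`: a validated list with the
#'   fields above plus `bin_times`, the bin-center times in nanoseconds.
#' @examples
#' acq <- acquisition_config()
#' acq$n_bins
#' @export
acquisition_config <- function(n_bins = 250L,
                               bin_width = 50,
                               period = 12.5,
                               irf_center = 1.0,
                               irf_fwhm = 150,
                               background_rate = 0.02) {
  check_number(n_bins, "n_bins", lower = 1)
  check_number(bin_width, "bin_width", lower = 1e-6)
  check_number(period, "period", lower = 1e-6)
  check_number(irf_center, "irf_center", lower = 1e-9)
  check_number(irf_fwhm, "irf_fwhm", lower = 1e-9)
  check_number(background_rate, "background_rate", lower = 0)
  n_bins <- as.integer(n_bins)
  if (n_bins * bin_width > period * 1000 + 1e-9) {
    abort("Time bins must fit inside one repetition period: n_bins * bin_width <= period * 1000.",
          class = "flimredox_parameter_error")
  }
  if (irf_fwhm >= period * 1000) {
    abort("`irf_fwhm` must be smaller than the repetition period.",
          class = "flimredox_parameter_error")
  }
  bw_ns <- bin_width / 1000
  structure(
    list(
      n_bins = n_bins,
      bin_width = bin_width,
      period = period,
      irf_center = irf_center,
      irf_fwhm = irf_fwhm,
      background_rate = background_rate,
      bin_times = (seq_len(n_bins) - 0.5) * bw_ns
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %d bins x %g ps, period %g ns, IRF %g ps FWHM @ %g ns, background %g/bin/px\n",
    x$n_bins, x$bin_width, x$period, x$irf_fwhm, x$irf_center,
    x$background_rate
  ))
  invisible(x)
}

as_acquisition_config <- function(x) {
  if (inherits(x, "acquisition_config")) return(x)
  if (is.list(x)) {
    return(acquisition_config(
      n_bins = x$n_bins, bin_width = x$bin_width, period = x$period,
      irf_center = x$irf_center, irf_fwhm = x$irf_fwhm,
      background_rate = x$background_rate %||% 0.02
    ))
  }
  abort("Cannot interpret `acq` as an acquisition_config.",
        class = "flimredox_parameter_error")
}
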