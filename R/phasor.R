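#' Phasor transform of a decay histogram
#'
#' Model-free Fourier summary of a decay at the fundamental laser frequency
#' `omega = 2*pi / period`:
#' `g = sum(counts * cos(omega*t)) / sum(counts)` and
#' `s = sum(counts * sin(omega*t)) / sum(counts)`, corrected for the
#' instrument response by complex division by the IRF's own phasor. After the
#' correction a mono-exponential decay of lifetime `tau` lands on the
#' universal semicircle `g^2 + s^2 = g`, at `g = 1 / (1 + (omega*tau)^2)`,
#' and mixtures lie on the chord between their component points weighted by
#' photon (intensity) fractions.
#'
#' @param h A [decay_histogram()] with at least one photon.
#' @return A one-row tibble with columns `g`, `s`, `tau_phase` (the
#'   phase lifetime `s / (g * omega)`, ns) and `n_photons`.
#' @examples
#' h <- simulate_histogram(model_decay_curve(1, 2, 2), 1e5, seed = 1)
#' phasor_transform(h)
#' @export
phasor_transform <- function(h) {
  stopifnot(inherits(h, "decay_histogram"))
  if (h$n_photons <= 0) {
    abort("Phasor transform is undefined for a zero-photon histogram.",
          class = "flimredox_parameter_error")
  }
  acq <- h$acq
  omega <- 2 * pi / acq$period
  ph <- function(v) {
    complex(real = sum(v * cos(omega * acq$bin_times)),
            imaginary = sum(v * sin(omega * acq$bin_times))) / sum(v)
  }
  z <- ph(h$counts) / ph(irf_curve(acq))
  g <- Re(z); s <- Im(z)
  tibble(g = g, s = s,
         tau_phase = if (abs(g) > 1e-12) s / (g * omega) else NA_real_,
         n_photons = h$n_photons)
}
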