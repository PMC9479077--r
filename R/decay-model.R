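# Bi-exponential TCSPC decay model with Gaussian IRF under periodic excitation.

# Exponential decay exp(-(t - t0)/tau) (unit pre-exponential amplitude)
# convolved with a Gaussian IRF of standard deviation `sigma` centred at `t0`,
# evaluated at times `t` (all in ns). Computed on the log scale so that small
# tau / large sigma combinations do not overflow the exp() prefactor.
exp_gauss <- function(t, tau, t0, sigma) {
  dt <- t - t0
  if (sigma <= 0) {
    out <- numeric(length(t))
    pos <- dt >= 0
    out[pos] <- exp(-dt[pos] / tau)
    return(out)
  }
  lg <- -log(2) + sigma^2 / (2 * tau^2) - dt / tau +
    log_erfc(sigma / (sqrt(2) * tau) - dt / (sqrt(2) * sigma))
  exp(lg)
}

# Periodic (wrapped) version: photons excited by earlier pulses that arrive in
# the current observation window. Summing a handful of prior periods is exact
# to double precision because exp(-period/tau) is tiny for any lifetime this
# model allows.
periodic_exp_gauss <- function(t, tau, t0, sigma, period, n_wrap = 12L) {
  out <- numeric(length(t))
  for (k in 0:n_wrap) {
    out <- out + exp_gauss(t + k * period, tau, t0, sigma)
  }
  out
}

#' Expected bi-exponential TCSPC decay curve
#'
#' Computes the expected (noise-free) arrival-time histogram of a
#' two-component NAD(P)H decay: amplitude fraction `a1` of free NAD(P)H with
#' lifetime `tau_free` and `a2 = 1 - a1` of protein-bound NAD(P)H with
#' lifetime `tau_bound`. The pure decay `a1*exp(-t/tau_free) +
#' a2*exp(-t/tau_bound)` is circularly convolved with the Gaussian IRF of
#' `acq` over one laser repetition period (so incomplete decays wrap around)
#' and normalized to sum to 1 over the bins.
#'
#' @param a1 Amplitude fraction of the free (short-lifetime) component, in
#'   `[0, 1]`.
#' @param tau_free Free-NAD(P)H lifetime in ns.
#' @param tau_bound Bound-NAD(P)H lifetime in ns. Ignored when `a1 = 1`.
#' @param acq An [acquisition_config()].
#'
#' @return A numeric vector of length `acq$n_bins` summing to 1, with the
#'   acquisition attached as attribute `"acq"`.
#' @examples
#' acq <- acquisition_config()
#' curve <- model_decay_curve(0.69, 0.4, 3.02, acq)
#' sum(curve)
#' @export
model_decay_curve <- function(a1, tau_free, tau_bound, acq = acquisition_config()) {
  acq <- as_acquisition_config(acq)
  check_number(a1, "a1", lower = 0, upper = 1)
  check_number(tau_free, "tau_free", lower = 1e-6)
  if (a1 < 1) check_number(tau_bound, "tau_bound", lower = 1e-6)
  sigma <- acq$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))
  t <- acq$bin_times
  curve <- a1 * periodic_exp_gauss(t, tau_free, acq$irf_center, sigma, acq$period)
  if (a1 < 1) {
    curve <- curve +
      (1 - a1) * periodic_exp_gauss(t, tau_bound, acq$irf_center, sigma, acq$period)
  }
  s <- sum(curve)
  if (!is.finite(s) || s <= 0) {
    abort("Decay model produced a degenerate curve; check parameters.",
          class = "flimredox_parameter_error")
  }
  structure(curve / s, acq = acq)
}

# Binned, wrapped Gaussian IRF on the acquisition grid, normalized to sum 1.
irf_curve <- function(acq) {
  acq <- as_acquisition_config(acq)
  sigma <- acq$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))
  t <- acq$bin_times
  v <- numeric(acq$n_bins)
  for (k in -2:2) {
    v <- v + dnorm(t + k * acq$period, mean = acq$irf_center, sd = sigma)
  }
  v / sum(v)
}

#' Amplitude-weighted mean lifetime
#'
#' The per-cell redox readout: `tau_mean = a1 * tau_free + a2 * tau_bound`
#' with `a2 = 1 - a1`. A longer mean lifetime indicates a more oxidized
#' NAD(P)H pool.
#'
#' @param a1 Free-component amplitude fraction in `[0, 1]` (vectorized).
#' @param tau_free,tau_bound Component lifetimes in ns (vectorized).
#' @return `a1 * tau_free + (1 - a1) * tau_bound`, in ns.
#' @examples
#' tau_mean_identity(0.690, 0.4, 3.02)
#' @export
tau_mean_identity <- function(a1, tau_free, tau_bound) {
  if (!is.numeric(a1) || any(!is.finite(a1)) || any(a1 < 0) || any(a1 > 1)) {
    abort("`a1` must be a fraction in [0, 1].", class = "flimredox_parameter_error")
  }
  a1 * tau_free + (1 - a1) * tau_bound
}

#' Intensity-weighted mean lifetime
#'
#' Weighted by emitted photons rather than molecular amplitudes:
#' `(a1*tau_free^2 + a2*tau_bound^2) / (a1*tau_free + a2*tau_bound)`. This is
#' the lifetime a phasor or mean-arrival-time measurement estimates for a
#' mixture, always at least as long as the amplitude-weighted mean.
#'
#' @inheritParams tau_mean_identity
#' @return Intensity-weighted lifetime in ns.
#' @export
tau_intensity_weighted <- function(a1, tau_free, tau_bound) {
  if (!is.numeric(a1) || any(!is.finite(a1)) || any(a1 < 0) || any(a1 > 1)) {
    abort("`a1` must be a fraction in [0, 1].", class = "flimredox_parameter_error")
  }
  (a1 * tau_free^2 + (1 - a1) * tau_bound^2) /
    (a1 * tau_free + (1 - a1) * tau_bound)
}
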