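# Shared fixtures: small acquisition grids and canonical simulation settings.

default_acq <- function() acquisition_config()

# fine grid with a near-delta IRF and long period, for closed-form checks
fine_acq <- function() {
  acquisition_config(n_bins = 4000, bin_width = 12.5, period = 50,
                     irf_center = 1.0, irf_fwhm = 1e-3,
                     background_rate = 0)
}

km_params <- list(a1 = 0.690, tau_free = 0.4, tau_bound = 3.02)
sc_params <- list(a1 = 0.773, tau_free = 0.4, tau_bound = 2.78)

km_histogram <- function(n_photons = 5e4, background = 0, seed = 1) {
  simulate_histogram(
    model_decay_curve(km_params$a1, km_params$tau_free, km_params$tau_bound),
    n_photons, background = background, seed = seed
  )
}
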