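# Poisson maximum-likelihood fitting of pooled decay histograms.

# Negative Poisson log-likelihood (up to the data-only constant) of counts y
# under per-bin means mu.
poisson_nll <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  sum(mu - y * log(mu))
}

new_fit_result <- function(a1, tau_free, tau_bound, amplitude, background,
                           chi2_reduced, converged, n_photons, acq,
                           tau_free_fixed, loglik) {
  # canonical ordering: component 1 is the shorter lifetime
  if (tau_free > tau_bound) {
    tmp <- tau_free; tau_free <- tau_bound; tau_bound <- tmp
    a1 <- 1 - a1
  }
  a2 <- 1 - a1
  structure(
    list(
      a1 = a1, a2 = a2,
      tau_free = tau_free, tau_bound = tau_bound,
      tau_mean = a1 * tau_free + a2 * tau_bound,
      tau_intensity = tau_intensity_weighted(a1, tau_free, tau_bound),
      amplitude = amplitude, background = background,
      chi2_reduced = chi2_reduced, converged = converged,
      n_photons = n_photons, tau_free_fixed = tau_free_fixed,
      loglik = loglik, acq = acq
    ),
    class = "flim_fit"
  )
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit> a1 %.3f / a2 %.3f, tau_free %.3f ns%s, tau_bound %.3f ns, tau_mean %.3f ns\n  %g photons, reduced chi2 %.3f, %s\n",
    x$a1, x$a2, x$tau_free, if (x$tau_free_fixed) " (fixed)" else "",
    x$tau_bound, x$tau_mean, x$n_photons, x$chi2_reduced,
    if (x$converged) "converged" else "NOT CONVERGED"
  ))
  invisible(x)
}

#' @export
tidy.flim_fit <- function(x, ...) {
  tibble(
    term = c("a1", "a2", "tau_free", "tau_bound", "tau_mean", "background"),
    estimate = c(x$a1, x$a2, x$tau_free, x$tau_bound, x$tau_mean, x$background),
    fixed = c(FALSE, FALSE, x$tau_free_fixed, FALSE, FALSE, FALSE)
  )
}

#' @export
glance.flim_fit <- function(x, ...) {
  tibble(
    n_photons = x$n_photons, chi2_reduced = x$chi2_reduced,
    logLik = x$loglik, converged = x$converged
  )
}

# Pearson reduced chi-square over bins with positive expectation.
pearson_chi2 <- function(y, mu, n_free) {
  use <- mu > 0
  chi2 <- sum((y[use] - mu[use])^2 / mu[use])
  df <- max(sum(use) - n_free, 1L)
  chi2 / df
}

#' Fit a bi-exponential decay by Poisson maximum likelihood
#'
#' Fits `counts ~ Poisson(amplitude * model_decay_curve(a1, tau_free,
#' tau_bound) + background)` to a pooled per-ROI histogram. Free parameters
#' are the free fraction `a1` (optimized on the logit scale), the bound
#' lifetime (log scale, bounded to 0.5–6 ns), the signal amplitude and a flat
#' background offset (both log scale). The free-NAD(P)H lifetime is held at
#' `fix_tau_free` (pipeline default 0.4 ns) unless `fix_tau_free = NULL`, in
#' which case it is fitted too. Components are reported in canonical order
#' (component 1 = shorter lifetime), so `tau_mean = a1*tau_free +
#' a2*tau_bound` is always the amplitude-weighted mean lifetime.
#'
#' On non-convergence the optimizer is restarted once from a coarse
#' grid-search optimum; if that also fails the result carries
#' `converged = FALSE`.
#'
#' @param h A [decay_histogram()] with at least `min_photons` counts.
#' @param fix_tau_free Free lifetime in ns to hold fixed, or `NULL` to fit it.
#' @param min_photons Histograms with fewer total photons are rejected
#'   (pooled-ROI bi-exponential fits are unstable below a few hundred counts).
#' @return A `flim_fit` object; see [tidy.flim_fit()] and
#'   [glance.flim_fit()].
#' @examples
#' curve <- model_decay_curve(0.69, 0.4, 3.02)
#' h <- simulate_histogram(curve, 5e4, seed = 1)
#' fit <- fit_biexponential(h)
#' fit$tau_mean
#' @export
fit_biexponential <- function(h, fix_tau_free = 0.4, min_photons = 500) {
  stopifnot(inherits(h, "decay_histogram"))
  if (h$n_photons < min_photons) {
    abort(sprintf("Histogram has %g photons; at least %g are required for a stable bi-exponential fit.",
                  h$n_photons, min_photons),
          class = "flimredox_low_photon_error")
  }
  if (!is.null(fix_tau_free)) check_number(fix_tau_free, "fix_tau_free", lower = 1e-3)
  acq <- h$acq
  y <- h$counts
  fit_free_tau <- is.null(fix_tau_free)
  tau_f0 <- if (fit_free_tau) 0.4 else fix_tau_free

  sigma <- acq$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))
  tbin <- acq$bin_times
  comp_curve <- function(tau) {
    periodic_exp_gauss(tbin, tau, acq$irf_center, sigma, acq$period)
  }
  cf_fixed <- if (!fit_free_tau) comp_curve(tau_f0) else NULL
  nll <- function(theta) {
    a1 <- plogis(theta[1])
    tb <- exp(theta[2])
    amp <- exp(theta[3])
    bg <- exp(theta[4])
    cf <- if (fit_free_tau) comp_curve(exp(theta[5])) else cf_fixed
    curve <- a1 * cf + (1 - a1) * comp_curve(tb)
    poisson_nll(y, amp * curve / sum(curve) + bg)
  }

  run_optim <- function(start) {
    lower <- c(qlogis(0.001), log(0.5), log(1), log(1e-8))
    upper <- c(qlogis(0.999), log(6.0), log(1e12), log(max(max(y), 1) * 2))
    if (fit_free_tau) {
      lower <- c(lower, log(0.05)); upper <- c(upper, log(6.0))
    }
    tryCatch(
      optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) list(convergence = 99L, par = start, value = nll(start))
    )
  }

  bg0 <- max(min(y), 0.01)
  start <- c(qlogis(0.7), log(2.5), log(max(h$n_photons, 1)), log(bg0))
  if (fit_free_tau) start <- c(start, log(0.4))
  opt <- run_optim(start)

  if (opt$convergence != 0L) {
    coarse <- fit_gridsearch_oracle(h, fix_tau_free = tau_f0,
                                    a1_step = 0.05, tau_step = 0.1,
                                    background = bg0)
    start2 <- c(qlogis(min(max(coarse$a1, 0.001), 0.999)),
                log(coarse$tau_bound), log(max(h$n_photons, 1)), log(bg0))
    if (fit_free_tau) start2 <- c(start2, log(0.4))
    opt2 <- run_optim(start2)
    if (opt2$value <= opt$value) opt <- opt2
  }

  a1 <- plogis(opt$par[1])
  tb <- exp(opt$par[2])
  amp <- exp(opt$par[3])
  bg <- exp(opt$par[4])
  tf <- if (fit_free_tau) exp(opt$par[5]) else tau_f0
  mu <- amp * model_decay_curve(a1, tf, tb, acq) + bg
  n_free <- if (fit_free_tau) 5L else 4L
  new_fit_result(
    a1 = a1, tau_free = tf, tau_bound = tb, amplitude = amp, background = bg,
    chi2_reduced = pearson_chi2(y, mu, n_free),
    converged = opt$convergence == 0L,
    n_photons = h$n_photons, acq = acq,
    tau_free_fixed = !fit_free_tau, loglik = -opt$value
  )
}

#' Exhaustive grid-search fit (verification oracle)
#'
#' Transparent brute-force maximizer of the Poisson log-likelihood over a
#' regular grid `a1 in {0, a1_step, ..., 1}` x `tau_bound in {0.5, ...,
#' 6.0}` ns, with the signal amplitude profiled analytically at each grid
#' point (for a unit-normalized curve and known background, the Poisson MLE
#' of the amplitude is the total count minus the expected background). Slow
#' but with no optimizer machinery; used to cross-check
#' [fit_biexponential()].
#'
#' @inheritParams fit_biexponential
#' @param fix_tau_free Free lifetime in ns (always fixed for the oracle).
#' @param a1_step,tau_step Grid resolutions for `a1` and `tau_bound` (ns).
#' @param background Known per-bin background mean (not estimated; default 0).
#' @return A `flim_fit` at the best grid point.
#' @export
fit_gridsearch_oracle <- function(h, fix_tau_free = 0.4, a1_step = 0.01,
                                  tau_step = 0.02, background = 0,
                                  min_photons = 500) {
  stopifnot(inherits(h, "decay_histogram"))
  if (h$n_photons < min_photons) {
    abort("Too few photons for the grid-search oracle.",
          class = "flimredox_low_photon_error")
  }
  check_number(fix_tau_free, "fix_tau_free", lower = 1e-3)
  acq <- h$acq
  y <- h$counts
  a1_grid <- seq(0, 1, by = a1_step)
  tb_grid <- seq(0.5, 6.0, by = tau_step)
  amp <- max(h$n_photons - background * acq$n_bins, 1)
  cf <- as.numeric(model_decay_curve(1, fix_tau_free, fix_tau_free, acq))
  # area-normalized curves for each candidate tau_bound, one column each
  cb <- vapply(tb_grid,
               function(tb) as.numeric(model_decay_curve(0, fix_tau_free, tb, acq)),
               numeric(acq$n_bins))
  best <- list(val = -Inf, a1 = NA_real_, tb = NA_real_)
  for (i in seq_along(a1_grid)) {
    a1 <- a1_grid[i]
    # a1 is an amplitude fraction; the photon (area) fraction of the free
    # component is a1*tau_free / (a1*tau_free + a2*tau_bound)
    w1 <- a1 * fix_tau_free / (a1 * fix_tau_free + (1 - a1) * tb_grid)
    mu <- amp * (outer(cf, w1) + sweep(cb, 2, 1 - w1, "*")) + background
    mu <- pmax(mu, 1e-12)
    ll <- colSums(y * log(mu) - mu)
    j <- which.max(ll)
    if (ll[j] > best$val) best <- list(val = ll[j], a1 = a1, tb = tb_grid[j])
  }
  mu_best <- amp *
    as.numeric(model_decay_curve(best$a1, fix_tau_free, best$tb, acq)) +
    background
  new_fit_result(
    a1 = best$a1, tau_free = fix_tau_free, tau_bound = best$tb,
    amplitude = amp, background = background,
    chi2_reduced = pearson_chi2(y, mu_best, 2L),
    converged = TRUE, n_photons = h$n_photons, acq = acq,
    tau_free_fixed = TRUE, loglik = best$val
  )
}

#' Poisson log-likelihood of a parameter pair for a histogram
#'
#' Convenience for comparing candidate parameters against an optimum (the
#' amplitude is profiled the same way as in [fit_gridsearch_oracle()]).
#'
#' @inheritParams fit_gridsearch_oracle
#' @param a1,tau_bound Candidate parameters.
#' @return The Poisson log-likelihood (data-constant omitted).
#' @export
decay_loglik <- function(h, a1, tau_bound, fix_tau_free = 0.4, background = 0) {
  stopifnot(inherits(h, "decay_histogram"))
  amp <- max(h$n_photons - background * h$acq$n_bins, 1)
  mu <- pmax(amp * model_decay_curve(a1, fix_tau_free, tau_bound, h$acq) +
               background, 1e-12)
  sum(h$counts * log(mu) - mu)
}
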