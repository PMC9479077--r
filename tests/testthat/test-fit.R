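test_that("noiseless histograms are recovered to high precision", {
  acq <- default_acq()
  curve <- model_decay_curve(km_params$a1, km_params$tau_free,
                             km_params$tau_bound, acq)
  h <- decay_histogram(as.numeric(curve) * 5e4, acq)
  fit <- fit_biexponential(h, fix_tau_free = 0.4)
  expect_true(fit$converged)
  expect_lt(abs(fit$a1 - km_params$a1), 1e-3)
  expect_lt(abs(fit$tau_bound - km_params$tau_bound), 5e-3)
  expect_equal(round(fit$tau_mean, 2), 1.21)
  expect_equal(fit$a1 + fit$a2, 1, tolerance = 1e-9)
  expect_equal(fit$tau_mean,
               fit$a1 * fit$tau_free + fit$a2 * fit$tau_bound)
})

test_that("mono-exponential input yields a vanishing bound fraction", {
  h <- simulate_histogram(model_decay_curve(1, 0.4, 3.0), 1e5, seed = 8)
  fit <- fit_biexponential(h, fix_tau_free = 0.4)
  expect_lte(fit$a2, 0.02)
  expect_lt(abs(fit$tau_mean - 0.4), 0.02)
})

test_that("low-photon histograms are rejected explicitly", {
  h <- simulate_histogram(model_decay_curve(0.7, 0.4, 3.0), 200, seed = 1)
  expect_error(fit_biexponential(h), class = "flimredox_low_photon_error")
  expect_error(fit_gridsearch_oracle(h), class = "flimredox_low_photon_error")
})

test_that("MLE and grid-search oracle agree within the grid resolution", {
  set.seed(5)
  cases <- expand.grid(a1 = c(0.55, 0.69, 0.85), tb = c(2.0, 3.0))
  for (i in seq_len(nrow(cases))) {
    curve <- model_decay_curve(cases$a1[i], 0.4, cases$tb[i])
    h <- simulate_histogram(curve, 5e4, seed = 100 + i)
    f <- fit_biexponential(h, fix_tau_free = 0.4)
    g <- fit_gridsearch_oracle(h, fix_tau_free = 0.4)
    expect_lt(abs(f$tau_mean - g$tau_mean), 0.02)
  }
})

test_that("the oracle is an argmax and pins exact grid points at high counts", {
  acq <- default_acq()
  curve <- model_decay_curve(0.70, 0.4, 3.00, acq)
  h <- simulate_histogram(curve, 2e6, seed = 17)
  g <- fit_gridsearch_oracle(h, fix_tau_free = 0.4)
  expect_equal(g$a1, 0.70)
  expect_equal(g$tau_bound, 3.00)
  # log-likelihood at the optimum beats off-optimum parameter pairs
  for (off in list(c(0.6, 3.0), c(0.7, 2.5), c(0.75, 3.2))) {
    expect_gte(g$loglik, decay_loglik(h, off[1], off[2]))
  }
})

test_that("parameter recovery is unbiased at the default photon budget", {
  preset <- species_preset("kmarxianus")
  sim <- simulate_roi_histograms(preset, 100, seed = 31)
  fits <- lapply(sim$histograms, fit_biexponential)
  tm_err <- vapply(fits, function(f) f$tau_mean, numeric(1)) -
    sim$truth$tau_mean
  a1_err <- vapply(fits, function(f) f$a1, numeric(1)) - sim$truth$a1
  expect_lte(median(abs(tm_err)), 0.03)
  expect_lte(abs(mean(a1_err)), 0.02)
})

test_that("fitted tau_mean increases with the true bound fraction", {
  acq <- default_acq()
  a2_ladder <- seq(0.1, 0.9, by = 0.2)
  fitted <- vapply(a2_ladder, function(a2) {
    curve <- model_decay_curve(1 - a2, 0.4, 3.0, acq)
    h <- decay_histogram(as.numeric(curve) * 1e5, acq)
    fit_biexponential(h, fix_tau_free = 0.4)$tau_mean
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("components are reported in canonical (short, long) order", {
  # generate with labels swapped; a free-lifetime fit must still report
  # component 1 as the shorter lifetime
  curve <- model_decay_curve(0.31, 3.02, 0.4)
  h <- simulate_histogram(curve, 2e5, seed = 12)
  fit <- fit_biexponential(h, fix_tau_free = NULL)
  expect_lte(fit$tau_free, fit$tau_bound)
  expect_lt(abs(fit$tau_mean - tau_mean_identity(0.69, 0.4, 3.02)), 0.05)
})

test_that("tidy and glance expose the fit in tabular form", {
  fit <- fit_biexponential(km_histogram(seed = 2))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term,
                  c("a1", "a2", "tau_free", "tau_bound", "tau_mean",
                    "background"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_gte(gl$chi2_reduced, 0)
})
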