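test_that("histogram simulation obeys the Poisson budget and determinism", {
  curve <- model_decay_curve(0.69, 0.4, 3.02)

  h0 <- simulate_histogram(curve, 0, background = 0, seed = 1)
  expect_true(all(h0$counts == 0))

  # empirical mean of totals over replicates within 3 SE of the budget
  n_rep <- 1000
  n_phot <- 2000
  bg <- 0.5
  acq <- attr(curve, "acq")
  expected <- n_phot + bg * acq$n_bins
  totals <- vapply(seq_len(n_rep), function(i) {
    simulate_histogram(curve, n_phot, background = bg, seed = 1e5 + i)$n_photons
  }, numeric(1))
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(totals) - expected), 3 * se)

  h1 <- simulate_histogram(curve, 5e4, background = 2, seed = 42)
  h2 <- simulate_histogram(curve, 5e4, background = 2, seed = 42)
  expect_identical(h1$counts, h2$counts)
  expect_equal(h1$n_photons, sum(h1$counts))

  expect_error(simulate_histogram(curve, -10), class = "flimredox_parameter_error")
})

test_that("field simulation conserves photons and ground-truth convexity", {
  preset <- species_preset("kmarxianus")
  layout <- field_layout(n_cells = 10)
  sim <- simulate_field(preset, layout, seed = 7)

  expect_equal(nrow(sim$truth), 10)
  # every true tau_mean is a convex combination of its two lifetimes
  lo <- pmin(preset$tau_free, sim$truth$tau_bound_true)
  hi <- pmax(preset$tau_free, sim$truth$tau_bound_true)
  expect_true(all(sim$truth$tau_mean_true >= lo - 1e-12 &
                    sim$truth$tau_mean_true <= hi + 1e-12))
  expect_equal(sim$truth$tau_mean_true,
               tau_mean_identity(sim$truth$a1_true, preset$tau_free,
                                 sim$truth$tau_bound_true))

  # photon conservation within 3 SE of signal + background budget
  acq <- acquisition_config()
  n_px <- prod(layout$image_shape)
  budget <- 10 * preset$photons_per_cell +
    acq$background_rate * acq$n_bins * n_px
  expect_lt(abs(sum(sim$stack$counts) - budget), 3 * sqrt(budget))

  # determinism: identical inputs give identical stacks
  sim2 <- simulate_field(preset, layout, seed = 7)
  expect_identical(sim$stack$counts, sim2$stack$counts)
  expect_identical(sim$truth, sim2$truth)
})

test_that("empty and infeasible layouts are handled", {
  sim <- simulate_field(species_preset("kmarxianus"),
                        field_layout(n_cells = 0), seed = 1)
  expect_equal(nrow(sim$truth), 0)
  acq <- acquisition_config()
  expect_lt(sum(sim$stack$counts),
            2 * acq$background_rate * acq$n_bins * 128^2)

  crowded <- field_layout(image_shape = c(48L, 48L), n_cells = 40,
                          cell_radius_range = c(8, 9), max_attempts = 30)
  expect_error(simulate_field(species_preset("kmarxianus"), crowded, seed = 1),
               class = "flimredox_placement_error")
})

test_that("species presets reproduce the published summaries through the identity", {
  km <- species_preset("kmarxianus")
  sc <- species_preset("scerevisiae")
  expect_equal(round(km$a1_mean, 3), 0.690)
  expect_equal(sc$tau_free, 0.4)
  # round-trip: preset parameters must reproduce the printed tau-mean and
  # a1/a2 to 2 decimal places
  expect_equal(round(tau_mean_identity(km$a1_mean, km$tau_free,
                                       km$tau_bound_mean), 2), 1.21)
  expect_equal(round(tau_mean_identity(sc$a1_mean, sc$tau_free,
                                       sc$tau_bound_mean), 2), 0.94)
  expect_equal(round(km$a1_mean / (1 - km$a1_mean), 2), 2.23)
  expect_equal(round(sc$a1_mean / (1 - sc$a1_mean), 2), 3.40)

  for (nm in c("km_30C", "km_45C", "km_control", "km_h2o2")) {
    p <- species_preset(nm)
    expect_s3_class(p, "cell_preset")
    expect_false(is.null(p$tau_mean_target))
  }
  expect_error(species_preset("ecoli"), class = "flimredox_lookup_error")
})

test_that("target-lifetime presets generate the requested tau_mean distribution", {
  p <- species_preset("km_45C")
  set.seed(11)
  draws <- flimredox:::draw_cell_params(p, 4000)
  expect_equal(mean(draws$tau_mean), 1.10, tolerance = 0.01)
  expect_equal(sd(draws$tau_mean), 0.09, tolerance = 0.01)
})

test_that("stacks survive a TIFF + JSON round trip", {
  sim <- simulate_field(species_preset("scerevisiae"),
                        field_layout(image_shape = c(64L, 64L), n_cells = 3),
                        seed = 3)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_flim_stack(sim$stack, path)
  expect_true(file.exists(sub("\\.tif$", ".json", path)))
  back <- read_flim_stack(path)
  expect_identical(back$counts, sim$stack$counts)
  expect_equal(back$acq$n_bins, sim$stack$acq$n_bins)
  expect_equal(back$seed, 3L)
})
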