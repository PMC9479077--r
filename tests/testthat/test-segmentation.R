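test_that("well-separated cells are all recovered with matching centroids", {
  sim <- simulate_field(species_preset("kmarxianus"),
                        field_layout(n_cells = 20), seed = 5)
  seg <- segment_cells(sim$stack)
  expect_equal(nrow(seg$cells), 20)
  d <- vapply(seq_len(nrow(seg$cells)), function(i) {
    min(sqrt((sim$truth$cy - seg$cells$cy[i])^2 +
               (sim$truth$cx - seg$cells$cx[i])^2))
  }, numeric(1))
  expect_true(all(d < 2))
  # one-to-one: nearest-truth assignment is a permutation
  nearest <- vapply(seq_len(nrow(seg$cells)), function(i) {
    which.min((sim$truth$cy - seg$cells$cy[i])^2 +
                (sim$truth$cx - seg$cells$cx[i])^2)
  }, integer(1))
  expect_equal(sort(nearest), seq_len(20))
})

test_that("segmentation recovery holds across replicate fields", {
  found <- 0L; total <- 0L
  for (sd in c(101, 202, 303)) {
    sim <- simulate_field(species_preset("scerevisiae"),
                          field_layout(n_cells = 15), seed = sd)
    seg <- segment_cells(sim$stack)
    found <- found + nrow(seg$cells)
    total <- total + 15L
  }
  expect_gte(found / total, 0.95)
})

test_that("blank fields segment to nothing", {
  acq <- acquisition_config(background_rate = 0)
  sim <- simulate_field(species_preset("kmarxianus"),
                        field_layout(n_cells = 0), acq = acq, seed = 1)
  seg <- segment_cells(sim$stack)
  expect_equal(nrow(seg$cells), 0)
  expect_true(all(seg$labels == 0))
})

test_that("touching blobs merge into one component (documented limitation)", {
  # synthetic stack with two bright rectangles sharing a corner
  acq <- acquisition_config(n_bins = 4L, bin_width = 50, background_rate = 0)
  counts <- array(0L, dim = c(4, 40, 40))
  counts[, 5:14, 5:14] <- 100L
  counts[, 15:24, 15:24] <- 100L
  stack <- structure(list(counts = counts, acq = acq, seed = 1L),
                     class = "flim_stack")
  seg <- segment_cells(stack, min_area = 10)
  expect_equal(nrow(seg$cells), 1)
  expect_equal(seg$cells$area, 200L)
})

test_that("ROI pooling is additive and conserves counts", {
  sim <- simulate_field(species_preset("kmarxianus"),
                        field_layout(image_shape = c(64L, 64L), n_cells = 3),
                        seed = 9)
  stack <- sim$stack
  d <- dim(stack$counts)

  # single pixel: unchanged histogram
  px <- which(intensity_image(stack) == max(intensity_image(stack)))[1]
  h1 <- pool_roi_histogram(stack, px)
  expect_equal(h1$counts, as.numeric(stack$counts[, (px - 1) %% d[2] + 1,
                                                  (px - 1) %/% d[2] + 1]))

  # whole image equals the per-bin totals
  all_mask <- matrix(TRUE, d[2], d[3])
  h_all <- pool_roi_histogram(stack, all_mask)
  expect_equal(h_all$counts, as.numeric(apply(stack$counts, 1, sum)))

  # random disjoint masks: pool(A union B) = pool(A) + pool(B)
  set.seed(4)
  for (i in 1:5) {
    pix <- sample(d[2] * d[3], 400)
    a <- pix[1:150]; b <- pix[151:400]
    expect_equal(pool_roi_histogram(stack, c(a, b))$counts,
                 pool_roi_histogram(stack, a)$counts +
                   pool_roi_histogram(stack, b)$counts)
  }

  expect_error(pool_roi_histogram(stack, integer(0)),
               class = "flimredox_empty_roi_error")
})

test_that("lifetime maps clamp, interpolate linearly, and reject bad ranges", {
  labels <- matrix(0L, 10, 10)
  labels[2:3, 2:3] <- 1L; labels[6:7, 6:7] <- 2L; labels[2:3, 6:7] <- 3L
  cells <- tibble::tibble(cell_id = 1:3, tau_mean = c(1.0, 2.75, 5.0))
  img <- render_lifetime_map(cells, labels, lut_range = c(1.5, 4.0))
  lut <- lifetime_lut()
  # below range: minimum color; above range: maximum color
  expect_equal(img[2, 2, ], unname(lut[, 1]))
  expect_equal(img[2, 6, ], unname(lut[, 256]))
  # midpoint of the range maps to the midpoint LUT entry
  expect_equal(img[6, 6, ], unname(lut[, 1 + round(0.5 * 255)]))
  # background stays black
  expect_equal(img[1, 1, ], c(0, 0, 0))
  # equal lifetimes get identical colors
  expect_equal(lifetime_color(c(2.2, 2.2)),
               lifetime_color(c(2.2, 2.2))[c(1, 1), , drop = FALSE])
  expect_error(render_lifetime_map(cells, labels, lut_range = c(4, 1.5)),
               class = "flimredox_parameter_error")
})

test_that("per-cell fits recover the simulated ground truth", {
  sim <- simulate_field(species_preset("kmarxianus"),
                        field_layout(n_cells = 12), seed = 21)
  seg <- segment_cells(sim$stack)
  cells <- fit_cells(sim$stack, seg)
  expect_equal(nrow(cells), 12)
  expect_true(all(cells$converged))
  # match each fitted cell to its nearest true cell and compare tau_mean
  for (i in seq_len(nrow(cells))) {
    j <- which.min((sim$truth$cy - cells$cy[i])^2 +
                     (sim$truth$cx - cells$cx[i])^2)
    expect_lt(abs(cells$tau_mean[i] - sim$truth$tau_mean_true[j]), 0.1)
  }
})
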