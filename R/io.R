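# On-disk formats: multi-page TIFF stacks with JSON sidecars, CSV tables.

#' Write a FLIM stack to disk
#'
#' Writes the stack as a multi-page 16-bit TIFF (page k = time bin k) plus a
#' JSON sidecar (same path with extension `.json`) holding the acquisition
#' settings and the simulation seed.
#'
#' @param stack A `flim_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  if (max(stack$counts) > 65535) {
    warn("Counts above 65535 were clamped for 16-bit TIFF storage.")
  }
  pages <- lapply(seq_len(d[1]), function(b) {
    pmin(matrix(stack$counts[b, , ], d[2], d[3]), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    acq = stack$acq[c("n_bins", "bin_width", "period", "irf_center",
                      "irf_fwhm", "background_rate")],
    seed = stack$seed
  )
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path, ignore.case = TRUE),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FLIM stack written by [write_flim_stack()]
#'
#' @param path TIFF path; the JSON sidecar is located by extension.
#' @return A `flim_stack`.
#' @export
read_flim_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (!file.exists(meta_path)) {
    abort(sprintf("Metadata sidecar not found: %s", meta_path),
          class = "flimredox_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  acq <- as_acquisition_config(meta$acq)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  counts <- array(0L, dim = c(length(pages), h, w))
  for (b in seq_along(pages)) {
    counts[b, , ] <- as.integer(round(pages[[b]] * 65535))
  }
  structure(list(counts = counts, acq = acq,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_),
            class = "flim_stack")
}

#' Write the simulation ground-truth table
#'
#' One row per generated cell with lifetimes rounded to 4 decimal places
#' (ns): `cell_id, cy, cx, a1_true, tau_bound_true, tau_mean_true`.
#'
#' @param truth Ground-truth tibble from [simulate_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- tibble(
    cell_id = truth$cell_id,
    cy = round(truth$cy, 2),
    cx = round(truth$cx, 2),
    a1_true = round(truth$a1_true, 4),
    tau_bound_true = round(truth$tau_bound_true, 4),
    tau_mean_true = round(truth$tau_mean_true, 4)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a per-cell fit table
#'
#' @param cells Per-cell tibble from [fit_cells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  out <- tibble(
    roi_id = cells$cell_id,
    n_photons = cells$n_photons,
    a1 = round(cells$a1, 5),
    a2 = round(cells$a2, 5),
    tau_free_ns = round(cells$tau_free, 5),
    tau_bound_ns = round(cells$tau_bound, 5),
    tau_mean_ns = round(cells$tau_mean, 5),
    chi2_reduced = round(cells$chi2_reduced, 4),
    converged = cells$converged
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels Integer label matrix (0 = background) or a
#'   `flim_segmentation`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  if (inherits(labels, "flim_segmentation")) labels <- labels$labels
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
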