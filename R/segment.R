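# Cell segmentation and per-ROI pooling.

# 8-connected component labelling by iterative minimum-label propagation.
# Deterministic; adequate for fields of compact cells. (EBImage's bwlabel is
# 4-connected, hence this small routine.)
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)          # unique provisional labels
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    old <- lab
    for (sft in shifts) {
      dy <- sft[1]; dx <- sft[2]
      ys <- max(1, 1 + dy):min(h, h + dy)
      xs <- max(1, 1 + dx):min(w, w + dx)
      sub <- lab[ys - dy, xs - dx, drop = FALSE]
      lab[ys, xs] <- pmin(lab[ys, xs], sub)
      lab[!mask] <- Inf   # labels must never propagate through background
    }
    if (identical(old, lab)) break
  }
  out <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg)) {
    provisional <- lab[fg]
    # relabel 1..K in raster order (row-major) of each component's first pixel
    rows <- (fg - 1L) %% h + 1L
    cols <- (fg - 1L) %/% h + 1L
    raster <- (rows - 1L) * w + cols
    first <- tapply(raster, provisional, min)
    ord <- names(sort(first))
    out[fg] <- match(as.character(provisional), ord)
  }
  out
}

#' Segment cells in a FLIM stack
#'
#' Builds the total-intensity image (photon counts summed over time bins),
#' thresholds it with Otsu's method, labels 8-connected foreground
#' components, and discards components outside `[min_area, max_area]` pixels
#' or touching the image border. Labels are assigned deterministically in
#' raster order of each component's first pixel. Touching cells merge into a
#' single component (no watershed splitting); that is a documented
#' limitation.
#'
#' @param stack A `flim_stack` from [simulate_field()] or
#'   [read_flim_stack()].
#' @param min_area,max_area Area gate in pixels.
#' @return An object of class `flim_segmentation`: list with `labels`
#'   (integer label matrix, 0 = background) and `cells`, a tibble with one
#'   row per retained component (`cell_id`, `cy`, `cx`, `area`).
#' @examples
#' sim <- simulate_field(species_preset("kmarxianus"),
#'                       field_layout(n_cells = 4), seed = 2)
#' seg <- segment_cells(sim$stack)
#' seg$cells
#' @export
segment_cells <- function(stack, min_area = 30, max_area = 5000) {
  stopifnot(inherits(stack, "flim_stack"))
  img <- intensity_image(stack)
  mx <- max(img)
  if (mx <= 0) {
    return(structure(
      list(labels = matrix(0L, nrow(img), ncol(img)),
           cells = tibble(cell_id = integer(), cy = numeric(),
                          cx = numeric(), area = integer())),
      class = "flim_segmentation"
    ))
  }
  thr <- EBImage::otsu(img / mx, range = c(0, 1))
  mask <- img / mx > thr
  # Otsu always splits, even a pure-noise background image; demand real
  # foreground/background contrast before accepting the split
  if (!any(mask) || all(mask) ||
      mean(img[mask]) < 3 * mean(img[!mask]) + 1) {
    return(structure(
      list(labels = matrix(0L, nrow(img), ncol(img)),
           cells = tibble(cell_id = integer(), cy = numeric(),
                          cx = numeric(), area = integer())),
      class = "flim_segmentation"
    ))
  }
  lab <- label_components8(mask)
  k <- max(lab)
  keep <- integer(0)
  if (k > 0) {
    h <- nrow(lab); w <- ncol(lab)
    border_ids <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
    areas <- tabulate(lab[lab > 0], nbins = k)
    keep <- which(areas >= min_area & areas <= max_area &
                    !(seq_len(k) %in% border_ids))
  }
  relab <- matrix(0L, nrow(lab), ncol(lab))
  cells <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    px <- which(lab == keep[i])
    relab[px] <- i
    rows <- (px - 1L) %% nrow(lab) + 1L
    cols <- (px - 1L) %/% nrow(lab) + 1L
    cells[[i]] <- tibble(cell_id = i, cy = mean(rows), cx = mean(cols),
                         area = length(px))
  }
  structure(
    list(labels = relab,
         cells = if (length(keep)) bind_rows(cells) else
           tibble(cell_id = integer(), cy = numeric(), cx = numeric(),
                  area = integer())),
    class = "flim_segmentation"
  )
}

#' @export
print.flim_segmentation <- function(x, ...) {
  cat(sprintf("<flim_segmentation> %d cells retained\n", nrow(x$cells)))
  invisible(x)
}

#' Pool the decay histogram of a region of interest
#'
#' Sums per-bin counts over the masked pixels, giving the single pooled
#' histogram that is fitted per cell. Pooling is additive: disjoint masks sum
#' bin-wise.
#'
#' @param stack A `flim_stack`.
#' @param mask Either a logical matrix of the stack's spatial shape, an
#'   integer vector of pixel indices (column-major into the spatial plane),
#'   or a `flim_segmentation` together with `cell_id`.
#' @param cell_id When `mask` is a segmentation, the label to pool.
#' @return A [decay_histogram()].
#' @export
pool_roi_histogram <- function(stack, mask, cell_id = NULL) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  if (inherits(mask, "flim_segmentation")) {
    if (is.null(cell_id)) {
      abort("Supply `cell_id` when pooling from a segmentation.",
            class = "flimredox_parameter_error")
    }
    idx <- which(mask$labels == cell_id)
  } else if (is.logical(mask)) {
    if (!identical(dim(mask), d[2:3])) {
      abort("Logical mask shape must match the stack's spatial shape.",
            class = "flimredox_parameter_error")
    }
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  if (length(idx) == 0) {
    abort("Empty ROI mask.", class = "flimredox_empty_roi_error")
  }
  flat <- matrix(stack$counts, nrow = d[1])
  counts <- if (length(idx) == 1L) flat[, idx] else rowSums(flat[, idx])
  decay_histogram(counts, stack$acq)
}

#' Segment, pool and fit every cell in a stack
#'
#' Pipeline convenience: runs [pool_roi_histogram()] and
#' [fit_biexponential()] for each retained cell of a segmentation and returns
#' the per-cell table that downstream group statistics consume.
#'
#' @param stack A `flim_stack`.
#' @param seg A `flim_segmentation`; segmented from `stack` if omitted.
#' @param fix_tau_free Free lifetime held fixed during fitting (ns);
#'   `NULL` frees it.
#' @param min_photons Cells whose pooled histograms fall below this photon
#'   count are dropped with a warning rather than fitted.
#' @return A tibble with one row per fitted cell: `cell_id, cy, cx, area,
#'   n_photons, a1, a2, tau_free, tau_bound, tau_mean, chi2_reduced,
#'   converged`.
#' @export
fit_cells <- function(stack, seg = NULL, fix_tau_free = 0.4,
                      min_photons = 500) {
  seg <- seg %||% segment_cells(stack)
  stopifnot(inherits(seg, "flim_segmentation"))
  rows <- vector("list", nrow(seg$cells))
  dropped <- 0L
  for (i in seq_len(nrow(seg$cells))) {
    id <- seg$cells$cell_id[i]
    h <- pool_roi_histogram(stack, seg, cell_id = id)
    if (h$n_photons < min_photons) {
      dropped <- dropped + 1L
      next
    }
    f <- fit_biexponential(h, fix_tau_free = fix_tau_free,
                           min_photons = min_photons)
    rows[[i]] <- tibble(
      cell_id = id, cy = seg$cells$cy[i], cx = seg$cells$cx[i],
      area = seg$cells$area[i], n_photons = f$n_photons,
      a1 = f$a1, a2 = f$a2, tau_free = f$tau_free, tau_bound = f$tau_bound,
      tau_mean = f$tau_mean, chi2_reduced = f$chi2_reduced,
      converged = f$converged
    )
  }
  if (dropped > 0) {
    warn(sprintf("%d cell(s) below the %g-photon floor were not fitted.",
                 dropped, min_photons))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(cell_id = integer(), cy = numeric(), cx = numeric(),
                  area = integer(), n_photons = numeric(), a1 = numeric(),
                  a2 = numeric(), tau_free = numeric(), tau_bound = numeric(),
                  tau_mean = numeric(), chi2_reduced = numeric(),
                  converged = logical()))
  }
  bind_rows(rows)
}
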