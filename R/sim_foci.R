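#' Simulate a two-channel fluorescent-focus field with ground truth
#'
#' Generates the input expected by the focus-distance pipeline: per-cell
#' GFP/CFP focus pairs whose separations are drawn from a log-normal law
#' parameterized by its median (strictly positive and heavy-tailed, like the
#' violin-shaped distance distributions this emulates), placed in
#' non-overlapping rectangular "cells" on a sparse monolayer grid, and
#' optionally rendered as a pair of noisy Gaussian-spot images. The exact
#' drawn coordinates and nm distances are returned as ground truth.
#'
#' The tile (cell) size adapts to the largest drawn offset so no separation is
#' censored by a cell boundary: the truth median is exactly the empirical
#' median of the drawn log-normal sample.
#'
#' @param n_cells Number of cells (>= 0).
#' @param median_nm Median pair separation in nm (134 for clustered loci;
#'   566 emulates the de-clustered state).
#' @param spread Log-scale spread (`sdlog`) of the log-normal distance law
#'   (default 0.5).
#' @param pairs_per_cell 1 or 2 focus pairs per cell (2 emulates cells whose
#'   tagged region is already replicated). Default 1.
#' @param pixel_nm Pixel size in nm (default 62).
#' @param psf_sigma_px Gaussian spot sigma in pixels (default 1.3, a
#'   diffraction-limited spot at this pixel size).
#' @param peak_intensity Spot peak amplitude above background (default 300).
#' @param background_level,noise_sd Image background mean and Gaussian noise
#'   SD (defaults 100 and 10).
#' @param render Also render the two channel images (default `FALSE`;
#'   coordinate tables are always returned).
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with elements `foci` (tibble: `cell`, `pair`, `channel`,
#'   `x_px`, `y_px`), `truth` (tibble: `cell`, `pair`, `distance_nm`),
#'   `pixel_nm`, and when `render = TRUE` the matrices `gfp_image` and
#'   `cfp_image` plus `image_shape`.
#' @export
simulate_foci_field <- function(n_cells,
                                median_nm = 134,
                                spread = 0.5,
                                pairs_per_cell = 1L,
                                pixel_nm = 62,
                                psf_sigma_px = 1.3,
                                peak_intensity = 300,
                                background_level = 100,
                                noise_sd = 10,
                                render = FALSE,
                                seed = 1L) {
  stopifnot(n_cells >= 0, median_nm > 0, spread > 0, pixel_nm > 0,
            pairs_per_cell %in% c(1L, 2L))
  if (psf_sigma_px <= 0) stop("`psf_sigma_px` must be > 0", call. = FALSE)
  empty <- list(
    foci = tibble::tibble(cell = integer(), pair = integer(),
                          channel = character(), x_px = numeric(), y_px = numeric()),
    truth = tibble::tibble(cell = integer(), pair = integer(),
                           distance_nm = numeric()),
    pixel_nm = pixel_nm
  )
  if (n_cells == 0L) return(empty)
  withr::local_seed(seed)

  n_pairs <- n_cells * pairs_per_cell
  d_nm <- stats::rlnorm(n_pairs, meanlog = log(median_nm), sdlog = spread)
  d_px <- d_nm / pixel_nm
  theta <- stats::runif(n_pairs, 0, 2 * pi)
  off_x <- d_px * cos(theta)
  off_y <- d_px * sin(theta)

  # tile large enough that GFP + offset (and the PSF skirt) always fits
  margin <- ceiling(4 * psf_sigma_px) + 2
  reach <- ceiling(max(abs(c(off_x, off_y)), 1))
  tile <- max(32, 2 * (reach + margin) + 8)
  ncol_tiles <- ceiling(sqrt(n_cells))
  nrow_tiles <- ceiling(n_cells / ncol_tiles)

  cell <- rep(seq_len(n_cells), each = pairs_per_cell)
  pair <- rep(seq_len(pairs_per_cell), times = n_cells)
  tile_ix <- (cell - 1L) %% ncol_tiles
  tile_iy <- (cell - 1L) %/% ncol_tiles
  # GFP jittered around the tile centre; for two pairs, offset the anchors so
  # sister pairs start in different halves of the cell
  anchor_x <- tile_ix * tile + tile / 2 +
    ifelse(pairs_per_cell == 2L, (pair - 1.5) * (tile / 3), 0)
  anchor_y <- tile_iy * tile + tile / 2
  gfp_x <- anchor_x + stats::runif(n_pairs, -2, 2)
  gfp_y <- anchor_y + stats::runif(n_pairs, -2, 2)
  cfp_x <- gfp_x + off_x
  cfp_y <- gfp_y + off_y

  foci <- dplyr::bind_rows(
    tibble::tibble(cell = cell, pair = pair, channel = "GFP",
                   x_px = gfp_x, y_px = gfp_y),
    tibble::tibble(cell = cell, pair = pair, channel = "CFP",
                   x_px = cfp_x, y_px = cfp_y)
  )
  truth <- tibble::tibble(cell = cell, pair = pair, distance_nm = d_nm)
  out <- list(foci = foci, truth = truth, pixel_nm = pixel_nm)

  if (render) {
    shape <- c(ncol_tiles * tile, nrow_tiles * tile)
    out$gfp_image <- render_channel(gfp_x, gfp_y, shape, psf_sigma_px,
                                    peak_intensity, background_level, noise_sd)
    out$cfp_image <- render_channel(cfp_x, cfp_y, shape, psf_sigma_px,
                                    peak_intensity, background_level, noise_sd)
    out$image_shape <- shape
  }
  out
}

# additive Gaussian spots on a flat noisy background; values rounded to
# integers as a camera would quantize them
render_channel <- function(x, y, shape, sigma, amp, bg, noise_sd) {
  if (any(shape <= 0)) stop("non-positive image dimensions", call. = FALSE)
  img <- matrix(0, nrow = shape[1L], ncol = shape[2L])
  w <- ceiling(4 * sigma)
  for (k in seq_along(x)) {
    i0 <- max(1L, floor(x[k]) - w); i1 <- min(shape[1L], ceiling(x[k]) + w)
    j0 <- max(1L, floor(y[k]) - w); j1 <- min(shape[2L], ceiling(y[k]) + w)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    gx <- exp(-((ii - x[k])^2) / (2 * sigma^2))
    gy <- exp(-((jj - y[k])^2) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amp * outer(gx, gy)
  }
  img <- img + bg + matrix(stats::rnorm(length(img), 0, noise_sd),
                           nrow = shape[1L])
  img <- round(img)
  img[img < 0] <- 0
  img
}

#' Run the full distance pipeline on a simulated field
#'
#' Convenience wrapper chaining [detect_foci()] on both rendered channels (or
#' using the simulated coordinates directly when images were not rendered),
#' [match_pairs()], [to_nm()] and [summarize_distances()].
#'
#' @param field Output of [simulate_foci_field()].
#' @param config An [imaging_config()].
#' @return A list with `pairs` (nm `pair_distance_set`) and `summary`
#'   (one-row tibble).
#' @export
foci_pipeline <- function(field, config = imaging_config()) {
  if (!is.null(field$gfp_image)) {
    gfp <- detect_foci(field$gfp_image, config, channel = "GFP")
    cfp <- detect_foci(field$cfp_image, config, channel = "CFP")
  } else {
    gfp <- dplyr::filter(field$foci, .data$channel == "GFP")
    cfp <- dplyr::filter(field$foci, .data$channel == "CFP")
  }
  cfg <- config
  cfg$pixel_nm <- field$pixel_nm %||% config$pixel_nm
  pairs <- to_nm(match_pairs(gfp, cfp, cfg), cfg)
  list(pairs = pairs, summary = summarize_distances(pairs))
}
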