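#' Imaging configuration for focus detection and distance analysis
#'
#' Bundles the handful of parameters shared across the two-channel
#' focus-distance pipeline.
#'
#' @param pixel_nm Physical pixel size in nanometres (default 62, i.e.
#'   1 pixel = 62 nm on the acquisition setup emulated here).
#' @param maxima_prominence Minimum background-subtracted intensity for a
#'   local maximum to be called a focus. Exposure-dependent; tune per dataset.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels applied
#'   before maxima detection (default 1; 0 disables). Suppresses shot-noise
#'   maxima without displacing diffraction-limited peaks.
#' @param background_radius_px Radius (pixels) of the disc used for the
#'   rolling-background (grayscale opening) estimate.
#' @param subpixel Refine maxima to sub-pixel positions by intensity-weighted
#'   centroid in a 3x3 window (default `TRUE`).
#' @param fold_change_cutoff Fold change of median distance considered a
#'   biologically meaningful de-clustering call (default 2.5).
#' @param distance_cutoff_nm Optional absolute median-distance threshold (nm);
#'   when set, the de-clustering call uses `treatment median >= cutoff`
#'   instead of the fold rule. Default `NULL` (fold rule).
#' @param alpha Significance level reported alongside the Mann-Whitney test
#'   (default 0.001).
#' @param max_pair_distance_px Optional gate discarding GFP-CFP pairs farther
#'   apart than this many pixels (default `Inf`, i.e. off).
#'
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_nm = 62,
                           maxima_prominence = 25,
                           smooth_sigma_px = 1,
                           background_radius_px = 8L,
                           subpixel = TRUE,
                           fold_change_cutoff = 2.5,
                           distance_cutoff_nm = NULL,
                           alpha = 0.001,
                           max_pair_distance_px = Inf) {
  stopifnot(pixel_nm > 0, maxima_prominence >= 0, background_radius_px >= 1,
            fold_change_cutoff > 1, alpha > 0, alpha < 1)
  structure(
    list(pixel_nm = pixel_nm, maxima_prominence = maxima_prominence,
         smooth_sigma_px = smooth_sigma_px,
         background_radius_px = as.integer(background_radius_px),
         subpixel = isTRUE(subpixel),
         fold_change_cutoff = fold_change_cutoff,
         distance_cutoff_nm = distance_cutoff_nm,
         alpha = alpha, max_pair_distance_px = max_pair_distance_px),
    class = "imaging_config"
  )
}

# grayscale opening with an odd-diameter disc; background estimate that
# flattens features narrower than the disc (i.e. diffraction-limited foci)
rolling_background <- function(image, radius_px) {
  brush_size <- 2L * as.integer(radius_px) + 1L
  kern <- EBImage::makeBrush(brush_size, shape = "disc")
  # EBImage grayscale morphology expects intensities in [0, 1]
  s <- max(image, 1)
  EBImage::opening(image / s, kern) * s
}

max_filter3 <- function(image) {
  s <- max(image, 1)
  EBImage::dilate(image / s, EBImage::makeBrush(3L, shape = "box")) * s
}

#' Detect fluorescent foci in one channel
#'
#' Subtracts a rolling background (grayscale opening with a disc of radius
#' `background_radius_px`) and calls local maxima whose background-subtracted
#' intensity (prominence) exceeds `maxima_prominence`, in the spirit of
#' ImageJ's find-maxima tool. Maxima are plateau-safe (strictly greater than
#' at least one neighbour, not less than any) and optionally refined to
#' sub-pixel coordinates by the intensity-weighted centroid of the 3x3
#' neighbourhood.
#'
#' @param image Numeric matrix of non-negative finite intensities; the first
#'   index is interpreted as x, the second as y (both 1-based; the sub-pixel
#'   coordinates keep that convention).
#' @param config An [imaging_config()].
#' @param channel Channel label stored with the detections (e.g. `"GFP"`).
#' @param image_id Image identifier stored with the detections.
#'
#' @return A tibble sorted by decreasing intensity with columns `image_id`,
#'   `channel`, `x_px`, `y_px`, `intensity` (background-subtracted peak
#'   intensity).
#' @export
detect_foci <- function(image, config = imaging_config(), channel = "GFP",
                        image_id = "image") {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("`image` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  if (any(image < 0)) stop("image contains negative intensities", call. = FALSE)
  if (config$smooth_sigma_px > 0 && min(dim(image)) > 8L) {
    image <- EBImage::gblur(image, sigma = config$smooth_sigma_px)
  }
  bg <- rolling_background(image, config$background_radius_px)
  sub <- image - bg
  sub[sub < 0] <- 0
  # grayscale dilation with a 3x3 box = max filter over the 8-neighbourhood
  mx <- max_filter3(sub)
  tol <- 1e-9 * max(sub, 1)
  cand <- which(sub >= mx - tol & sub > config$maxima_prominence, arr.ind = TRUE)
  empty <- tibble::tibble(image_id = character(), channel = character(),
                          x_px = numeric(), y_px = numeric(), intensity = numeric())
  if (nrow(cand) == 0L) return(empty)
  # collapse plateaus: keep one representative per connected candidate clump
  if (nrow(cand) > 1L) {
    keep <- rep(TRUE, nrow(cand))
    ord <- order(cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand) - 1L)) {
      if (!keep[i]) next
      j <- i + 1L
      while (j <= nrow(cand) && cand[j, 1L] - cand[i, 1L] <= 1L) {
        if (abs(cand[j, 2L] - cand[i, 2L]) <= 1L) keep[j] <- FALSE
        j <- j + 1L
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  nr <- nrow(sub); nc <- ncol(sub)
  res <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    x <- as.numeric(i); y <- as.numeric(j)
    if (config$subpixel && i > 1L && i < nr && j > 1L && j < nc) {
      win <- sub[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      tot <- sum(win)
      if (tot > 0) {
        x <- sum(rep((i - 1L):(i + 1L), times = 3L) * win) / tot
        y <- sum(rep((j - 1L):(j + 1L), each = 3L) * win) / tot
      }
    }
    tibble::tibble(image_id = image_id, channel = channel,
                   x_px = x, y_px = y, intensity = sub[i, j])
  })
  dplyr::arrange(res, dplyr::desc(.data$intensity))
}

#' Pair each GFP focus with its closest CFP focus
#'
#' One-directional nearest-neighbour matching: for every focus in the first
#' (GFP) channel the focus in the second (CFP) channel minimizing the
#' Euclidean pixel distance is selected. A CFP focus may be the partner of
#' several GFP foci. Ties are broken deterministically by lowest CFP row
#' index. GFP foci with no CFP focus available (empty CFP channel, or all
#' partners beyond `max_pair_distance_px`) are counted as unmatched and
#' excluded from the distance set.
#'
#' @param gfp,cfp Focus tables (tibbles from [detect_foci()] or any data frame
#'   with `x_px`, `y_px` columns) for the two channels of the same image.
#' @param config An [imaging_config()]; only `max_pair_distance_px` is used.
#' @param mutual Require mutual nearest neighbours (off by default; the
#'   default mirrors the one-directional closest-CFP description).
#'
#' @return A tibble of class `pair_distance_set` with columns `gfp_x`,
#'   `gfp_y`, `cfp_x`, `cfp_y`, `distance_px`, and attributes `n_unmatched`
#'   and `unit` (`"px"`).
#' @export
match_pairs <- function(gfp, cfp, config = imaging_config(), mutual = FALSE) {
  need <- function(d) all(c("x_px", "y_px") %in% names(d))
  stopifnot(is.data.frame(gfp), is.data.frame(cfp), need(gfp) || nrow(gfp) == 0L,
            need(cfp) || nrow(cfp) == 0L)
  empty <- tibble::tibble(gfp_x = numeric(), gfp_y = numeric(),
                          cfp_x = numeric(), cfp_y = numeric(),
                          distance_px = numeric())
  if (nrow(gfp) == 0L) {
    return(new_pair_set(empty, n_unmatched = 0L, unit = "px"))
  }
  if (nrow(cfp) == 0L) {
    return(new_pair_set(empty, n_unmatched = nrow(gfp), unit = "px"))
  }
  dx <- outer(gfp$x_px, cfp$x_px, "-")
  dy <- outer(gfp$y_px, cfp$y_px, "-")
  d <- sqrt(dx^2 + dy^2)
  nn <- apply(d, 1L, which.min) # which.min breaks ties at the lowest index
  dist <- d[cbind(seq_len(nrow(gfp)), nn)]
  if (mutual) {
    nn_rev <- apply(d, 2L, which.min)
    ok <- nn_rev[nn] == seq_len(nrow(gfp))
  } else {
    ok <- rep(TRUE, nrow(gfp))
  }
  ok <- ok & dist <= config$max_pair_distance_px
  out <- tibble::tibble(
    gfp_x = gfp$x_px[ok], gfp_y = gfp$y_px[ok],
    cfp_x = cfp$x_px[nn][ok], cfp_y = cfp$y_px[nn][ok],
    distance_px = dist[ok]
  )
  new_pair_set(out, n_unmatched = sum(!ok), unit = "px")
}

new_pair_set <- function(df, n_unmatched, unit) {
  structure(df, n_unmatched = as.integer(n_unmatched), unit = unit,
            class = c("pair_distance_set", class(df)))
}

#' Convert pair distances from pixels to nanometres
#'
#' @param pairs A `pair_distance_set` from [match_pairs()] (pixel units).
#' @param config An [imaging_config()]; `pixel_nm` provides the scale
#'   (default 62 nm per pixel).
#'
#' @return The same table with a `distance_nm` column and unit attribute
#'   `"nm"`.
#' @export
to_nm <- function(pairs, config = imaging_config()) {
  stopifnot(is.data.frame(pairs), "distance_px" %in% names(pairs))
  if (config$pixel_nm <= 0) stop("`pixel_nm` must be > 0", call. = FALSE)
  out <- dplyr::mutate(tibble::as_tibble(pairs),
                       distance_nm = .data$distance_px * config$pixel_nm)
  new_pair_set(out, n_unmatched = attr(pairs, "n_unmatched") %||% 0L, unit = "nm")
}

#' Summarize a pair-distance distribution
#'
#' Median and quartiles of the nm distances, computed by linear interpolation
#' between order statistics (`stats::quantile(type = 7)`; the inclusive
#' convention).
#'
#' @param pairs A `pair_distance_set` carrying `distance_nm` (see [to_nm()]),
#'   or any data frame with a `distance_nm` column, or a bare numeric vector
#'   of nm distances.
#'
#' @return A one-row tibble with `n`, `median_nm`, `q1_nm`, `q3_nm`.
#' @export
summarize_distances <- function(pairs) {
  d <- if (is.data.frame(pairs)) {
    if (!"distance_nm" %in% names(pairs)) {
      stop("no `distance_nm` column; run to_nm() first", call. = FALSE)
    }
    pairs$distance_nm
  } else {
    as.numeric(pairs)
  }
  if (length(d) == 0L) stop("empty distance set", call. = FALSE)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(d), median_nm = q[2L], q1_nm = q[1L], q3_nm = q[3L])
}

#' Compare pair-distance distributions between two conditions
#'
#' The de-clustering decision used throughout the locus-pair analysis: the
#' fold change of median distances (treatment over control) together with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test. Because these
#' distributions typically hold hundreds of foci, even small median shifts
#' reach p < 0.001; the call therefore follows the fold-change rule
#' (default: fold >= 2.5), with the p-value reported alongside. An absolute
#' nm threshold on the treatment median can be used instead via
#' `distance_cutoff_nm` in the config.
#'
#' @param control,treatment nm distance sets (`pair_distance_set`, data frame
#'   with `distance_nm`, or numeric vector), both non-empty.
#' @param config An [imaging_config()].
#' @param labels Length-2 character vector of condition labels.
#'
#' @return An object of class `decluster_comparison`: a list with the two
#'   [summarize_distances()] rows, `fold_change`, `statistic` (Mann-Whitney
#'   U), `p_value`, and the logical `declustered` call. Has [tidy()] and
#'   [glance()] methods.
#' @export
compare_conditions <- function(control, treatment, config = imaging_config(),
                               labels = c("control", "treatment")) {
  pull_d <- function(x) {
    if (is.data.frame(x)) x$distance_nm else as.numeric(x)
  }
  dc <- pull_d(control); dt <- pull_d(treatment)
  if (length(dc) == 0L || length(dt) == 0L) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  sc <- summarize_distances(dc); st <- summarize_distances(dt)
  fold <- st$median_nm / sc$median_nm
  wt <- suppressWarnings(stats::wilcox.test(dt, dc, alternative = "two.sided"))
  call <- if (!is.null(config$distance_cutoff_nm)) {
    st$median_nm >= config$distance_cutoff_nm
  } else {
    fold >= config$fold_change_cutoff
  }
  structure(
    list(labels = labels, control = sc, treatment = st,
         control_data = dc, treatment_data = dt,
         fold_change = fold, statistic = unname(wt$statistic),
         p_value = wt$p.value, significant = wt$p.value < config$alpha,
         declustered = call, config = config),
    class = "decluster_comparison"
  )
}

#' @export
print.decluster_comparison <- function(x, ...) {
  cat(sprintf("Pair-distance comparison: %s vs %s\n", x$labels[1L], x$labels[2L]))
  cat(sprintf("  medians: %.1f nm -> %.1f nm (fold change %.2f)\n",
              x$control$median_nm, x$treatment$median_nm, x$fold_change))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n", x$statistic, x$p_value))
  cat(sprintf("  de-clustering call: %s\n", if (x$declustered) "YES" else "no"))
  invisible(x)
}

#' Measure cell lengths and nucleoid (DAPI) intensity
#'
#' Scales per-cell pixel lengths to micrometres and, when a DAPI image and
#' per-cell masks are supplied, reports the background-subtracted mean DAPI
#' intensity per cell (background = image median, robust for sparse fields).
#'
#' @param cells A data frame with a `length_px` column (one row per cell) and
#'   optionally a `mask` list-column of pixel index vectors into `dapi`, or a
#'   bare numeric vector of pixel lengths.
#' @param dapi Optional DAPI intensity matrix.
#' @param config An [imaging_config()] supplying `pixel_nm`.
#'
#' @return A tibble with `length_um` and, when measurable, `dapi_mean`.
#' @export
measure_cells <- function(cells, dapi = NULL, config = imaging_config()) {
  if (!is.data.frame(cells)) cells <- tibble::tibble(length_px = as.numeric(cells))
  if (!"length_px" %in% names(cells)) {
    stop("`cells` must have a `length_px` column", call. = FALSE)
  }
  if (any(cells$length_px <= 0)) stop("cell lengths must be > 0", call. = FALSE)
  out <- tibble::as_tibble(cells)
  out$length_um <- out$length_px * config$pixel_nm / 1000
  if (!is.null(dapi) && "mask" %in% names(cells)) {
    bg <- stats::median(dapi)
    out$dapi_mean <- purrr::map_dbl(cells$mask, function(m) {
      if (length(m) == 0L) stop("empty cell mask", call. = FALSE)
      mean(dapi[m]) - bg
    })
  }
  out$mask <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
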