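#' Violin plot of pair-distance distributions
#'
#' The standard presentation of locus-pair separations: one violin per
#' condition with the median (solid) and quartiles (dashed) marked.
#'
#' @param distances A data frame with columns `condition` and `distance_nm`,
#'   or a named list of nm distance sets (names become conditions).
#' @return A ggplot object.
#' @export
plot_pair_distances <- function(distances) {
  if (!is.data.frame(distances)) {
    distances <- purrr::imap_dfr(distances, function(d, nm) {
      v <- if (is.data.frame(d)) d$distance_nm else as.numeric(d)
      tibble::tibble(condition = nm, distance_nm = v)
    })
  }
  distances$condition <- factor(distances$condition,
                                levels = unique(distances$condition))
  ggplot2::ggplot(distances,
                  ggplot2::aes(x = .data$condition, y = .data$distance_nm)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey30") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, linewidth = 0.4) +
    ggplot2::stat_summary(fun = function(x) stats::quantile(x, 0.25),
                          geom = "crossbar", width = 0.4,
                          linetype = "dashed", linewidth = 0.25) +
    ggplot2::stat_summary(fun = function(x) stats::quantile(x, 0.75),
                          geom = "crossbar", width = 0.4,
                          linetype = "dashed", linewidth = 0.25) +
    ggplot2::labs(x = NULL, y = "pair distance (nm)") +
    ggplot2::theme_classic()
}

#' Bar plot of a normalized transposition-frequency profile
#'
#' Mean percent-of-max per bin with SD error bars, the highest bin standing
#' at exactly 100 percent.
#'
#' @param summary An [aggregate_replicates()] tibble.
#' @param start_bin Optional donor-Mu bin, marked with a triangle.
#' @return A ggplot object.
#' @export
plot_contact_profile <- function(summary, start_bin = NULL) {
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$bin, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.9) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_pct - .data$sd_pct),
                   ymax = .data$mean_pct + .data$sd_pct),
      width = 0, colour = "grey50", linewidth = 0.3) +
    ggplot2::labs(x = "genome bin", y = "transposition frequency (% of max)") +
    ggplot2::theme_classic()
  if (!is.null(start_bin)) {
    p <- p + ggplot2::annotate("point", x = start_bin, y = 104,
                               shape = 25, fill = "red", size = 2.5)
  }
  p
}

#' Heat map of transposition frequency across conditions
#'
#' Bins-by-conditions tile map of mean percent-of-max values; the 100 percent
#' bin of each condition is visually distinct at the top of the fill scale.
#'
#' @param m A matrix from [heatmap_matrix()] (rows = bins, columns =
#'   conditions).
#' @return A ggplot object.
#' @export
plot_contact_heatmap <- function(m) {
  df <- tibble::as_tibble(m, rownames = "bin") |>
    tidyr::pivot_longer(-"bin", names_to = "condition", values_to = "pct") |>
    dplyr::mutate(bin = as.integer(.data$bin))
  df$condition <- factor(df$condition, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$bin,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% of max") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "genome bin") +
    ggplot2::theme_minimal()
}

#' Replicate-vs-replicate z-score scatter of an enrichment result
#'
#' Each protein plotted by its z-score in two replicates with the enrichment
#' cutoff drawn on both axes; enriched proteins (in the top-right square
#' under the all-replicates rule) are highlighted.
#'
#' @param x An `enrichment_result` from [call_enriched()].
#' @param reps Which two replicate columns to plot (default first two).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x, reps = c(1L, 2L)) {
  stopifnot(inherits(x, "enrichment_result"))
  zc <- x$config$z_cutoff
  cols <- paste0("rep", reps)
  df <- x$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[cols[1L]]], y = .data[[cols[2L]]],
                                   colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = zc, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = zc, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = "enriched") +
    ggplot2::labs(x = sprintf("z (replicate %d)", reps[1L]),
                  y = sprintf("z (replicate %d)", reps[2L])) +
    ggplot2::theme_classic()
}

#' Intersection (upset-style) bar summary of enrichment calls across samples
#'
#' @param x An `enrichment_intersection` from [intersect_samples()].
#' @param max_patterns Show at most this many intersection patterns.
#' @return A ggplot object.
#' @export
plot_intersection <- function(x, max_patterns = 20L) {
  stopifnot(inherits(x, "enrichment_intersection"))
  df <- utils::head(x$patterns, max_patterns)
  df$pattern <- factor(df$pattern, levels = rev(df$pattern))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$pattern)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "proteins", y = "enriched-in pattern") +
    ggplot2::theme_classic()
}

#' @export
autoplot.decluster_comparison <- function(object, ...) {
  plot_pair_distances(stats::setNames(
    list(object$control_data %||% numeric(), object$treatment_data %||% numeric()),
    object$labels))
}

#' @export
autoplot.enrichment_result <- function(object, ...) plot_enrichment(object, ...)

#' @export
autoplot.enrichment_intersection <- function(object, ...) plot_intersection(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
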