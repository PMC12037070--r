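#' Normalize a per-bin insertion profile for depth and replication bias
#'
#' Converts raw per-bin Mu insertion counts into a normalized transposition
#' frequency profile. Two corrections are applied in closed form: the
#' insertion counts are first expressed as a fraction of the replicate's total
#' insertions (read-depth correction), then divided by the bin's share of
#' total mapped reads, which corrects the replication effect -- ori-proximal
#' bins are present at higher copy number in asynchronously replicating cells
#' and their mapped-read coverage tracks that copy number:
#'
#'   `f_b = (I_b / sum(I)) / (R_b / sum(R))`
#'
#' Bins with zero mapped reads cannot be corrected and are masked (returned as
#' `NA`, excluded from the maximum). The profile is then rescaled so the
#' highest frequency is exactly 100 percent.
#'
#' @param profile A data frame with columns `bin`, `insertions` and
#'   `mapped_reads` (one replicate). Extra columns are preserved.
#'
#' @return A tibble with the input columns plus `freq` (normalized frequency
#'   `f_b`) and `pct_of_max` (`100 * f_b / max(f_b)`, in `[0, 100]`); masked
#'   bins carry `NA` in both.
#' @export
normalize_profile <- function(profile) {
  stopifnot(is.data.frame(profile))
  req <- c("bin", "insertions", "mapped_reads")
  if (!all(req %in% names(profile))) {
    stop("`profile` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  I <- profile$insertions
  R <- profile$mapped_reads
  if (any(I < 0) || any(R < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(I) <= 0) stop("all-zero insertion counts", call. = FALSE)
  if (sum(R) <= 0) stop("all-zero coverage", call. = FALSE)
  f <- (I / sum(I)) / (R / sum(R))
  f[R == 0] <- NA_real_
  fmax <- max(f, na.rm = TRUE)
  pct <- if (fmax > 0) 100 * f / fmax else f * 0
  dplyr::mutate(tibble::as_tibble(profile), freq = f, pct_of_max = pct)
}

#' Aggregate normalized replicate profiles into a condition summary
#'
#' Per-bin arithmetic mean and sample (n-1) standard deviation of the
#' percent-of-max values across biological replicates. Scaling to percent of
#' maximum is done per replicate before averaging, so the SD reflects
#' replicate-to-replicate scaling noise.
#'
#' @param profiles A data frame of stacked [normalize_profile()] outputs with
#'   a `replicate` column, or a list of such tibbles (replicate ids taken from
#'   names or positions).
#' @param condition Optional condition label stored in the output.
#'
#' @return A tibble with columns `bin`, `mean_pct`, `sd_pct` and `n_replicates`
#'   (`sd_pct` is 0 for a single replicate, flagged by `n_replicates == 1`).
#' @export
aggregate_replicates <- function(profiles, condition = NULL) {
  if (!is.data.frame(profiles)) {
    profiles <- dplyr::bind_rows(profiles, .id = "replicate")
  }
  stopifnot(all(c("bin", "pct_of_max") %in% names(profiles)))
  if (!"replicate" %in% names(profiles)) profiles$replicate <- 1L
  nb <- dplyr::count(profiles, .data$replicate)
  if (length(unique(nb$n)) != 1L) {
    stop("replicates have mismatched bin counts", call. = FALSE)
  }
  out <- profiles |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct_of_max, na.rm = TRUE),
      sd_pct = ifelse(dplyr::n() > 1L,
                      stats::sd(.data$pct_of_max, na.rm = TRUE), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  out$sd_pct[is.na(out$sd_pct)] <- 0
  if (!is.null(condition)) out <- dplyr::mutate(out, condition = condition, .before = 1L)
  out
}

#' Compare transposition frequencies between conditions at rrn bins
#'
#' Two-sample two-tailed Student t test (equal variance pooled by default,
#' matching the named test; Welch via `var_equal = FALSE`) of per-replicate
#' percent-of-max values between two conditions at each rrn-containing bin.
#' No multiple-testing correction is applied across bins: each bin is starred
#' on its own p-value, as is conventional for these per-locus panels.
#'
#' Degenerate inputs follow a fixed convention: when both groups have zero
#' variance and equal means the bins are indistinguishable and `p = 1`; zero
#' variance with unequal means gives `p` at the smallest positive double and
#' a significant flag.
#'
#' @param a,b Data frames with columns `bin`, `replicate`, `pct_of_max`
#'   (stacked [normalize_profile()] outputs), one per condition.
#' @param rrn_bins Integer vector of bin indices to test.
#' @param alpha Significance level for the flag (default 0.05).
#' @param var_equal Use the pooled-variance Student t (default `TRUE`).
#'
#' @return A tibble with one row per tested bin: `bin`, `mean_a`, `mean_b`,
#'   `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_rrn_bins <- function(a, b, rrn_bins, alpha = 0.05, var_equal = TRUE) {
  stopifnot(all(c("bin", "pct_of_max") %in% names(a)),
            all(c("bin", "pct_of_max") %in% names(b)))
  purrr::map_dfr(rrn_bins, function(bn) {
    xa <- a$pct_of_max[a$bin == bn]
    xb <- b$pct_of_max[b$bin == bn]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("need >= 2 replicates per condition at bin ", bn, call. = FALSE)
    }
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else .Machine$double.eps
      tt <- list(statistic = if (p == 1) 0 else Inf,
                 parameter = length(xa) + length(xb) - 2L, p.value = p)
    } else {
      ht <- stats::t.test(xa, xb, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    tibble::tibble(
      bin = bn, mean_a = mean(xa), mean_b = mean(xb),
      statistic = tt$statistic, df = tt$parameter,
      p_value = tt$p.value, significant = tt$p.value < alpha
    )
  })
}

#' Assemble condition summaries into a bins-by-conditions heat-map matrix
#'
#' @param summaries A named list of [aggregate_replicates()] outputs sharing
#'   the same binning; names become column (condition) labels, in order.
#'
#' @return A numeric matrix of mean percent-of-max values with rows = bins and
#'   one column per condition.
#' @seealso [plot_contact_heatmap()]
#' @export
heatmap_matrix <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(condition = summaries)
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    names(summaries) <- paste0("condition_", seq_along(summaries))
  }
  bins <- summaries[[1L]]$bin
  cols <- purrr::map(summaries, function(s) {
    if (!identical(s$bin, bins)) stop("conditions do not share a binning", call. = FALSE)
    s$mean_pct
  })
  m <- do.call(cbind, cols)
  rownames(m) <- bins
  m
}
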