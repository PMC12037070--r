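#' Miller units from absorbance readings
#'
#' The standard beta-galactosidase reporter normalization:
#'
#'   `MU = 1000 * A420 / (reaction_minutes * A600 * volume_factor)`
#'
#' with the usual 60-minute reaction and 0.02 mL culture-volume factor as
#' defaults. Linear in A420 and inverse-linear in A600 and reaction time.
#'
#' Accepts either a data frame (first argument, typically with columns
#' `sample`, `time_min`, `a420`, `a600`) -- returning the same tibble with a
#' `miller_units` column -- or bare numeric vectors.
#'
#' @param readings Data frame with `a420` and `a600` columns, or a numeric
#'   A420 vector.
#' @param a600 A600 readings (ignored when `readings` is a data frame).
#' @param reaction_minutes Reaction time in minutes (default 60).
#' @param volume_factor Culture volume factor in mL (default 0.02).
#' @return A tibble with a `miller_units` column, or a numeric vector.
#' @examples
#' miller_units(0.6, 0.5) # 1000
#' @export
miller_units <- function(readings, a600 = NULL, reaction_minutes = 60,
                         volume_factor = 0.02) {
  if (reaction_minutes <= 0) stop("`reaction_minutes` must be > 0", call. = FALSE)
  if (volume_factor <= 0) stop("`volume_factor` must be > 0", call. = FALSE)
  mu <- function(a420, a600) {
    if (any(a600 <= 0)) stop("`a600` must be > 0", call. = FALSE)
    1000 * a420 / (reaction_minutes * a600 * volume_factor)
  }
  if (is.data.frame(readings)) {
    stopifnot(all(c("a420", "a600") %in% names(readings)))
    return(dplyr::mutate(tibble::as_tibble(readings),
                         miller_units = mu(.data$a420, .data$a600)))
  }
  mu(as.numeric(readings), as.numeric(a600))
}

#' Summarize Miller-unit time series per sample and timepoint
#'
#' Mean and sample SD over replicate readings at each sample/timepoint, with
#' an optional pairwise two-tailed Student t test between two samples at each
#' shared timepoint (reusing the pooled-variance machinery of
#' [compare_rrn_bins()]).
#'
#' @param readings Data frame with `sample`, `time_min`, `a420`, `a600`.
#' @inheritParams miller_units
#' @return A tibble with `sample`, `time_min`, `n`, `mean_mu`, `sd_mu`.
#' @export
miller_summary <- function(readings, reaction_minutes = 60, volume_factor = 0.02) {
  stopifnot(all(c("sample", "time_min", "a420", "a600") %in% names(readings)))
  miller_units(readings, reaction_minutes = reaction_minutes,
               volume_factor = volume_factor) |>
    dplyr::group_by(.data$sample, .data$time_min) |>
    dplyr::summarise(n = dplyr::n(), mean_mu = mean(.data$miller_units),
                     sd_mu = ifelse(dplyr::n() > 1,
                                    stats::sd(.data$miller_units), 0),
                     .groups = "drop")
}

#' Survival fraction after induction
#'
#' Fraction of colony-forming units that survive induction relative to the
#' uninduced control: `cfu_induced / cfu_uninduced`.
#'
#' @param records Data frame with `cfu_induced` and `cfu_uninduced` columns,
#'   or a numeric `cfu_induced` vector.
#' @param cfu_uninduced Uninduced CFU counts (ignored for data-frame input).
#' @return A tibble with a `survival` column, or a numeric vector.
#' @export
survival_fraction <- function(records, cfu_uninduced = NULL) {
  frac <- function(ind, unind) {
    if (any(ind < 0) || any(unind < 0)) stop("CFU counts must be >= 0", call. = FALSE)
    if (any(unind == 0)) stop("`cfu_uninduced` must be > 0", call. = FALSE)
    ind / unind
  }
  if (is.data.frame(records)) {
    stopifnot(all(c("cfu_induced", "cfu_uninduced") %in% names(records)))
    return(dplyr::mutate(tibble::as_tibble(records),
                         survival = frac(.data$cfu_induced, .data$cfu_uninduced)))
  }
  frac(as.numeric(records), as.numeric(cfu_uninduced))
}
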