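#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pair-distance condition comparison
#'
#' @param x A `decluster_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A two-row tibble (one row per condition) with the distance
#'   summaries plus the shared fold change, test statistic, p-value and call.
#' @export
tidy.decluster_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$control, condition = x$labels[1L], .before = 1L),
    dplyr::mutate(x$treatment, condition = x$labels[2L], .before = 1L)
  ) |>
    dplyr::mutate(fold_change = x$fold_change, statistic = x$statistic,
                  p_value = x$p_value, declustered = x$declustered)
}

#' Glance at a pair-distance condition comparison
#'
#' @inheritParams tidy.decluster_comparison
#' @return A one-row tibble: `fold_change`, `statistic`, `p_value`,
#'   `significant`, `declustered`, `n_control`, `n_treatment`.
#' @export
glance.decluster_comparison <- function(x, ...) {
  tibble::tibble(
    fold_change = x$fold_change, statistic = x$statistic,
    p_value = x$p_value, significant = x$significant,
    declustered = x$declustered,
    n_control = x$control$n, n_treatment = x$treatment$n
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [call_enriched()].
#' @param ... Unused.
#' @return The per-protein score tibble (z per replicate, `min_z`, `fdr`,
#'   `enriched`, `fdr_pass`).
#' @export
tidy.enrichment_result <- function(x, ...) {
  x$scores
}

#' Glance at an enrichment result
#'
#' @inheritParams tidy.enrichment_result
#' @return A one-row tibble: `n_proteins`, `n_enriched`, `n_fdr_pass`,
#'   `z_cutoff`, `call_rule`, `z_method`.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$scores), n_enriched = length(x$enriched),
    n_fdr_pass = sum(x$scores$fdr_pass), z_cutoff = x$config$z_cutoff,
    call_rule = x$config$call_rule, z_method = x$config$z_method
  )
}
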