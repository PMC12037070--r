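#' Simulate pulldown spectral-count tables with planted enrichment
#'
#' Generates a target-gRNA table and a matched negative-control (lacZ-style)
#' table of per-protein spectral counts across replicates. Counts follow a
#' negative-binomial law (`mu = baseline_mean`, `size = dispersion`; larger
#' `size` means less overdispersion), the standard choice for overdispersed
#' proteomic count data. In the target table, planted proteins have their
#' mean multiplied by the given fold-enrichment; all other proteins are
#' exchangeable with the control.
#'
#' @param n_proteins Number of proteins (ids `P0001`, `P0002`, ...).
#' @param n_replicates Replicates per table (default 3, >= 2).
#' @param baseline_mean Expected spectral count of a null protein (default 20).
#' @param dispersion Negative-binomial size parameter (> 0; default 20).
#' @param planted A data frame with columns `protein`, `fold` (> 0) naming
#'   the enriched proteins, or `NULL` for none. Protein names not of the
#'   `P####` form are added to the universe.
#' @param seed Integer seed.
#'
#' @return A list with `target` and `control` (tibbles: `protein` plus one
#'   integer column per replicate, `rep1`..`repN`, matching the layout of
#'   published per-sgRNA spectral-count supplements) and `truth` (tibble of
#'   planted proteins and folds).
#' @export
simulate_spectral_counts <- function(n_proteins,
                                     n_replicates = 3L,
                                     baseline_mean = 20,
                                     dispersion = 20,
                                     planted = NULL,
                                     seed = 1L) {
  stopifnot(n_proteins >= 1, n_replicates >= 2, baseline_mean > 0)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), all(c("protein", "fold") %in% names(planted)))
    if (any(planted$fold <= 0)) stop("fold-enrichment must be > 0", call. = FALSE)
    proteins <- union(proteins, planted$protein)
  }
  withr::local_seed(seed)
  mu_target <- rep(baseline_mean, length(proteins))
  names(mu_target) <- proteins
  if (!is.null(planted)) {
    mu_target[planted$protein] <- baseline_mean * planted$fold
  }
  draw <- function(mu) {
    m <- vapply(seq_len(n_replicates), function(r) {
      as.numeric(stats::rnbinom(length(mu), size = dispersion, mu = mu))
    }, numeric(length(mu)))
    colnames(m) <- paste0("rep", seq_len(n_replicates))
    tibble::as_tibble(cbind(tibble::tibble(protein = proteins),
                            tibble::as_tibble(m)))
  }
  target <- draw(mu_target)
  control <- draw(rep(baseline_mean, length(proteins)))
  truth <- if (is.null(planted)) {
    tibble::tibble(protein = character(), fold = numeric())
  } else {
    tibble::as_tibble(planted)
  }
  list(target = target, control = control, truth = truth)
}
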