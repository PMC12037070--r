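#' Simulate Mu single-hop insertion data with a replication gradient
#'
#' Generates per-replicate insertion positions and per-bin mapped-read
#' coverage with the statistical structure the contact-mapping normalization
#' assumes. Insertion probability per bin is proportional to
#' `contact_profile * copy_number`, where the copy number models the
#' replication gradient of an asynchronous culture:
#'
#'   `c(b) = 2 ^ (gradient_strength * (1 - d(b)))`
#'
#' with `d(b)` the circular bin distance from `ori_bin` normalized to `[0, 1]`
#' (so `gradient_strength = 0` gives flat copy number and `1` the full 2:1
#' ori:ter gradient). Donor-proximal contact enrichment is added by weighting
#' `start_bin` with `local_contact_weight` on top of the profile. Coverage
#' reflects the same copy number (weighted by bin width) with multinomial
#' sampling at fixed depth; insertions are multinomial at fixed
#' `n_insertions`, so totals are conserved exactly.
#'
#' @param n_insertions Insertions per replicate.
#' @param binning A [make_binning()] partition (default: MG1655, 100 bins).
#' @param contact_profile Per-bin relative insertion propensity (non-negative,
#'   not all zero). Default uniform.
#' @param start_bin Donor Mu bin (default `NULL`: bin 73 of a 100-bin
#'   partition -- the rrnD-proximal donor position -- or the proportional bin
#'   for other bin counts).
#' @param local_contact_weight Extra weight added to `start_bin`'s propensity,
#'   in units of the mean profile value (default 0).
#' @param ori_bin Bin containing the replication origin (default `NULL`:
#'   bin 90 of a 100-bin partition, proportional otherwise).
#' @param gradient_strength In `[0, 1]`; see above. Default 1.
#' @param n_replicates Number of biological replicates (default 3).
#' @param reads_per_replicate Total mapped reads per replicate for the
#'   coverage track (default 1e6).
#' @param seed Integer seed.
#'
#' @return A list with `insertions` (tibble: `replicate`, `chrom`, `start`,
#'   `end`, `bin`; BED-convention 0-based half-open, `end = start + 1`),
#'   `coverage` (tibble: `replicate`, `bin`, `mapped_reads`), `truth` (tibble:
#'   `bin`, `contact`, `copy_number`, `p_insert`), and `binning`.
#' @export
simulate_mu_insertions <- function(n_insertions,
                                   binning = make_binning(),
                                   contact_profile = NULL,
                                   start_bin = NULL,
                                   local_contact_weight = 0,
                                   ori_bin = NULL,
                                   gradient_strength = 1,
                                   n_replicates = 3L,
                                   reads_per_replicate = 1e6,
                                   seed = 1L) {
  stopifnot(inherits(binning, "genome_binning"), n_replicates >= 1,
            gradient_strength >= 0, gradient_strength <= 1,
            local_contact_weight >= 0)
  if (n_insertions < 0) stop("`n_insertions` must be >= 0", call. = FALSE)
  n_bins <- nrow(binning)
  if (is.null(contact_profile)) contact_profile <- rep(1, n_bins)
  if (length(contact_profile) != n_bins || any(contact_profile < 0)) {
    stop("`contact_profile` must be non-negative with one entry per bin",
         call. = FALSE)
  }
  if (sum(contact_profile) == 0) stop("zero-sum contact profile", call. = FALSE)
  start_bin <- start_bin %||% max(1L, round(0.73 * n_bins))
  ori_bin <- ori_bin %||% max(1L, round(0.90 * n_bins))
  if (start_bin < 1 || start_bin > n_bins || ori_bin < 1 || ori_bin > n_bins) {
    stop("`start_bin` and `ori_bin` must be valid bin indices", call. = FALSE)
  }
  withr::local_seed(seed)

  contact <- contact_profile
  contact[start_bin] <- contact[start_bin] +
    local_contact_weight * mean(contact_profile)
  d_circ <- pmin(abs(seq_len(n_bins) - ori_bin),
                 n_bins - abs(seq_len(n_bins) - ori_bin)) / (n_bins / 2)
  copy_number <- 2^(gradient_strength * (1 - d_circ))
  p_insert <- contact * copy_number
  p_insert <- p_insert / sum(p_insert)
  p_reads <- copy_number * binning$width_bp
  p_reads <- p_reads / sum(p_reads)

  reps <- purrr::map(seq_len(n_replicates), function(r) {
    counts <- as.vector(stats::rmultinom(1L, n_insertions, p_insert))
    bin_of <- rep.int(seq_len(n_bins), counts)
    # uniform position within each bin
    u <- stats::runif(length(bin_of))
    start <- floor(binning$start[bin_of] +
                     u * (binning$end[bin_of] - binning$start[bin_of]))
    ins <- tibble::tibble(replicate = r, chrom = "U00096.3",
                          start = start, end = start + 1, bin = bin_of)
    cov <- tibble::tibble(
      replicate = r, bin = seq_len(n_bins),
      mapped_reads = as.vector(stats::rmultinom(1L, reads_per_replicate, p_reads))
    )
    list(ins = ins, cov = cov)
  })
  list(
    insertions = dplyr::bind_rows(purrr::map(reps, "ins")),
    coverage = dplyr::bind_rows(purrr::map(reps, "cov")),
    truth = tibble::tibble(bin = seq_len(n_bins), contact = contact,
                           copy_number = copy_number, p_insert = p_insert),
    binning = binning
  )
}

#' Bin and normalize simulated (or real) insertion data per replicate
#'
#' Convenience wrapper producing stacked [normalize_profile()] outputs, one
#' per replicate, from insertion records plus a coverage table.
#'
#' @param insertions Tibble with `replicate` and `start` columns (BED starts).
#' @param coverage Tibble with `replicate`, `bin`, `mapped_reads`.
#' @param binning A [make_binning()] partition.
#' @return A tibble of stacked normalized profiles with a `replicate` column.
#' @export
profile_replicates <- function(insertions, coverage, binning) {
  purrr::map_dfr(sort(unique(insertions$replicate)), function(r) {
    counts <- bin_insertions(insertions[insertions$replicate == r, ], binning)
    cov <- coverage[coverage$replicate == r, c("bin", "mapped_reads")]
    prof <- dplyr::left_join(counts, cov, by = "bin")
    prof$mapped_reads[is.na(prof$mapped_reads)] <- 0
    dplyr::mutate(normalize_profile(prof), replicate = r, .before = 1L)
  })
}
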