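#' Partition a circular genome into equally sized bins
#'
#' Builds the fixed genome partition used throughout the Mu-transposition
#' contact analysis: `n_bins` bins of width `genome_length_bp / n_bins`,
#' indexed 1..`n_bins`. Bin `b` covers the 0-based half-open interval
#' `[(b-1) * w, b * w)` with integer boundaries (`floor((b-1) * w)`), the last
#' bin extended to the genome end so the bins partition `[0, genome_length_bp)`
#' exactly.
#'
#' @param genome_length_bp Genome length in base pairs. Defaults to the
#'   E. coli K-12 MG1655 chromosome (4,641,652 bp), for which 100 bins are
#'   ~46 kb each.
#' @param n_bins Number of bins (default 100).
#'
#' @return A tibble with one row per bin and columns `bin` (1-based index),
#'   `start`, `end` (0-based half-open genomic interval) and `width_bp`.
#' @examples
#' binning <- make_binning(4641652, 100)
#' mean(binning$width_bp) / 1000 # ~46 kb
#' @export
make_binning <- function(genome_length_bp = 4641652L, n_bins = 100L) {
  if (!is.numeric(genome_length_bp) || length(genome_length_bp) != 1L ||
      !is.finite(genome_length_bp) || genome_length_bp < 1) {
    stop("`genome_length_bp` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    stop("`n_bins` must be a positive count", call. = FALSE)
  }
  if (genome_length_bp < n_bins) {
    stop("`genome_length_bp` must be at least `n_bins`", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  w <- genome_length_bp / n_bins
  start <- floor(w * (seq_len(n_bins) - 1L))
  end <- c(start[-1L], genome_length_bp)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    start = start,
    end = end,
    width_bp = end - start
  )
  attr(out, "genome_length_bp") <- genome_length_bp
  class(out) <- c("genome_binning", class(out))
  out
}

#' Assign insertion positions to genome bins
#'
#' Counts Mu insertion sites per genome bin. Positions are 0-based (BED
#' convention; the insertion position is the BED `start`), and every position
#' must satisfy `0 <= position < genome_length`. Out-of-range records are an
#' error that names the offending records rather than being silently dropped.
#'
#' @param insertions A data frame with a `start` column (e.g. from
#'   [read_insertions()]) or a bare numeric vector of 0-based positions.
#' @param binning A binning from [make_binning()].
#'
#' @return A tibble with columns `bin` and `insertions` (count per bin,
#'   including zero rows), whose counts sum to the number of input records.
#' @export
bin_insertions <- function(insertions, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  pos <- if (is.data.frame(insertions)) {
    if (!"start" %in% names(insertions)) {
      stop("`insertions` must have a `start` column", call. = FALSE)
    }
    insertions$start
  } else {
    as.numeric(insertions)
  }
  genome_length <- attr(binning, "genome_length_bp")
  bad <- which(!is.finite(pos) | pos < 0 | pos >= genome_length)
  if (length(bad)) {
    stop(
      "insertion position(s) outside [0, genome length) at record(s): ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "",
      call. = FALSE
    )
  }
  # findInterval on the integer bin starts honours the extended last bin
  idx <- findInterval(pos, binning$start)
  counts <- tabulate(idx, nbins = nrow(binning))
  tibble::tibble(bin = binning$bin, insertions = counts)
}
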