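#' Read Mu insertion sites from a BED file
#'
#' BED is 0-based half-open; the insertion position is the record's `start`.
#' Malformed lines (fewer than 3 fields, non-numeric or negative coordinates,
#' `start > end`) are rejected with their line numbers rather than silently
#' coerced.
#'
#' @param path Path to a BED file (3+ columns, tab-separated; `track` and
#'   `#` comment lines are skipped).
#' @return A tibble with `chrom`, `start`, `end` (integers, 0-based
#'   half-open).
#' @export
read_insertions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- integer()
  recs <- purrr::map(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) { bad <<- c(bad, lineno[i]); return(NULL) }
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end) || start < 0 || start > end) {
      bad <<- c(bad, lineno[i]); return(NULL)
    }
    tibble::tibble(chrom = f[1L], start = start, end = end)
  })
  if (length(bad)) {
    stop("malformed BED line(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  }
  out
}

#' Write insertion records as BED
#'
#' @param insertions Tibble with `chrom`, `start`, `end` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertions <- function(insertions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(insertions)))
  readr::write_tsv(insertions[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a per-bin coverage table
#'
#' @param path TSV with columns `bin` and `mapped_reads` (header required;
#'   an optional `replicate` column is kept).
#' @return A tibble.
#' @export
read_bin_coverage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("bin", "mapped_reads") %in% names(out))) {
    stop("coverage TSV needs `bin` and `mapped_reads` columns", call. = FALSE)
  }
  if (any(out$mapped_reads < 0)) stop("negative mapped_reads", call. = FALSE)
  out
}

#' Read a spectral-count table
#'
#' CSV in the layout of published per-sgRNA spectral-count supplements: a
#' protein-id column (named `protein`, or the first column) followed by one
#' integer count column per replicate. Blank cells become 0 with a warning;
#' duplicate protein ids and non-numeric counts are errors.
#'
#' @param path Path to the CSV.
#' @return A tibble with `protein` plus numeric replicate columns.
#' @export
read_spectral_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  if (!"protein" %in% names(out)) names(out)[1L] <- "protein"
  cnt <- setdiff(names(out), "protein")
  if (length(cnt) < 2L) {
    stop("need at least 2 replicate count columns", call. = FALSE)
  }
  dup <- out$protein[duplicated(out$protein)]
  if (length(dup)) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  n_blank <- 0L
  for (cc in cnt) {
    v <- out[[cc]]
    if (is.character(v)) {
      blank <- !nzchar(trimws(v))
      v[blank] <- "0"
      vv <- suppressWarnings(as.numeric(v))
      if (any(is.na(vv))) stop("non-numeric counts in column ", cc, call. = FALSE)
      n_blank <- n_blank + sum(blank)
      out[[cc]] <- vv
    } else if (anyNA(v)) {
      n_blank <- n_blank + sum(is.na(v))
      out[[cc]][is.na(v)] <- 0
    }
    if (any(out[[cc]] < 0)) stop("negative counts in column ", cc, call. = FALSE)
  }
  if (n_blank > 0L) {
    warning(n_blank, " blank count cell(s) set to 0", call. = FALSE)
  }
  out
}

#' Write a spectral-count table
#' @param tbl Tibble with `protein` plus count columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}
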