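#' Enrichment-calling configuration
#'
#' @param z_cutoff z-score threshold for an enrichment call (default 2.5).
#' @param fdr_level Empirical false-discovery-rate level (default 0.05).
#' @param pseudocount Added to every count before the log-ratio (default 1),
#'   keeping ratios finite for proteins absent from one table.
#' @param call_rule `"all-replicates"` (default; the protein must exceed the
#'   cutoff in every replicate, i.e. the top-right-corner geometry of a
#'   replicate-vs-replicate z plot) or `"any-replicate"`.
#' @param z_method `"robust"` (default; per-replicate median/MAD over the
#'   protein population) or `"meansd"` (plain mean/SD).
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(z_cutoff = 2.5, fdr_level = 0.05,
                              pseudocount = 1,
                              call_rule = c("all-replicates", "any-replicate"),
                              z_method = c("robust", "meansd")) {
  stopifnot(z_cutoff > 0, fdr_level > 0, fdr_level < 1, pseudocount >= 0)
  structure(
    list(z_cutoff = z_cutoff, fdr_level = fdr_level, pseudocount = pseudocount,
         call_rule = match.arg(call_rule), z_method = match.arg(z_method)),
    class = "enrichment_config"
  )
}

count_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "protein" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "protein")])
  if (!is.numeric(m) || ncol(m) < 1L) {
    stop("spectral table needs numeric replicate columns", call. = FALSE)
  }
  rownames(m) <- tbl$protein
  m
}

#' Control-normalized log-ratios of spectral counts
#'
#' Places the target and control tables on a shared protein universe (union;
#' missing proteins get zero counts), scales every replicate column to the
#' common mean column total (so differences in pulldown depth cancel), and
#' returns per-protein per-replicate
#' `log2((target + pseudocount) / (control + pseudocount))`, pairing target
#' replicate i with control replicate i.
#'
#' @param target,control Spectral-count tables: data frames with a `protein`
#'   column and one numeric column per replicate. `control` must have at
#'   least as many replicate columns as `target`.
#' @param config An [enrichment_config()].
#' @return A tibble with `protein` and one `rep<i>` log-ratio column per
#'   target replicate.
#' @export
normalize_to_control <- function(target, control, config = enrichment_config()) {
  tm <- count_matrix(target); cm <- count_matrix(control)
  if (ncol(cm) < ncol(tm)) {
    stop("fewer control than target replicates", call. = FALSE)
  }
  cm <- cm[, seq_len(ncol(tm)), drop = FALSE]
  prots <- union(rownames(tm), rownames(cm))
  pad <- function(m) {
    out <- matrix(0, nrow = length(prots), ncol = ncol(m),
                  dimnames = list(prots, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  tm <- pad(tm); cm <- pad(cm)
  totals <- c(colSums(tm), colSums(cm))
  ref <- mean(totals[totals > 0])
  scale_cols <- function(m) {
    cs <- colSums(m)
    sweep(m, 2L, ifelse(cs > 0, cs / ref, 1), "/")
  }
  tm <- scale_cols(tm); cm <- scale_cols(cm)
  lr <- log2((tm + config$pseudocount) / (cm + config$pseudocount))
  colnames(lr) <- paste0("rep", seq_len(ncol(lr)))
  dplyr::bind_cols(tibble::tibble(protein = prots), tibble::as_tibble(lr))
}

#' Per-replicate z-scores of control-normalized log-ratios
#'
#' Standardizes each replicate column against the protein population so the
#' unenriched bulk sits near z = 0. The default is robust:
#' `z = (lr - median(lr)) / (1.4826 * MAD(lr))`, insensitive to the small
#' enriched tail; plain mean/SD is available for sensitivity analysis
#' (`z_method = "meansd"`). A zero MAD falls back to mean/SD; a zero SD too
#' gives all-zero z.
#'
#' @param log_ratios Output of [normalize_to_control()].
#' @param config An [enrichment_config()].
#' @return A tibble with `protein` and one z column per replicate.
#' @export
z_scores <- function(log_ratios, config = enrichment_config()) {
  stopifnot(is.data.frame(log_ratios), "protein" %in% names(log_ratios))
  m <- count_matrix(log_ratios)
  if (nrow(m) < 10L) {
    warning("fewer than 10 proteins: z-scores are unstable", call. = FALSE)
  }
  z <- apply(m, 2L, function(x) {
    if (config$z_method == "robust") {
      s <- stats::mad(x) # includes the 1.4826 consistency constant
      if (s > 0) return((x - stats::median(x)) / s)
    }
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(m), dimnames = dimnames(m))
  dplyr::bind_cols(tibble::tibble(protein = log_ratios$protein),
                   tibble::as_tibble(z))
}

min_z <- function(z_tbl, rule) {
  m <- count_matrix(z_tbl)
  if (rule == "all-replicates") apply(m, 1L, min) else apply(m, 1L, max)
}

#' Call significantly enriched proteins
#'
#' A protein is enriched when its z-score exceeds `z_cutoff` in every
#' replicate (default rule; `"any-replicate"` available). An empirical FDR is
#' attached by rebuilding the z-scores under all target/control replicate
#' label swaps (2^r - 1 non-identity swap patterns for r replicate pairs) and
#' comparing each protein's decision statistic (min-z under the default rule)
#' with the pooled null: `FDR(m) = mean null count at >= m / observed count
#' at >= m`, made monotone.
#'
#' @param target,control Spectral-count tables as in [normalize_to_control()].
#' @param config An [enrichment_config()].
#' @return An object of class `enrichment_result`: list with `scores` (tibble:
#'   `protein`, per-replicate z columns, `min_z`, `fdr`, `enriched`,
#'   `fdr_pass`), `enriched` (character vector), and `config`.
#' @export
call_enriched <- function(target, control, config = enrichment_config()) {
  lr <- normalize_to_control(target, control, config)
  z <- z_scores(lr, config)
  mz <- min_z(z, config$call_rule)
  enr <- mz > config$z_cutoff

  # empirical null: swap target/control labels replicate-wise
  tm <- count_matrix(target); cm <- count_matrix(control)
  r <- ncol(tm)
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), r)))
  swaps <- swaps[rowSums(swaps) > 0, , drop = FALSE]
  null_mz <- unlist(lapply(seq_len(nrow(swaps)), function(k) {
    tk <- tm; ck <- cm[, seq_len(r), drop = FALSE]
    sw <- swaps[k, ]
    tmp <- tk[, sw, drop = FALSE]
    tk[, sw] <- ck[, sw, drop = FALSE]
    ck[, sw] <- tmp
    t_tbl <- dplyr::bind_cols(tibble::tibble(protein = rownames(tk)),
                              tibble::as_tibble(tk))
    c_tbl <- dplyr::bind_cols(tibble::tibble(protein = rownames(ck)),
                              tibble::as_tibble(ck))
    min_z(z_scores(normalize_to_control(t_tbl, c_tbl, config), config),
          config$call_rule)
  }))
  n_perm <- nrow(swaps)
  ord <- order(mz, decreasing = TRUE)
  obs_sorted <- mz[ord]
  null_ge <- vapply(obs_sorted, function(m) sum(null_mz >= m) / n_perm, numeric(1))
  fdr_sorted <- pmin(1, null_ge / seq_along(obs_sorted))
  fdr_sorted <- rev(cummin(rev(fdr_sorted))) # monotone in the threshold
  fdr <- numeric(length(mz))
  fdr[ord] <- fdr_sorted

  scores <- dplyr::mutate(z, min_z = mz, fdr = fdr, enriched = enr,
                          fdr_pass = fdr <= config$fdr_level)
  structure(
    list(scores = scores, enriched = z$protein[enr], config = config),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment result: %d / %d proteins enriched (z > %.2f, %s rule)\n",
    length(x$enriched), nrow(x$scores), x$config$z_cutoff, x$config$call_rule))
  invisible(x)
}

#' Intersect enriched-protein sets across sgRNA samples
#'
#' Builds the co-occurrence (upset-style) summary of enrichment calls across
#' samples: per-protein membership across samples, counts per intersection
#' pattern, and per-sample totals.
#'
#' @param results A named list mapping sample (sgRNA) labels to
#'   `enrichment_result` objects or bare character vectors of enriched
#'   protein ids.
#' @return An object of class `enrichment_intersection`: list with
#'   `membership` (tibble: `protein`, one logical column per sample,
#'   `n_samples`), `patterns` (tibble: `pattern`, `count`), `sample_totals`
#'   (tibble: `sample`, `n_enriched`).
#' @export
intersect_samples <- function(results) {
  stopifnot(length(results) >= 1L)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("sample_", seq_along(results))
  }
  sets <- purrr::map(results, function(r) {
    if (inherits(r, "enrichment_result")) r$enriched else as.character(r)
  })
  prots <- sort(unique(unlist(sets)))
  memb <- purrr::map_dfc(sets, function(s) prots %in% s)
  membership <- dplyr::bind_cols(tibble::tibble(protein = prots), memb)
  membership$n_samples <- rowSums(as.matrix(memb))
  patterns <- if (length(prots)) {
    membership |>
      dplyr::mutate(pattern = apply(as.matrix(memb), 1L, function(v) {
        paste(names(sets)[v], collapse = "&")
      })) |>
      dplyr::count(.data$pattern, name = "count", sort = TRUE)
  } else {
    tibble::tibble(pattern = character(), count = integer())
  }
  structure(
    list(membership = membership, patterns = patterns,
         sample_totals = tibble::tibble(sample = names(sets),
                                        n_enriched = unname(lengths(sets)))),
    class = "enrichment_intersection"
  )
}

#' @export
print.enrichment_intersection <- function(x, ...) {
  cat(sprintf("Enrichment intersection over %d samples, %d proteins\n",
              nrow(x$sample_totals), nrow(x$membership)))
  print(x$sample_totals)
  invisible(x)
}
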