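#' Run an end-to-end pipeline stage from a YAML configuration
#'
#' Thin driver tying the analysis stages together for shell use. The YAML
#' config carries a global `seed`, an `outdir`, and one block per stage with
#' that stage's parameters; the full parameter set, the seed, and MD5 hashes
#' of every input and output are echoed into a `manifest_<command>.json` so
#' any output can be regenerated from the manifest alone. A single global
#' seed is fanned out to stages by a fixed per-stage offset, so stages are
#' individually reproducible. On error, partially written outputs are
#' removed and the error is rethrown.
#'
#' Commands:
#' * `simulate` -- generate the three synthetic datasets (focus field CSV +
#'   truth JSON; per-replicate insertion BED + coverage TSV + truth JSON;
#'   target/control spectral CSVs + truth JSON).
#' * `imaging` -- read `control` and `treatment` focus-coordinate CSVs
#'   (columns `image_id`, `channel`, `x_px`, `y_px`), pair, scale to nm,
#'   compare; write pair distances and the comparison.
#' * `mu` -- read insertion BED(s) and coverage TSV, normalize per replicate,
#'   aggregate; write the per-bin summary TSV.
#' * `pulldown` -- read `target` and `control` spectral CSVs, call
#'   enrichment; write the per-protein score CSV.
#' * `assays` -- read a Miller CSV (`sample`, `time_min`, `a420`, `a600`);
#'   write per-reading Miller units.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param command One of `"simulate"`, `"imaging"`, `"mu"`, `"pulldown"`,
#'   `"assays"`.
#' @param outdir Output directory (overrides the config's `outdir`).
#' @return Invisibly, the manifest list (with elements `command`, `seed`,
#'   `parameters`, `inputs`, `outputs`).
#' @export
run_pipeline <- function(config, command = c("simulate", "imaging", "mu",
                                             "pulldown", "assays"),
                         outdir = NULL) {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("invalid config", call. = FALSE)
  outdir <- outdir %||% config$outdir %||% stop("no `outdir` in config", call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage_offset <- c(simulate = 0L, imaging = 1L, mu = 2L, pulldown = 3L,
                    assays = 4L)
  stage_seed <- seed + 1000L * stage_offset[[command]]

  written <- character()
  emit <- function(obj, file, writer) {
    path <- file.path(outdir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  inputs <- character()

  result <- tryCatch({
    switch(command,
      simulate = {
        p <- config$simulate %||% list()
        if (!is.null(p$foci)) {
          f <- do.call(simulate_foci_field,
                       c(p$foci, list(seed = stage_seed)))
          emit(f$foci, "foci.csv", readr::write_csv)
          emit(f$truth, "foci_truth.json", function(o, pth)
            jsonlite::write_json(o, pth, digits = NA))
        }
        if (!is.null(p$mu)) {
          bn <- make_binning(p$mu$genome_length_bp %||% 4641652,
                             p$mu$n_bins %||% 100L)
          args <- p$mu
          args$genome_length_bp <- NULL; args$n_bins <- NULL
          m <- do.call(simulate_mu_insertions,
                       c(args, list(binning = bn, seed = stage_seed + 1L)))
          for (r in unique(m$insertions$replicate)) {
            emit(m$insertions[m$insertions$replicate == r, ],
                 sprintf("insertions_rep%d.bed", r), write_insertions)
          }
          emit(m$coverage, "coverage.tsv", readr::write_tsv)
          emit(m$truth, "mu_truth.json", function(o, pth)
            jsonlite::write_json(o, pth, digits = NA))
        }
        if (!is.null(p$spectra)) {
          args <- p$spectra
          if (!is.null(args$planted)) {
            args$planted <- dplyr::bind_rows(args$planted)
          }
          s <- do.call(simulate_spectral_counts,
                       c(args, list(seed = stage_seed + 2L)))
          emit(s$target, "spectra_target.csv", write_spectral_table)
          emit(s$control, "spectra_control.csv", write_spectral_table)
          emit(s$truth, "spectra_truth.json", function(o, pth)
            jsonlite::write_json(o, pth, digits = NA))
        }
        invisible(NULL)
      },
      imaging = {
        p <- config$imaging %||% stop("no `imaging` block", call. = FALSE)
        cfg <- do.call(imaging_config, p$config %||% list())
        read_cond <- function(path) {
          inputs <<- c(inputs, path)
          tbl <- readr::read_csv(path, show_col_types = FALSE)
          gfp <- tbl[tbl$channel == "GFP", ]
          cfp <- tbl[tbl$channel == "CFP", ]
          to_nm(match_pairs(gfp, cfp, cfg), cfg)
        }
        ctl <- read_cond(p$control)
        trt <- read_cond(p$treatment)
        cmp <- compare_conditions(ctl, trt, cfg)
        emit(tibble::as_tibble(ctl), "pairs_control.csv", readr::write_csv)
        emit(tibble::as_tibble(trt), "pairs_treatment.csv", readr::write_csv)
        emit(tidy(cmp), "comparison.tsv", readr::write_tsv)
        cmp
      },
      mu = {
        p <- config$mu %||% stop("no `mu` block", call. = FALSE)
        bn <- make_binning(p$genome_length_bp %||% 4641652,
                           p$n_bins %||% 100L)
        cov_path <- p$coverage
        inputs <- c(inputs, cov_path, unlist(p$insertions))
        cov <- read_bin_coverage(cov_path)
        ins <- purrr::imap_dfr(as.list(unlist(p$insertions)), function(pth, i) {
          dplyr::mutate(read_insertions(pth), replicate = as.integer(i))
        })
        if (!"replicate" %in% names(cov)) cov$replicate <- 1L
        profs <- profile_replicates(ins, cov, bn)
        summ <- aggregate_replicates(profs, condition = p$condition %||% "condition")
        emit(profs, "profiles.tsv", readr::write_tsv)
        emit(summ, "profile_summary.tsv", readr::write_tsv)
        summ
      },
      pulldown = {
        p <- config$pulldown %||% stop("no `pulldown` block", call. = FALSE)
        cfg <- do.call(enrichment_config, p$config %||% list())
        inputs <- c(inputs, p$target, p$control)
        res <- call_enriched(read_spectral_table(p$target),
                             read_spectral_table(p$control), cfg)
        emit(res$scores, "enrichment.csv", readr::write_csv)
        res
      },
      assays = {
        p <- config$assays %||% stop("no `assays` block", call. = FALSE)
        inputs <- c(inputs, p$readings)
        tbl <- readr::read_csv(p$readings, show_col_types = FALSE)
        emit(miller_units(tbl), "miller_units.csv", readr::write_csv)
        invisible(NULL)
      }
    )
  }, error = function(e) {
    unlink(written)
    stop(e)
  })

  manifest <- list(
    command = command,
    seed = seed,
    stage_seed = stage_seed,
    parameters = config,
    inputs = lapply(stats::setNames(nm = unique(inputs)),
                    function(p) unname(tools::md5sum(p))),
    outputs = lapply(stats::setNames(nm = written),
                     function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(outdir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
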