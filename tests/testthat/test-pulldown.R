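tbl <- function(protein, ...) {
  m <- cbind(...)
  colnames(m) <- paste0("rep", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(protein = protein), tibble::as_tibble(m))
}

test_that("normalize_to_control gives zero log-ratios for identical tables", {
  t1 <- tbl(sprintf("P%02d", 1:12), rpois(12, 30) + 1, rpois(12, 30) + 1,
            rpois(12, 30) + 1)
  lr <- normalize_to_control(t1, t1)
  expect_equal(unlist(lr[, -1]), rep(0, 36), ignore_attr = TRUE)
})

test_that("normalize_to_control matches the pseudocount formula at equal totals", {
  prot <- sprintf("P%02d", 1:11)
  # one protein at 40 vs 10; the others identical so column totals stay equal
  base <- rep(30, 10)
  t_counts <- c(40, base)
  c_counts <- c(10, base + 3) # +3 x 10 = +30 balances the 40 - 10
  expect_equal(sum(t_counts), sum(c_counts))
  lr <- normalize_to_control(tbl(prot, t_counts, t_counts),
                             tbl(prot, c_counts, c_counts))
  expect_equal(lr$rep1[1], log2(41 / 11), tolerance = 1e-10)

  # protein absent from control: finite via pseudocount, on the protein union
  lr2 <- normalize_to_control(tbl(c("A", "B"), c(10, 10), c(10, 10)),
                              tbl(c("A", "C"), c(10, 10), c(10, 10)))
  expect_true(all(is.finite(unlist(lr2[, -1]))))
  expect_setequal(lr2$protein, c("A", "B", "C"))

  expect_error(normalize_to_control(tbl("A", 1, 1, 1), tbl("A", cbind(1, 1))),
               "fewer control")
})

test_that("column scaling makes z-scores insensitive to per-replicate depth", {
  withr::local_seed(12)
  sim <- simulate_spectral_counts(100, seed = 12)
  z1 <- z_scores(normalize_to_control(sim$target, sim$control))
  t2 <- sim$target
  t2$rep2 <- t2$rep2 * 10 # one replicate acquired at 10x depth
  z2 <- z_scores(normalize_to_control(t2, sim$control))
  # exact up to the pseudocount's weight relative to the common column total
  expect_equal(z1$rep2, z2$rep2, tolerance = 0.03)
  # with no pseudocount the invariance is exact
  cfg0 <- enrichment_config(pseudocount = 0)
  sim2 <- lapply(sim[c("target", "control")], function(tb) {
    dplyr::mutate(tb, dplyr::across(-"protein", ~ .x + 1))
  })
  za <- z_scores(normalize_to_control(sim2$target, sim2$control, cfg0), cfg0)
  t3 <- sim2$target
  t3$rep2 <- t3$rep2 * 10
  zb <- z_scores(normalize_to_control(t3, sim2$control, cfg0), cfg0)
  expect_equal(za$rep2, zb$rep2, tolerance = 1e-12)
})

test_that("z_scores centre the bulk and rank a spiked protein highest", {
  lr <- tbl(sprintf("P%02d", 1:20), rep(0.5, 20), rep(0.5, 20))
  z <- z_scores(lr)
  expect_equal(unlist(z[, -1]), rep(0, 40), ignore_attr = TRUE)

  withr::local_seed(3)
  vals <- rnorm(30, 0, 0.3)
  vals[7] <- 6
  z2 <- z_scores(tbl(sprintf("P%02d", 1:30), vals, vals))
  expect_equal(which.max(z2$rep1), 7L)
  expect_gt(z2$rep1[7], 2.5)

  expect_warning(z_scores(tbl(c("A", "B"), c(0, 1), c(0, 1))), "unstable")
})

test_that("call_enriched applies the all-replicates rule and is deterministic", {
  sim <- simulate_spectral_counts(
    150, planted = tibble::tibble(protein = "P0001", fold = 10), seed = 77)
  r1 <- call_enriched(sim$target, sim$control)
  expect_true("P0001" %in% r1$enriched)
  expect_identical(r1$scores, call_enriched(sim$target, sim$control)$scores)
  # min_z is the per-protein decision statistic
  expect_equal(r1$enriched,
               r1$scores$protein[r1$scores$min_z > 2.5])
  # any-replicate rule can only grow the set
  r2 <- call_enriched(sim$target, sim$control,
                      enrichment_config(call_rule = "any-replicate"))
  expect_true(all(r1$enriched %in% r2$enriched))
  # mean/SD convention also flags the 10x spike
  r3 <- call_enriched(sim$target, sim$control,
                      enrichment_config(z_method = "meansd"))
  expect_true("P0001" %in% r3$enriched)
})

test_that("null tables give (almost) no calls and controlled permutation FDR", {
  calls <- 0L; fdr_hits <- 0L
  for (s in 1:8) {
    sim <- simulate_spectral_counts(200, seed = 300 + s)
    res <- call_enriched(sim$target, sim$control)
    calls <- calls + length(res$enriched)
    fdr_hits <- fdr_hits + sum(res$scores$fdr_pass)
  }
  expect_lte(calls / (8 * 200), 0.01)
  expect_lte(fdr_hits / (8 * 200), 1.5 * 0.05)
})

test_that("intersect_samples builds membership and pattern counts", {
  x <- intersect_samples(list(A = c("p1", "p2"), B = c("p2", "p3")))
  expect_equal(x$membership$n_samples[x$membership$protein == "p2"], 2)
  expect_equal(sort(x$sample_totals$n_enriched), c(2L, 2L))
  expect_setequal(x$patterns$pattern, c("A", "B", "A&B"))
  expect_equal(x$patterns$count[x$patterns$pattern == "A&B"], 1L)

  empty <- intersect_samples(list(A = character(), B = character()))
  expect_equal(nrow(empty$membership), 0L)
  expect_equal(nrow(empty$patterns), 0L)
})
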