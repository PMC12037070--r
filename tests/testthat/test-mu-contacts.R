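prof <- function(I, R) tibble::tibble(bin = seq_along(I), insertions = I,
                                      mapped_reads = R)

test_that("normalize_profile implements the depth-then-coverage correction", {
  # uniform insertions over uniform coverage: every bin at 100%
  p <- normalize_profile(prof(rep(5, 4), rep(100, 4)))
  expect_equal(p$pct_of_max, rep(100, 4))

  # equal insertions, 1:2 coverage -> frequencies 2:1 -> percent 100:50
  p <- normalize_profile(prof(c(10, 10), c(100, 200)))
  expect_equal(p$freq, c(1.5, 0.75))
  expect_equal(p$pct_of_max, c(100, 50))

  # zero-coverage bin is masked and the rest rescaled to max 100
  p <- normalize_profile(prof(c(10, 10, 5), c(100, 0, 100)))
  expect_true(is.na(p$pct_of_max[2]))
  expect_equal(max(p$pct_of_max, na.rm = TRUE), 100)

  expect_error(normalize_profile(prof(c(0, 0), c(1, 1))), "all-zero insertion")
  expect_error(normalize_profile(prof(c(1, 1), c(0, 0))), "all-zero coverage")
})

test_that("percent-of-max is invariant to rescaling counts or coverage", {
  withr::local_seed(5)
  for (k in 1:5) {
    I <- rpois(20, 50) + 1
    R <- rpois(20, 1000) + 1
    base <- normalize_profile(prof(I, R))$pct_of_max
    expect_equal(normalize_profile(prof(I * 7, R))$pct_of_max, base)
    expect_equal(normalize_profile(prof(I, R * 13))$pct_of_max, base)
  }
  p <- normalize_profile(prof(rpois(20, 50) + 1, rpois(20, 1000) + 1))
  expect_equal(max(p$pct_of_max), 100)
})

test_that("aggregate_replicates gives per-bin mean and sample SD", {
  stack <- dplyr::bind_rows(
    tibble::tibble(replicate = 1, bin = 1:2, pct_of_max = c(100, 90)),
    tibble::tibble(replicate = 2, bin = 1:2, pct_of_max = c(100, 100)),
    tibble::tibble(replicate = 3, bin = 1:2, pct_of_max = c(100, 110))
  )
  s <- aggregate_replicates(stack)
  expect_equal(s$mean_pct, c(100, 100))
  expect_equal(s$sd_pct, c(0, 10))
  expect_equal(s$n_replicates, c(3L, 3L))

  one <- aggregate_replicates(tibble::tibble(replicate = 1, bin = 1,
                                             pct_of_max = 42))
  expect_equal(one$mean_pct, 42)
  expect_equal(one$sd_pct, 0)
  expect_equal(one$n_replicates, 1L)

  bad <- dplyr::bind_rows(
    tibble::tibble(replicate = 1, bin = 1:2, pct_of_max = 1),
    tibble::tibble(replicate = 2, bin = 1, pct_of_max = 1)
  )
  expect_error(aggregate_replicates(bad), "mismatched")
})

test_that("compare_rrn_bins matches the pooled-variance t oracle", {
  a <- tibble::tibble(bin = 1, replicate = 1:3, pct_of_max = c(1, 2, 3))
  b <- tibble::tibble(bin = 1, replicate = 1:3, pct_of_max = c(4, 5, 6))
  r <- compare_rrn_bins(a, b, 1)
  expect_equal(abs(r$statistic), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.02131, tolerance = 1e-3)
  expect_true(r$significant)

  # identical groups: not significant
  r2 <- compare_rrn_bins(a, a, 1)
  expect_false(r2$significant)

  # zero variance in both groups, equal means: p = 1 by convention
  c1 <- tibble::tibble(bin = 1, replicate = 1:2, pct_of_max = c(100, 100))
  r3 <- compare_rrn_bins(c1, c1, 1)
  expect_equal(r3$p_value, 1)
  # zero variance, unequal means: flagged, p in (0, 1]
  c2 <- tibble::tibble(bin = 1, replicate = 1:2, pct_of_max = c(50, 50))
  r4 <- compare_rrn_bins(c1, c2, 1)
  expect_true(r4$significant)
  expect_gt(r4$p_value, 0)

  expect_error(
    compare_rrn_bins(c1[1, ], c2, 1),
    ">= 2 replicates"
  )
})

test_that("heatmap_matrix preserves condition order and detects binning clashes", {
  s1 <- tibble::tibble(bin = 1:3, mean_pct = c(100, 50, 25), sd_pct = 0,
                       n_replicates = 3L)
  s2 <- dplyr::mutate(s1, mean_pct = c(10, 100, 30))
  m <- heatmap_matrix(list(ctl = s1, trt = s2))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(colnames(m), c("ctl", "trt"))
  expect_equal(m[, "ctl"], c(`1` = 100, `2` = 50, `3` = 25))
  # identical conditions give identical columns
  m2 <- heatmap_matrix(list(a = s1, b = s1))
  expect_equal(m2[, 1], m2[, 2])
  s3 <- dplyr::mutate(s1, bin = 4:6)
  expect_error(heatmap_matrix(list(a = s1, b = s3)), "share a binning")
})
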