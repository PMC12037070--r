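test_that("detect_foci finds isolated Gaussian spots at their centres", {
  cfg <- imaging_config(maxima_prominence = 10)
  # constant-zero image: nothing to find
  expect_equal(nrow(detect_foci(matrix(0, 30, 30), cfg)), 0L)

  # one spot, zero background: one focus at (10, 10)
  img <- spot_image(cbind(10, 10), shape = c(21L, 21L))
  f <- detect_foci(img, cfg)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$x_px, f$y_px), c(10, 10), tolerance = 0.05)

  # two equal spots
  img2 <- spot_image(rbind(c(5, 5), c(20, 20)), shape = c(25L, 25L))
  f2 <- detect_foci(img2, cfg)
  expect_equal(nrow(f2), 2L)
  got <- f2[order(f2$x_px), ]
  expect_equal(got$x_px, c(5, 20), tolerance = 0.1)
  expect_equal(got$y_px, c(5, 20), tolerance = 0.1)

  expect_error(detect_foci(matrix(c(1, NA, 1, 1), 2, 2), cfg), "non-finite")
  expect_error(detect_foci(matrix(numeric(0), 0, 0), cfg), "non-empty")
})

test_that("detection recovers >= 95% of planted high-SNR foci within 1 px", {
  withr::local_seed(21)
  grid <- expand.grid(x = seq(10, 145, by = 15), y = seq(10, 85, by = 15))
  n <- nrow(grid) # 60 planted foci on a jittered grid
  centres <- as.matrix(grid) + matrix(runif(2 * n, -2, 2), ncol = 2)
  img <- spot_image(centres, shape = c(160L, 100L), amplitude = 100,
                    sigma = 1.3, background = 50, noise_sd = 10, seed = 9)
  f <- detect_foci(img, imaging_config(maxima_prominence = 25))
  hit <- vapply(seq_len(n), function(k) {
    any(sqrt((f$x_px - centres[k, 1])^2 + (f$y_px - centres[k, 2])^2) <= 1)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("match_pairs is one-directional nearest-CFP with reuse, vs brute force", {
  # Pythagorean example
  p <- match_pairs(foci_tbl(cbind(0, 0)), foci_tbl(cbind(3, 4)))
  expect_equal(p$distance_px, 5)
  expect_equal(attr(p, "n_unmatched"), 0L)

  # no CFP at all: unmatched, no distances
  p2 <- match_pairs(foci_tbl(cbind(0, 0)), foci_tbl(cbind(numeric(0), numeric(0))))
  expect_equal(nrow(p2), 0L)
  expect_equal(attr(p2, "n_unmatched"), 1L)

  # CFP partner reused by two GFP foci
  p3 <- match_pairs(foci_tbl(rbind(c(0, 0), c(10, 0))), foci_tbl(cbind(1, 0)))
  expect_equal(sort(p3$distance_px), c(1, 9))
  expect_equal(unique(p3$cfp_x), 1)

  # random instances against the all-pairs minimization oracle
  withr::local_seed(33)
  for (k in 1:10) {
    g <- foci_tbl(matrix(runif(2 * sample(1:50, 1), 0, 100), ncol = 2))
    c_ <- foci_tbl(matrix(runif(2 * sample(1:50, 1), 0, 100), ncol = 2))
    got <- match_pairs(g, c_)
    oracle <- brute_force_pairs(g, c_)
    expect_equal(got$distance_px, oracle[, "d"])
    expect_equal(got$cfp_x, c_$x_px[oracle[, "j"]])
  }
})

test_that("mutual matching and the max-distance gate drop non-reciprocal pairs", {
  g <- foci_tbl(rbind(c(0, 0), c(10, 0)))
  c_ <- foci_tbl(cbind(1, 0))
  m <- match_pairs(g, c_, mutual = TRUE)
  expect_equal(nrow(m), 1L) # only the reciprocal pair survives
  expect_equal(attr(m, "n_unmatched"), 1L)
  gated <- match_pairs(g, c_, imaging_config(max_pair_distance_px = 5))
  expect_equal(gated$distance_px, 1)
  expect_equal(attr(gated, "n_unmatched"), 1L)
})

test_that("to_nm scales by the pixel size", {
  p <- match_pairs(foci_tbl(rbind(c(0, 0), c(0, 0))),
                   foci_tbl(rbind(c(5, 0))))
  nm <- to_nm(p, imaging_config(pixel_nm = 62))
  expect_equal(nm$distance_nm, c(310, 310))
  p0 <- match_pairs(foci_tbl(cbind(0, 0)), foci_tbl(cbind(0, 0)))
  expect_equal(to_nm(p0)$distance_nm, 0)
  p1 <- match_pairs(foci_tbl(cbind(0, 0)), foci_tbl(cbind(1, 0)))
  expect_equal(to_nm(p1)$distance_nm, 62)
})

test_that("summarize_distances uses interpolated quartiles", {
  s <- summarize_distances(c(62))
  expect_equal(c(s$median_nm, s$q1_nm, s$q3_nm), c(62, 62, 62))
  expect_equal(summarize_distances(c(1, 2, 3, 4))$median_nm, 2.5)
  s3 <- summarize_distances(c(0, 62, 124))
  expect_equal(c(s3$q1_nm, s3$median_nm, s3$q3_nm), c(31, 62, 93))
  expect_true(s3$q1_nm <= s3$median_nm && s3$median_nm <= s3$q3_nm)
  expect_error(summarize_distances(numeric(0)), "empty")
})

test_that("compare_conditions applies the 2.5-fold median rule", {
  x <- c(100, 120, 140, 160)
  same <- compare_conditions(x, x)
  expect_equal(same$fold_change, 1)
  expect_false(same$declustered)

  # shift a clustered-like sample so medians land at the published values
  withr::local_seed(8)
  ctl <- rlnorm(400, log(134), 0.4)
  ctl <- ctl * 134 / median(ctl)
  up <- ctl * 566 / 134
  r <- compare_conditions(ctl, up)
  expect_equal(r$fold_change, 566 / 134, tolerance = 1e-6)
  expect_true(r$declustered)
  expect_lt(r$p_value, 0.001)

  shx <- ctl * 214 / 134
  r2 <- compare_conditions(ctl, shx)
  expect_equal(r2$fold_change, 214 / 134, tolerance = 1e-6)
  expect_false(r2$declustered) # 1.60-fold: below the 2.5-fold rule
  expect_lt(r2$p_value, 0.001) # yet highly significant by rank test

  # the absolute-nm alternative rule
  r3 <- compare_conditions(ctl, shx, imaging_config(distance_cutoff_nm = 230))
  expect_false(r3$declustered)
  r4 <- compare_conditions(ctl, up, imaging_config(distance_cutoff_nm = 230))
  expect_true(r4$declustered)
})

test_that("tidy and glance expose the comparison as tibbles", {
  r <- compare_conditions(c(100, 130, 160), c(400, 500, 600))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$declustered)
  expect_equal(gl$n_control, 3L)
})

test_that("measure_cells scales lengths and background-subtracts DAPI", {
  m <- measure_cells(45)
  expect_equal(m$length_um, 2.79)
  expect_equal(mean(measure_cells(c(2800, 2500) / 62)$length_um), 2.65)

  dapi <- matrix(7, 20, 20)
  cells <- tibble::tibble(length_px = 45, mask = list(1:10))
  out <- measure_cells(cells, dapi)
  expect_equal(out$dapi_mean, 0) # uniform image: zero after background
  expect_error(measure_cells(tibble::tibble(length_px = 45, mask = list(integer(0))),
                             dapi), "empty")
  expect_error(measure_cells(0), "> 0")
})
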