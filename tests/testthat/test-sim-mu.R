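bn10 <- make_binning(1000, 10)

test_that("simulate_mu_insertions conserves totals and is reproducible", {
  s <- simulate_mu_insertions(500, bn10, n_replicates = 2, seed = 1)
  for (r in 1:2) {
    expect_equal(sum(s$insertions$replicate == r), 500L)
    expect_equal(sum(s$coverage$mapped_reads[s$coverage$replicate == r]), 1e6)
  }
  expect_true(all(s$insertions$start >= 0 & s$insertions$start < 1000))
  expect_identical(s$insertions,
                   simulate_mu_insertions(500, bn10, n_replicates = 2,
                                          seed = 1)$insertions)
  expect_error(simulate_mu_insertions(10, bn10, contact_profile = rep(0, 10)),
               "zero-sum")
  expect_error(simulate_mu_insertions(-5, bn10), ">= 0")
})

test_that("flat gradient and uniform profile give uniform insertions", {
  # chi-square goodness of fit vs uniform, 20 seeds: reject rarely
  reject <- 0L
  for (s in 1:20) {
    sim <- simulate_mu_insertions(2000, bn10, gradient_strength = 0,
                                  n_replicates = 1, seed = s)
    cts <- bin_insertions(sim$insertions, bn10)$insertions
    if (stats::chisq.test(cts)$p.value <= 0.01) reject <- reject + 1L
  }
  expect_gte(20L - reject, 18L)
})

test_that("a dominant donor-bin weight makes the start bin modal", {
  sim <- simulate_mu_insertions(2000, bn10, start_bin = 4L,
                                local_contact_weight = 50,
                                gradient_strength = 1, seed = 2)
  cts <- bin_insertions(sim$insertions, bn10)$insertions
  expect_equal(which.max(cts), 4L)
})

test_that("the copy-number gradient is 2 at ori, 1 at ter, and flattens at 0", {
  s <- simulate_mu_insertions(10, bn10, ori_bin = 1L, gradient_strength = 1,
                              seed = 3)
  expect_equal(s$truth$copy_number[1], 2)
  expect_equal(s$truth$copy_number[6], 1) # opposite side of the circle
  s0 <- simulate_mu_insertions(10, bn10, gradient_strength = 0, seed = 3)
  expect_equal(s0$truth$copy_number, rep(1, 10))
})

test_that("profile_replicates chains binning, coverage join and normalization", {
  sim <- simulate_mu_insertions(5000, bn10, n_replicates = 3, seed = 4)
  profs <- profile_replicates(sim$insertions, sim$coverage, bn10)
  expect_equal(nrow(profs), 30L)
  expect_equal(as.vector(tapply(profs$pct_of_max, profs$replicate, max)),
               rep(100, 3))
  summ <- aggregate_replicates(profs)
  expect_equal(nrow(summ), 10L)
  expect_true(all(summ$sd_pct >= 0))
})
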