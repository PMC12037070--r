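# small in-code fixtures shared across test files

# an image with Gaussian spots at given sub-pixel centres, no noise by default
spot_image <- function(centres, shape = c(41L, 41L), amplitude = 100,
                       sigma = 2, background = 0, noise_sd = 0, seed = 1L) {
  withr::local_seed(seed)
  img <- matrix(background, shape[1L], shape[2L])
  for (k in seq_len(nrow(centres))) {
    gx <- exp(-((seq_len(shape[1L]) - centres[k, 1L])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(shape[2L]) - centres[k, 2L])^2) / (2 * sigma^2))
    img <- img + amplitude * outer(gx, gy)
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd), shape[1L])
  pmax(img, 0)
}

foci_tbl <- function(xy) {
  tibble::tibble(x_px = xy[, 1L], y_px = xy[, 2L],
                 intensity = rep(1, nrow(xy)))
}

# brute-force nearest-CFP oracle used against match_pairs()
brute_force_pairs <- function(gfp, cfp) {
  t(vapply(seq_len(nrow(gfp)), function(i) {
    d <- sqrt((cfp$x_px - gfp$x_px[i])^2 + (cfp$y_px - gfp$y_px[i])^2)
    j <- which.min(d)
    c(j = j, d = d[j])
  }, numeric(2)))
}
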