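# Shared fixtures for the test suite. The bank is expensive to build
# (24k sampled curves), so it is constructed once per run.

TEST_BANK <- gaussian_bank()
STIM_CAM <- TEST_BANK$freq_cam

# A compact patch whose geometry leaves room for the default 6-mm field
# smoothing: 80 x 80 px (26.4 mm), band width 8 mm, field inside the
# stimulus span.
test_patch <- function(grid = c(80, 80))
  patch_config(grid_shape = grid, mask_semi_mm = c(12, 11))

test_tono <- function(...) {
  args <- list(...)
  if (is.null(args$cam_range)) args$cam_range <- c(12, 18)
  do.call(tonotopy_truth, args)
}

test_core <- function()
  core_truth(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(7.5, 3),
                                   orientation_deg = 0, effect = 0.15),
             selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(8, 3.5),
                                        orientation_deg = 0, effect = NULL))

# Noiseless Gaussian beta stack for given preferred-frequency / width maps.
make_betas <- function(pf, tw, depths = 11, height = 2, noise_sd = 0,
                       freq_cam = STIM_CAM) {
  nx <- nrow(pf); ny <- ncol(pf)
  arr <- array(NA_real_, c(nx, ny, depths, length(freq_cam)))
  for (d in seq_len(depths)) for (k in seq_along(freq_cam)) {
    m <- height * exp(-(freq_cam[k] - pf)^2 / (2 * tw^2))
    if (noise_sd > 0) m <- m + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
    arr[, , d, k] <- m
  }
  arr
}

# Brute-force per-orientation reversal oracle: explicit loops over pixels
# and the 180 orientations, with the same nearest-pixel offset convention.
oracle_reversal_count <- function(gx, gy) {
  nx <- nrow(gx); ny <- ncol(gx)
  cnt <- matrix(0L, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    for (th in 0:179) {
      ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
      dx <- round(ct); dy <- round(st)
      i1 <- i + dx; j1 <- j + dy; i2 <- i - dx; j2 <- j - dy
      if (i1 < 1 || i1 > nx || j1 < 1 || j1 > ny) next
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny) next
      p1 <- gx[i1, j1] * ct + gy[i1, j1] * st
      p2 <- gx[i2, j2] * ct + gy[i2, j2] * st
      if (!is.na(p1) && !is.na(p2) && p1 * p2 < 0) cnt[i, j] <- cnt[i, j] + 1L
    }
  }
  cnt
}

# Largest cluster of a given denomination.
largest_cluster <- function(clusters, den) {
  cl <- Filter(function(c) c$denomination == den, clusters)
  if (!length(cl)) return(NULL)
  cl[[which.max(vapply(cl, function(c) c$size, 0))]]
}
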