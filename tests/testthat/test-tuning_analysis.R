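test_that("centroid and spread match direct-sum oracles and handle edge cases", {
  fc <- STIM_CAM
  # point mass and symmetric two-point cases
  expect_equal(tuning_centroid(c(0, 0, 0, 1, 0, 0, 0), fc), fc[4])
  expect_equal(tuning_centroid(c(1, 0, 0, 0, 0, 0, 1), fc), (fc[1] + fc[7]) / 2)
  expect_equal(tuning_spread(c(0, 0, 1, 0, 0, 0, 0), fc), 0)
  expect_equal(tuning_spread(c(1, 0, 0, 0, 0, 0, 1), fc), (fc[7] - fc[1]) / 2)

  # random curves against explicit loops (with zero-clipping)
  set.seed(14)
  for (r in 1:50) {
    b <- rnorm(7)
    w <- pmax(b, 0)
    if (sum(w) == 0) next
    C_o <- sum(w * fc) / sum(w)
    S_o <- sqrt(sum(w * (fc - C_o)^2) / sum(w))
    expect_equal(tuning_centroid(b, fc), C_o, tolerance = 1e-12)
    expect_equal(tuning_spread(b, fc), S_o, tolerance = 1e-12)
    S_lit <- sum((fc - C_o)^2) / sum(b)
    expect_equal(tuning_spread(b, fc, form = "literal"), S_lit, tolerance = 1e-12)
  }

  # all-negative curve has no defined centroid
  expect_true(is.na(tuning_centroid(rep(-1, 7), fc)))
})

test_that("debias self-matches bank curves and is idempotent on them", {
  idx <- c(1L, 777L, 5000L, 12000L, 20000L, length(TEST_BANK$mode))
  est <- debias(TEST_BANK$curves[idx, ], TEST_BANK)
  expect_identical(est, TEST_BANK$mode[idx])
  # idempotence: re-debiasing curves sampled at the matched entries
  re <- debias(exp(-outer(est, STIM_CAM, "-")^2 /
                   (2 * TEST_BANK$width[idx]^2)), TEST_BANK)
  expect_identical(re, est)
})

test_that("debias places monotone curves beyond the stimulus range", {
  inc <- seq(0.1, 1, length.out = 7)
  expect_gt(debias(inc, TEST_BANK), hz_to_cam(6009))
  dec <- rev(inc)
  expect_lt(debias(dec, TEST_BANK), hz_to_cam(251))
})

test_that("centroid is edge-biased while the debiased estimate is not (wide curves)", {
  fc <- STIM_CAM
  modes <- seq(fc[1], fc[7], length.out = 25)
  for (w in c(4, 8)) {
    curves <- exp(-outer(modes, fc, "-")^2 / (2 * w^2))
    C <- tuning_centroid(curves, fc)
    est <- debias(curves, TEST_BANK)
    # centroid error grows toward the range edges, debias error does not
    expect_gt(abs(C[1] - modes[1]), 1)
    expect_gt(abs(C[25] - modes[25]), 1)
    expect_lt(max(abs(est - modes)), 0.3)
    expect_lt(abs(C[13] - modes[13]), 0.5)
  }
})

test_that("tuning width is recovered within 2% on noiseless curves", {
  fc <- STIM_CAM
  set.seed(15)
  nx <- 24; ny <- 24
  truew <- matrix(runif(nx * ny, 2, 10), nx, ny)
  truem <- matrix(runif(nx * ny, fc[3], fc[5]), nx, ny)
  betas <- make_betas(truem, truew, depths = 3)
  fit <- tuning_width_map(betas, fc, smoothing_fwhm_mm = 0)
  relerr <- abs(fit$width - truew) / truew
  expect_lt(max(relerr, na.rm = TRUE), 0.02)
  # flat curves are marked invalid
  betas[2, 2, , ] <- 1
  fit2 <- tuning_width_map(betas, fc, smoothing_fwhm_mm = 0)
  expect_true(is.na(fit2$width[2, 2]))
})

test_that("tuning width fit agrees with a brute-force 4D grid enumeration", {
  fc <- STIM_CAM
  set.seed(16)
  n <- 20
  truew <- runif(n, 2, 12)
  # modes, heights and offsets on the enumeration grids so that the coarse
  # oracle can represent the optimum exactly; only the width is off-grid
  truem <- sample(seq(fc[4] - 2, fc[4] + 2, by = 0.25), n, replace = TRUE)
  hgt <- sample(seq(1, 3, by = 0.25), n, replace = TRUE)
  off <- sample(seq(-0.3, 0, by = 0.1), n, replace = TRUE)
  betas <- array(NA_real_, c(n, 1, 1, 7))
  for (k in 1:7)
    betas[, 1, 1, k] <- hgt * exp(-(fc[k] - truem)^2 / (2 * truew^2)) + off
  fit <- tuning_width_map(betas, fc, smoothing_fwhm_mm = 0)

  grid_m <- seq(fc[4] - 2.5, fc[4] + 2.5, by = 0.25)
  grid_w <- exp(seq(log(0.4), log(20), length.out = 80))
  grid_h <- seq(0.5, 3.5, by = 0.25)
  grid_o <- seq(-0.5, 0, by = 0.1)
  for (i in seq_len(n)) {
    y <- betas[i, 1, 1, ]
    best <- Inf; bw <- NA
    for (m0 in grid_m) for (w0 in grid_w) {
      g <- exp(-(fc - m0)^2 / (2 * w0^2))
      for (h0 in grid_h) for (o0 in grid_o) {
        rss <- sum((y - h0 * g - o0)^2)
        if (rss < best) { best <- rss; bw <- w0 }
      }
    }
    # within one geometric width-grid cell of the enumeration optimum
    expect_lt(abs(log(fit$width[i, 1]) - log(bw)), log(20 / 0.4) / 79 + 1e-9)
  }
})

test_that("narrow-tuning regions are detected against wide surroundings under noise", {
  set.seed(17)
  p <- patch_config(grid_shape = c(60, 60), mask_semi_mm = c(9, 8))
  core <- core_truth(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(6, 2.5),
                                           orientation_deg = 0, effect = 0.15),
                     selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(6.5, 3),
                                                orientation_deg = 0, effect = NULL))
  tr <- generate_truth(p, test_tono(cam_range = c(13, 17), band_width_mm = 6), core)
  b <- simulate_betas(tr, noise = noise_model(beta_noise_sd = 1), seed = 18)
  fit <- tuning_width_map(b, STIM_CAM, smoothing_fwhm_mm = 3,
                          mask = tr$masks$responsive)
  sel <- tonocore:::inside_ellipse(tonocore:::patch_frame_coords(p)$u,
                                   tonocore:::patch_frame_coords(p)$v,
                                   core$selectivity_ellipse)
  inside <- fit$width[sel & tr$masks$responsive]
  outside <- fit$width[!sel & tr$masks$responsive]
  tst <- t.test(inside, outside, alternative = "less")
  expect_lt(tst$p.value, 0.01)
})

test_that("split-half reliability behaves at its limits and rises as noise falls", {
  set.seed(19)
  p <- patch_config(grid_shape = c(40, 40), mask_semi_mm = c(6, 5))
  tr <- generate_truth(p, test_tono(band_width_mm = 4, cam_range = c(13, 17)),
                       core_truth(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(4, 1.5),
                                                        orientation_deg = 0, effect = 0.15),
                                  selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(4.5, 2),
                                                             orientation_deg = 0, effect = NULL)))
  b <- simulate_betas(tr, noise = noise_model(beta_noise_sd = 0.5), seed = 20)
  expect_equal(split_half(b, b, TEST_BANK, mask = tr$masks$responsive), 1)

  r_by_noise <- sapply(c(2, 0.8, 0.2), function(sd) {
    a <- simulate_betas(tr, noise = noise_model(beta_noise_sd = sd), seed = 21)
    b2 <- simulate_betas(tr, noise = noise_model(beta_noise_sd = sd), seed = 22)
    split_half(a, b2, TEST_BANK, mask = tr$masks$responsive)
  })
  expect_true(all(diff(r_by_noise) > 0))
  expect_true(all(r_by_noise > 0 & r_by_noise < 1))
  expect_error(split_half(b[1:2, 1:1, , , drop = FALSE],
                          b[1:2, 1:1, , , drop = FALSE], TEST_BANK),
               "fewer than 3")
})
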