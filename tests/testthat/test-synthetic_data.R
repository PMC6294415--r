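test_that("ground truth is deterministic and honors its configured geometry", {
  p <- test_patch()
  tr1 <- generate_truth(p, test_tono(), test_core())
  tr2 <- generate_truth(p, test_tono(), test_core())
  expect_identical(tr1, tr2)
  # every label mask is inside the responsive mask
  for (nm in names(tr1$masks))
    expect_true(all(tr1$masks$responsive[tr1$masks[[nm]]]))
  # degenerate cam range gives a flat map
  flat <- generate_truth(p, test_tono(cam_range = c(12, 12)), test_core())
  expect_lt(diff(range(flat$preferred_cam, na.rm = TRUE)), 1e-12)
})

test_that("truth Sobel directions match the configured gradient angles", {
  p <- test_patch()
  tr <- generate_truth(p, test_tono(), test_core())
  fld <- sobel_field(tr$preferred_cam)
  dirs <- field_direction(fld)
  fr <- tonocore:::patch_frame_coords(p)
  in_band <- function(lo, hi) {
    m <- tr$masks$responsive & fr$v > lo & fr$v < hi & fld$mask
    wrap_angle(dirs[m] - p$hg_axis_deg)
  }
  ant <- in_band(1, 7)
  post <- in_band(-7, -1)
  expect_lt(max(abs(ant - 70)), 2)
  expect_lt(max(abs(post + 70)), 2)
})

test_that("noiseless betas sample the tuning Gaussian exactly", {
  p <- test_patch(c(40, 40))
  tr <- generate_truth(patch_config(grid_shape = c(40, 40), mask_semi_mm = c(6, 5)),
                       test_tono(band_width_mm = 4, cam_range = c(13, 17)),
                       core_truth(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(4, 1.5),
                                                        orientation_deg = 0, effect = 0.15),
                                  selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(4.5, 2),
                                                             orientation_deg = 0, effect = NULL)))
  nb <- noise_model(beta_noise_sd = 0)
  b <- simulate_betas(tr, noise = nb, depths = 3)
  i <- which(tr$masks$responsive)[100]
  fc <- hz_to_cam(default_stim_frequencies())
  expected <- 2 * exp(-(fc - tr$preferred_cam[i])^2 / (2 * tr$tuning_width[i]^2))
  for (d in 1:3)
    expect_equal(sapply(1:7, function(k) b[, , d, k][i]), expected, tolerance = 1e-12)
  # pixel whose mode sits on stimulus 4 peaks at sample 4
  j <- which(abs(tr$preferred_cam - fc[4]) < 0.05 & tr$masks$responsive)[1]
  expect_identical(which.max(sapply(1:7, function(k) b[, , 1, k][j])), 4L)
})

test_that("beta noise is unbiased around the clean curve", {
  p <- patch_config(grid_shape = c(8, 8), mask_semi_mm = c(100, 100))
  tr <- generate_truth(p, test_tono(), test_core())
  nm <- noise_model(beta_noise_sd = 0.5)
  set.seed(11)
  reps <- replicate(800, simulate_betas(tr, noise = nm, depths = 1,
                                        seed = sample.int(2^30, 1))[4, 4, 1, ])
  fc <- hz_to_cam(default_stim_frequencies())
  clean <- 2 * exp(-(fc - tr$preferred_cam[4, 4])^2 / (2 * tr$tuning_width[4, 4]^2))
  se <- 0.5 / sqrt(800)
  expect_true(all(abs(rowMeans(reps) - clean) < 3.5 * se))
})

test_that("cohorts are seed-deterministic with once-per-hemisphere jitter", {
  p <- test_patch(c(40, 40))
  args <- list(n = 3, patch = patch_config(grid_shape = c(40, 40), mask_semi_mm = c(6, 5)),
               tono = test_tono(band_width_mm = 4, cam_range = c(13, 17)),
               core = core_truth(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(4, 1.5),
                                                       orientation_deg = 0, effect = 0.15),
                                 selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(4.5, 2),
                                                            orientation_deg = 0, effect = NULL)),
               seed = 21, structural = FALSE, depths = 2)
  c1 <- do.call(simulate_cohort, args)
  c2 <- do.call(simulate_cohort, args)
  expect_identical(c1, c2)
  # zero jitter -> identical hemispheres
  args$noise <- noise_model(beta_noise_sd = 0,
                            jitter = list(angle_sd_deg = 0, offset_sd_mm = 0, effect_sd = 0))
  c3 <- do.call(simulate_cohort, args)
  expect_identical(c3[[1]]$truth, c3[[2]]$truth)
  expect_identical(c3[[1]]$betas, c3[[3]]$betas)
})

test_that("angle jitter has the configured spread and null cohorts are isotropic", {
  p <- patch_config(grid_shape = c(10, 10), mask_semi_mm = c(100, 100))
  nm <- noise_model(beta_noise_sd = 0, jitter = list(angle_sd_deg = 10, offset_sd_mm = 0, effect_sd = 0))
  co <- simulate_cohort(n = 200, patch = p, tono = test_tono(), core = test_core(),
                        noise = nm, seed = 31, betas = FALSE, structural = FALSE)
  a <- sapply(co, function(h) h$truth$realized$anterior_angle_deg)
  expect_equal(sd(a), 10, tolerance = 0.2 * 10)
  nullco <- simulate_cohort(n = 400, patch = p, tono = test_tono(), core = test_core(),
                            noise = nm, seed = 32, null_cohort = TRUE,
                            betas = FALSE, structural = FALSE)
  th <- sapply(nullco, function(h) h$truth$realized$anterior_angle_deg) * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(R, 3 / sqrt(400))
})
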