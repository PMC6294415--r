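test_that("Sobel fields are exact on ramps and rotation-equivariant", {
  # ramp along +x: uniform direction 0, unit magnitude
  ramp <- outer(1:30, 1:30, function(i, j) i)
  f <- sobel_field(ramp)
  d <- field_direction(f)
  expect_true(all(abs(d[f$mask]) < 1e-10))
  expect_true(all(abs(sqrt(f$gx[f$mask]^2 + f$gy[f$mask]^2) - 1) < 1e-10))
  # ramp rotated 30 degrees
  r30 <- outer(1:30, 1:30, function(i, j) i * cos(pi / 6) + j * sin(pi / 6))
  d30 <- field_direction(sobel_field(r30))
  expect_lt(max(abs(d30 - 30), na.rm = TRUE), 1)
  # constant map -> zero vectors
  f0 <- sobel_field(matrix(3, 20, 20))
  expect_true(all(f0$gx[f0$mask] == 0 & f0$gy[f0$mask] == 0))
})

test_that("mask-aware smoothing preserves constants and has the right kernel width", {
  m <- matrix(2.5, 40, 40)
  m[1:10, 1:10] <- NA
  out <- smooth_map_or_field(m, 4, 1)
  expect_equal(out[!is.na(m)], rep(2.5, sum(!is.na(m))), tolerance = 1e-12)
  expect_true(all(is.na(out[is.na(m)])))
  # fwhm 0 is the identity
  r <- matrix(rnorm(100), 10, 10)
  expect_identical(smooth_map_or_field(r, 0), r)
  # impulse response FWHM within 5% of nominal (interpolated half crossings)
  imp <- matrix(0, 161, 161); imp[81, 81] <- 1
  s <- smooth_map_or_field(imp, 20, 1)
  prof <- s[, 81]
  half <- max(prof) / 2
  lo <- approx(prof[1:81], 1:81, xout = half)$y
  hi <- approx(prof[161:81], 161:81, xout = half)$y
  expect_lt(abs((hi - lo) - 20) / 20, 0.05)
})

test_that("sign maps project onto the requested direction", {
  f70 <- sobel_field(outer(1:20, 1:20, function(i, j)
    i * cos(70 * pi / 180) + j * sin(70 * pi / 180)))
  s90 <- sign_map(f70, 90)
  expect_true(all(s90[f70$mask] == 1))       # cos(20 deg) > 0
  # field along +y, direction 0: exactly perpendicular -> sign 0
  fy <- structure(list(gx = matrix(0, 5, 5), gy = matrix(1, 5, 5),
                       mask = matrix(TRUE, 5, 5)), class = "vector_field")
  expect_true(all(sign_map(fy, 0) == 0))
  # field along +x: parallel and antiparallel projections
  fx <- structure(list(gx = matrix(1, 5, 5), gy = matrix(0, 5, 5),
                       mask = matrix(TRUE, 5, 5)), class = "vector_field")
  expect_true(all(sign_map(fx, 0) == 1))
  expect_true(all(sign_map(fx, 180) == -1))
})

test_that("reversal detection finds valley lines and nothing on ramps", {
  # 1D valley |x - x0| after 6-px smoothing
  m <- outer(1:60, rep(1, 40), function(i, j) abs(i - 30))
  fs <- smooth_map_or_field(sobel_field(m), 6, 1)
  ms <- smooth_map_or_field(m, 6, 1)
  rm <- detect_reversals(fs, ms, 10)
  rows <- unique(which(rm$mask, arr.ind = TRUE)[, 1])
  expect_true(all(abs(rows - 30) <= 1))
  low <- rm$mask & !is.na(rm$denomination) & rm$denomination == -1
  expect_gt(sum(low), 0)
  expect_equal(sum(rm$mask & !is.na(rm$denomination) & rm$denomination == 1), 0)

  # inverted V is denominated high on the same line
  rmh <- detect_reversals(smooth_map_or_field(sobel_field(-m), 6, 1),
                          smooth_map_or_field(-m, 6, 1), 10)
  high <- rmh$mask & !is.na(rmh$denomination) & rmh$denomination == 1
  expect_gt(sum(high), 0)
  expect_equal(sum(rmh$mask & !is.na(rmh$denomination) & rmh$denomination == -1), 0)

  # planar ramp: no reversals anywhere
  ramp <- outer(1:40, 1:40, function(i, j) 0.2 * i + 0.1 * j)
  rr <- detect_reversals(smooth_map_or_field(sobel_field(ramp), 6, 1), ramp, 10)
  expect_identical(sum(rr$mask), 0L)

  expect_error(detect_reversals(fs, ms, 0), "criterion")
  expect_error(detect_reversals(fs, ms, 200), "criterion")
})

test_that("reversal counts equal the brute-force per-orientation oracle", {
  set.seed(23)
  for (r in 1:3) {
    gx <- matrix(rnorm(400), 20, 20)
    gy <- matrix(rnorm(400), 20, 20)
    fld <- structure(list(gx = gx, gy = gy,
                          mask = matrix(TRUE, 20, 20)), class = "vector_field")
    rm <- detect_reversals(fld, matrix(0, 20, 20), 10)
    expect_identical(rm$count, oracle_reversal_count(gx, gy))
  }
})

test_that("reversal masks shrink monotonically with the criterion", {
  m <- outer(1:60, rep(1, 40), function(i, j) abs(i - 30))
  fs <- smooth_map_or_field(sobel_field(m), 6, 1)
  ms <- smooth_map_or_field(m, 6, 1)
  prev <- detect_reversals(fs, ms, 5)$mask
  for (crit in c(20, 60, 120)) {
    cur <- detect_reversals(fs, ms, crit)$mask
    expect_true(all(prev[cur]))
    prev <- cur
  }
})

test_that("clustering recovers line orientation and joins collinear segments", {
  # straight 1-px line at 35 degrees
  nx <- 80
  mask <- matrix(FALSE, nx, nx)
  for (t in seq(-30, 30, by = 0.5)) {
    i <- round(40 + t * cos(35 * pi / 180)); j <- round(40 + t * sin(35 * pi / 180))
    mask[i, j] <- TRUE
  }
  rm <- list(mask = mask, denomination = ifelse(mask, -1L, NA_integer_),
             count = mask * 50L, criterion = 10)
  class(rm) <- "reversal_map"
  cl <- cluster_reversals(rm, pixel_mm = 1)
  expect_length(cl, 1)
  expect_lt(min(abs(cl[[1]]$orientation_deg - 35), abs(cl[[1]]$orientation_deg - 215)), 2)

  # two collinear segments with a small gap merge; perpendicular ones do not
  seg <- matrix(FALSE, 60, 60)
  seg[10:25, 30] <- TRUE
  seg[28:43, 30] <- TRUE        # gap of 2 px, collinear
  seg[30, 45:59] <- TRUE        # perpendicular line elsewhere
  rm2 <- list(mask = seg, denomination = ifelse(seg, -1L, NA_integer_),
              count = seg * 50L, criterion = 10)
  class(rm2) <- "reversal_map"
  cl2 <- cluster_reversals(rm2, collinearity_tol_deg = 20, gap_tol_mm = 3,
                           pixel_mm = 1)
  expect_length(cl2, 2)
  sizes <- sort(vapply(cl2, function(c) c$size, 0))
  expect_identical(sizes, c(15, 32))
})
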