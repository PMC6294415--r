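# Gaussian ridge running at a given angle through the grid centre.
ridge_map <- function(angle_deg, n = 80, width = 6, amp = 1) {
  th <- angle_deg * pi / 180
  outer(seq_len(n) - (n + 1) / 2, seq_len(n) - (n + 1) / 2,
        function(x, y) {
          v <- -x * sin(th) + y * cos(th)
          amp * exp(-v^2 / (2 * width^2))
        })
}

test_that("the HG frame recovers ridge orientation from curvature gradients", {
  for (ang in c(40, 130)) {
    curv <- ridge_map(ang)
    roi <- curv > 0.4
    fr <- hg_frame(curv, roi)
    expect_lt(min(abs(fr$axis_deg - ang), 180 - abs(fr$axis_deg - ang)), 2)
  }
  # equivariance: rotating the ridge by 90 degrees rotates the axis by 90
  f1 <- hg_frame(ridge_map(20), ridge_map(20) > 0.4)
  f2 <- hg_frame(ridge_map(110), ridge_map(110) > 0.4)
  d <- abs(f2$axis_deg - f1$axis_deg) %% 180
  expect_lt(abs(d - 90), 2)
  # isotropic bump raises the instability warning
  bump <- outer(1:60, 1:60, function(i, j) exp(-((i - 30)^2 + (j - 30)^2) / 50))
  expect_warning(hg_frame(bump, bump > 0.3), "isotropic")
  expect_error(hg_frame(bump, matrix(FALSE, 60, 60)), "empty")
})

test_that("roi_stats reports axes, centroids, and mean directions in the frame", {
  frame <- structure(list(origin_px = c(40, 40), axis_deg = 0, sv_ratio = 10),
                     class = "frame")
  # axis-aligned 2:1 ellipse rotated to 70 degrees
  xy <- expand.grid(x = 1:80, y = 1:80)
  th <- 70 * pi / 180
  a <- (xy$x - 40) * cos(th) + (xy$y - 40) * sin(th)
  b <- -(xy$x - 40) * sin(th) + (xy$y - 40) * cos(th)
  roi <- matrix((a / 20)^2 + (b / 10)^2 <= 1, 80, 80)
  st <- roi_stats(roi, frame, pixel_mm = 1)
  expect_lt(min(abs(st$axis_deg - 70), 180 - abs(st$axis_deg - 70)), 1)
  expect_equal(unname(st$centroid_mm), c(0, 0), tolerance = 0.2)
  expect_equal(st$area_mm2, sum(roi))
  # disc: near-equal singular values flag instability
  disc <- matrix((a / 12)^2 + (b / 12)^2 <= 1, 80, 80)
  expect_false(roi_stats(disc, frame, pixel_mm = 1)$axis_stable)
  # uniform field -> exact mean direction
  fld <- structure(list(gx = matrix(cos(th), 80, 80), gy = matrix(sin(th), 80, 80),
                        mask = matrix(TRUE, 80, 80)), class = "vector_field")
  expect_equal(roi_stats(roi, frame, fld, pixel_mm = 1)$mean_direction_deg, 70,
               tolerance = 1e-9)
  expect_error(roi_stats(matrix(FALSE, 2, 2), frame), "empty")
})

test_that("core thresholding uses the midway criterion with either polarity", {
  n <- 60
  xy <- expand.grid(x = 1:n, y = 1:n)
  inside <- matrix((xy$x - 30)^2 / 225 + (xy$y - 30)^2 / 64 <= 1, n, n)
  map <- ifelse(inside, 1, 0)
  labels <- list(te10 = inside, te11 = matrix(FALSE, n, n), te12 = matrix(FALSE, n, n),
                 anterior_noncore = !inside & xy$y > 38,
                 posterior_noncore = !inside & xy$y < 22)
  dim(labels$anterior_noncore) <- c(n, n); dim(labels$posterior_noncore) <- c(n, n)
  up <- core_roi(map, labels, polarity = "above")
  expect_equal(up$criterion, 0.5)
  expect_identical(up$roi, inside)
  dn <- core_roi(map, labels, polarity = "below")
  expect_identical(dn$roi, !inside)
  # noisy ellipse still recovered with Dice > 0.8
  set.seed(24)
  noisy <- map + matrix(rnorm(n * n, 0, 0.25), n, n)
  nz <- core_roi(noisy, labels, polarity = "above")
  dice <- 2 * sum(nz$roi & inside) / (sum(nz$roi) + sum(inside))
  expect_gt(dice, 0.8)
  expect_error(core_roi(map, list(te10 = matrix(FALSE, n, n),
                                  anterior_noncore = labels$anterior_noncore,
                                  posterior_noncore = labels$posterior_noncore),
                        polarity = "above"), "empty label")
})

test_that("gradient ROIs fill the bands between reversal polylines", {
  tr <- generate_truth(test_patch(), test_tono(), test_core())
  fld <- sobel_field(tr$preferred_cam)
  fs <- smooth_map_or_field(fld, 6, 0.33)
  ps <- smooth_map_or_field(tr$preferred_cam, 6, 0.33)
  cl <- cluster_reversals(detect_reversals(fs, ps, 10))
  frame <- structure(list(origin_px = c(40.5, 40.5), axis_deg = 40, sv_ratio = 10),
                     class = "frame")
  g <- gradient_rois(cl, frame, tr$masks$responsive)
  fr <- tonocore:::patch_frame_coords(test_patch())
  # bands sit strictly on either side of the low line, inside the folds
  expect_gt(sum(g$anterior), 200)
  expect_gt(sum(g$posterior), 200)
  expect_true(all(fr$v[g$anterior] > -0.5 & fr$v[g$anterior] < 9))
  expect_true(all(fr$v[g$posterior] < 0.5 & fr$v[g$posterior] > -9))
  # clipping: masked-out corridor is excluded
  mask2 <- tr$masks$responsive
  mask2[, 38:42] <- FALSE
  g2 <- gradient_rois(cl, frame, mask2)
  expect_identical(sum(g2$anterior[, 38:42]), 0L)
  # missing side is reported by name
  cl_no_post <- Filter(function(c) !(c$denomination == "high" &&
                                       mean(fr$v[c$pixels]) < 0), cl)
  expect_error(gradient_rois(cl_no_post, frame, tr$masks$responsive), "posterior")
})

test_that("overlap statistics follow the smaller-ROI convention", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_equal(overlap_stats(a, a, a)$overlap_anterior, 1)
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(overlap_stats(a, b, b)$overlap_anterior, 0)
  # symmetric straddling core -> ratio 1
  core <- matrix(FALSE, 10, 10); core[4:7, 3:8] <- TRUE
  ant <- matrix(FALSE, 10, 10); ant[1:5, ] <- TRUE
  post <- matrix(FALSE, 10, 10); post[6:10, ] <- TRUE
  ov <- overlap_stats(core, ant, post)
  expect_equal(ov$overlap_ratio, 1)
  # overlap is symmetric in its two arguments
  expect_equal(sum(a & b) / min(sum(a), sum(b)),
               sum(b & a) / min(sum(b), sum(a)))
})

test_that("reversal orientation averages clusters axially with pixel weights", {
  frame <- structure(list(origin_px = c(0, 0), axis_deg = 0, sv_ratio = 10),
                     class = "frame")
  mk <- function(ori, n) list(pixels = matrix(0, n, 2), orientation_deg = ori, size = n,
                              denomination = "low")
  expect_equal(reversal_orientation(list(mk(0, 50)), frame), 0)
  expect_equal(reversal_orientation(list(mk(10, 100), mk(170, 100)), frame), 0,
               tolerance = 1e-9)
  # weighting: a heavier cluster dominates
  r <- reversal_orientation(list(mk(20, 300), mk(170, 100)), frame)
  expect_gt(r, 5)
  expect_error(reversal_orientation(list(), frame), "no clusters")
})

test_that("curvature-by-frequency binning averages within bins", {
  set.seed(25)
  roi <- matrix(TRUE, 30, 30)
  pref <- matrix(runif(900, 10, 20), 30, 30)
  # constant curvature -> every bin equals the constant
  tbl <- curvature_by_frequency(roi, pref, matrix(0.3, 30, 30), n_bins = 5)
  expect_equal(tbl$mean_curvature, rep(0.3, 5))
  # single bin equals the ROI mean
  curv <- matrix(rnorm(900), 30, 30)
  tbl1 <- curvature_by_frequency(roi, pref, curv, n_bins = 1)
  expect_equal(tbl1$mean_curvature, mean(curv))
  # a linear curvature-frequency relation is monotone across bins
  curv_lin <- (pref - 15) * 0.1 + matrix(rnorm(900, 0, 0.05), 30, 30)
  tbl2 <- curvature_by_frequency(roi, pref, curv_lin, n_bins = 6)
  expect_true(all(diff(tbl2$mean_curvature) > 0))
})
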