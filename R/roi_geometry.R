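#' ROI geometry in the Heschl's-gyrus coordinate frame
#'
#' All ROI statistics are expressed in a hemisphere-specific frame defined
#' by the centroid and long-axis orientation of the HG ROI: `along` is the
#' coordinate along the HG long axis, `across` the signed coordinate
#' perpendicular to it (positive = anterior by package convention).
#'
#' @name roi_geometry
NULL

#' HG coordinate frame from cortical curvature
#'
#' Computes Sobel gradients of the curvature map within the HG ROI, takes
#' the singular value decomposition of the n x 2 gradient matrix, and uses
#' the second right-singular vector as the (axial) long-axis orientation:
#' curvature gradients point across the gyral ridge, so the second singular
#' direction runs along it. The frame origin is the ROI pixel centroid. A
#' warning is raised when the gradient distribution is nearly isotropic
#' (singular-value ratio < 1.05) and the axis is unstable.
#'
#' @param curvature_map Curvature matrix.
#' @param hg_roi Logical matrix (nonempty).
#' @return A `frame` list: `origin_px` (x, y), `axis_deg` (axial, [0, 180)),
#'   `sv_ratio`.
#' @export
hg_frame <- function(curvature_map, hg_roi) {
  if (!any(hg_roi)) stop("hg_frame: empty HG ROI")
  fld <- sobel_field(curvature_map)
  ok <- hg_roi & fld$mask
  G <- cbind(fld$gx[ok], fld$gy[ok])
  G <- G[rowSums(G^2) > 0, , drop = FALSE]
  if (nrow(G) < 2) stop("hg_frame: too few curvature gradients in ROI")
  sv <- svd(G)
  ratio <- sv$d[1] / max(sv$d[2], .Machine$double.eps)
  if (ratio < 1.05)
    warning("hg_frame: near-isotropic curvature gradients; axis unstable")
  axis_deg <- wrap_axial(rad2deg(atan2(sv$v[2, 2], sv$v[1, 2])))
  xy <- mask_coords(hg_roi)
  structure(list(origin_px = colMeans(xy), axis_deg = axis_deg,
                 sv_ratio = ratio), class = "frame")
}

# Convert pixel coordinates (n x 2) to frame coordinates in mm.
to_frame_mm <- function(xy, frame, pixel_mm) {
  d <- sweep(xy, 2, frame$origin_px) * pixel_mm
  u <- unit_vec(frame$axis_deg)
  cbind(along = d %*% u, across = d %*% c(-u[2], u[1]))
}

#' Geometric statistics of an ROI
#'
#' Long axis from the SVD of the ROI's centred pixel coordinates (first
#' right-singular vector, axial), centroid in frame coordinates (mm), area,
#' and (when a vector field is supplied) the mean gradient direction: the
#' direction of the vector sum over ROI pixels, relative to the frame axis.
#'
#' @param roi Logical matrix (nonempty).
#' @param frame A `frame` from [hg_frame()].
#' @param field Optional `vector_field` for the mean gradient direction.
#' @param pixel_mm Pixel size in mm.
#' @return List with `axis_deg` (relative to frame, axial), `axis_abs_deg`,
#'   `centroid_mm` (along, across), `area_mm2`, `n_pixels`,
#'   `mean_direction_deg` (relative to frame; `NA` without `field`),
#'   `axis_stable` (FALSE when the coordinate SVD is nearly isotropic).
#' @export
roi_stats <- function(roi, frame, field = NULL, pixel_mm = 0.33) {
  if (!any(roi)) stop("roi_stats: empty ROI")
  xy <- mask_coords(roi)
  pa <- if (nrow(xy) > 1) principal_axis(xy) else list(axis_deg = 0, d = c(0, 0))
  stable <- nrow(xy) > 2 && pa$d[1] > 1.05 * pa$d[2]
  cen <- to_frame_mm(matrix(colMeans(xy), 1), frame, pixel_mm)
  mean_dir <- NA_real_
  if (!is.null(field)) {
    ok <- roi & field$mask
    sx <- sum(field$gx[ok]); sy <- sum(field$gy[ok])
    if (sx != 0 || sy != 0)
      mean_dir <- wrap_angle(rad2deg(atan2(sy, sx)) - frame$axis_deg)
  }
  list(axis_deg = wrap_axial(pa$axis_deg - frame$axis_deg),
       axis_abs_deg = pa$axis_deg,
       centroid_mm = c(along = cen[1], across = cen[2]),
       area_mm2 = nrow(xy) * pixel_mm^2, n_pixels = nrow(xy),
       mean_direction_deg = mean_dir, axis_stable = stable)
}

#' Core ROI from an individualized threshold criterion
#'
#' The criterion is set midway between the average map value within the
#' TE1.0 label and the average within the conjunction of the anterior and
#' posterior non-core labels; pixels on the core side of the criterion
#' (below it for tuning width, above it for myelin) within the responsive
#' mask form the ROI. The alternative criterion compares the conjunction of
#' all three TE1 labels against the non-core labels.
#'
#' @param map Marker map (tuning width or myelin).
#' @param labels List of logical matrices: `te10`, `te11`, `te12`,
#'   `anterior_noncore`, `posterior_noncore`.
#' @param polarity `"below"` (core = values below criterion; tuning width)
#'   or `"above"` (myelin).
#' @param responsive_mask Logical matrix limiting the ROI.
#' @param criterion_mode `"te10"` (default) or `"all_te"` (supplementary
#'   variant).
#' @param largest_component Restrict to the largest connected component
#'   (default `FALSE`).
#' @return List with `roi` (logical matrix) and `criterion` (the threshold).
#' @export
core_roi <- function(map, labels, polarity = c("below", "above"),
                     responsive_mask = NULL,
                     criterion_mode = c("te10", "all_te"),
                     largest_component = FALSE) {
  polarity <- match.arg(polarity)
  criterion_mode <- match.arg(criterion_mode)
  core_lab <- if (criterion_mode == "te10") labels$te10
              else labels$te10 | labels$te11 | labels$te12
  noncore <- labels$anterior_noncore | labels$posterior_noncore
  if (!any(core_lab) || !any(noncore)) stop("core_roi: empty label masks")
  crit <- (mean(map[core_lab], na.rm = TRUE) +
           mean(map[noncore], na.rm = TRUE)) / 2
  roi <- if (polarity == "below") !is.na(map) & map < crit
         else !is.na(map) & map > crit
  if (!is.null(responsive_mask)) roi <- roi & responsive_mask
  if (largest_component && any(roi)) {
    lab <- label_components(roi)
    sizes <- tabulate(lab[lab > 0])
    roi <- lab == which.max(sizes)
  }
  list(roi = roi, criterion = crit)
}

# Interpolated across-axis position of a reversal polyline as a function of
# the along-axis coordinate (HG frame, mm), linearly extended at the ends.
polyline_fun <- function(xy_frame) {
  o <- order(xy_frame[, 1])
  u <- xy_frame[o, 1]; v <- xy_frame[o, 2]
  # average across-coordinates at duplicate along positions
  agg <- tapply(v, round(u, 6), mean)
  uu <- as.numeric(names(agg)); vv <- as.numeric(agg)
  if (length(uu) < 2) return(function(x) rep(vv[1], length(x)))
  stats::approxfun(uu, vv, rule = 2)
}

#' Gradient ROIs bounded by reversal lines
#'
#' The anterior gradient ROI lies between the high-frequency reversal
#' anterior to HG and the low-frequency reversal on HG; the posterior
#' gradient ROI between the low-frequency reversal and the posterior
#' high-frequency reversal. Cluster polylines are expressed in the HG frame
#' (positive across = anterior); each in-mask pixel is assigned by comparing
#' its across coordinate with the polylines interpolated at its along
#' coordinate. Mediolateral ends are clipped by the responsive mask. A
#' margin of `margin_mm` next to each bounding reversal line is excluded:
#' reversal pixels mark the border itself, where gradient directions mix
#' across the reversal, so they belong to neither gradient.
#'
#' @param clusters List of reversal clusters from [cluster_reversals()].
#' @param frame A `frame`.
#' @param responsive_mask Logical matrix.
#' @param pixel_mm Pixel size in mm.
#' @param margin_mm Exclusion margin at the bounding lines (default 1).
#' @return List with `anterior`, `posterior` (logical matrices) and the
#'   identified `low`, `high_anterior`, `high_posterior` clusters.
#' @export
gradient_rois <- function(clusters, frame, responsive_mask, pixel_mm = 0.33,
                          margin_mm = 1) {
  if (!length(clusters)) stop("gradient_rois: no reversal clusters")
  fc <- lapply(clusters, function(cl) to_frame_mm(cl$pixels, frame, pixel_mm))
  across_cen <- vapply(fc, function(m) mean(m[, 2]), 0)
  den <- vapply(clusters, function(cl) cl$denomination, "")
  size <- vapply(clusters, function(cl) cl$size, 0)

  low_i <- which(den == "low")
  if (!length(low_i)) stop("gradient_rois: no low-frequency reversal cluster")
  low_i <- low_i[which.max(size[low_i] / (1 + abs(across_cen[low_i])))]
  low_v <- across_cen[low_i]

  hi_ant <- which(den == "high" & across_cen > low_v)
  hi_post <- which(den == "high" & across_cen < low_v)
  if (!length(hi_ant)) stop("gradient_rois: missing high-frequency reversal on the anterior side")
  if (!length(hi_post)) stop("gradient_rois: missing high-frequency reversal on the posterior side")
  hi_ant <- hi_ant[which.max(size[hi_ant])]
  hi_post <- hi_post[which.max(size[hi_post])]

  f_low <- polyline_fun(fc[[low_i]])
  f_ant <- polyline_fun(fc[[hi_ant]])
  f_post <- polyline_fun(fc[[hi_post]])

  xy <- mask_coords(responsive_mask)
  fm <- to_frame_mm(xy, frame, pixel_mm)
  vl <- f_low(fm[, 1]); va <- f_ant(fm[, 1]); vp <- f_post(fm[, 1])
  ant_sel <- fm[, 2] > vl + margin_mm & fm[, 2] < va - margin_mm
  post_sel <- fm[, 2] < vl - margin_mm & fm[, 2] > vp + margin_mm

  shape <- function(sel) {
    m <- matrix(FALSE, nrow(responsive_mask), ncol(responsive_mask))
    m[xy[sel, , drop = FALSE]] <- TRUE
    m
  }
  anterior <- shape(ant_sel); posterior <- shape(post_sel)
  if (!any(anterior)) warning("gradient_rois: empty anterior ROI (zero-width band)")
  if (!any(posterior)) warning("gradient_rois: empty posterior ROI (zero-width band)")
  list(anterior = anterior, posterior = posterior,
       low = clusters[[low_i]], high_anterior = clusters[[hi_ant]],
       high_posterior = clusters[[hi_post]])
}

#' Overlap statistics between a core ROI and the gradient ROIs
#'
#' `overlap(A, B) = |A intersect B| / min(|A|, |B|)`; the overlap ratio is
#' `overlap(core, anterior) / overlap(core, posterior)` and ranges from 0
#' (exclusively posterior) to infinity (exclusively anterior), 1 indicating
#' equal overlap.
#'
#' @param core,anterior,posterior Logical ROI matrices.
#' @return List with `overlap_anterior`, `overlap_posterior`,
#'   `overlap_ratio`.
#' @export
overlap_stats <- function(core, anterior, posterior) {
  ov <- function(a, b) {
    if (!any(a) || !any(b)) return(NA_real_)
    sum(a & b) / min(sum(a), sum(b))
  }
  oa <- ov(core, anterior)
  op <- ov(core, posterior)
  ratio <- if (is.na(oa) || is.na(op) || (oa == 0 && op == 0)) NA_real_
           else oa / op
  list(overlap_anterior = oa, overlap_posterior = op, overlap_ratio = ratio)
}

#' Pixel-weighted orientation of the low-frequency reversal
#'
#' Axial mean (via angle doubling) of the cluster orientations, weighted by
#' cluster pixel counts, expressed relative to the frame axis.
#'
#' @param clusters List of low-frequency reversal clusters.
#' @param frame A `frame`.
#' @return Orientation in degrees, axial, relative to the HG axis (in
#'   (-90, 90]).
#' @export
reversal_orientation <- function(clusters, frame) {
  if (!length(clusters)) stop("reversal_orientation: no clusters")
  ori <- vapply(clusters, function(cl) cl$orientation_deg, 0)
  wts <- vapply(clusters, function(cl) cl$size, 0)
  th2 <- deg2rad(2 * ori)
  mean2 <- atan2(sum(wts * sin(th2)), sum(wts * cos(th2)))
  rel <- wrap_axial(rad2deg(mean2) / 2 - frame$axis_deg)
  if (rel > 90) rel <- rel - 180
  rel
}

#' Mean cortical curvature by preferred-frequency bin
#'
#' Pixels of the ROI are binned by preferred frequency (equal-width or
#' equal-count bins in Cam) and curvature is averaged within each bin.
#'
#' @param roi Logical matrix.
#' @param preferred_map Preferred-frequency map (Cam).
#' @param curvature_map Curvature matrix.
#' @param n_bins Number of bins (default 8).
#' @param binning `"equal_count"` (default) or `"equal_width"`.
#' @return Data frame with `bin_center_cam`, `mean_curvature`, `se`, `n`.
#' @export
curvature_by_frequency <- function(roi, preferred_map, curvature_map,
                                   n_bins = 8,
                                   binning = c("equal_count", "equal_width")) {
  binning <- match.arg(binning)
  if (!any(roi)) stop("curvature_by_frequency: empty ROI")
  ok <- roi & !is.na(preferred_map) & !is.na(curvature_map)
  f <- preferred_map[ok]; k <- curvature_map[ok]
  brks <- if (binning == "equal_count")
    unique(stats::quantile(f, probs = seq(0, 1, length.out = n_bins + 1)))
  else seq(min(f), max(f), length.out = n_bins + 1)
  bin <- cut(f, brks, include.lowest = TRUE)
  agg <- function(v, fn) as.numeric(tapply(v, bin, fn))
  n <- agg(k, length)
  data.frame(bin_center_cam = agg(f, mean),
             mean_curvature = agg(k, mean),
             se = agg(k, stats::sd) / sqrt(n),
             n = ifelse(is.na(n), 0L, n))
}
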