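#' Tonotopic gradient vector fields and gradient-reversal detection
#'
#' A vector field is stored as a list with `gx`, `gy` component matrices (in
#' map units per pixel) and a logical `mask` of pixels where the field is
#' defined. Directions follow the package convention: degrees CCW from the
#' +x (first index) axis.
#'
#' @name gradient_analysis
NULL

#' 2D Sobel gradient field of a masked map
#'
#' Computes local gradient vectors between each pixel and its immediate
#' neighbors with the standard 3x3 Sobel kernels (scaled so that a unit/pixel
#' linear ramp has unit gradient magnitude). Pixels whose 3x3 neighborhood
#' leaves the mask (or the grid) are marked invalid.
#'
#' @param map Numeric matrix; `NA` entries are treated as outside the mask.
#' @param mask Optional logical matrix; defaults to `!is.na(map)`.
#' @return A list of class `vector_field` with `gx`, `gy`, `mask`.
#' @export
sobel_field <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(map)
  m <- map
  m[!mask] <- NA
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(NA_real_, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  sh <- function(dx, dy) pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  # Sobel: derivative along one axis, smoothing [1 2 1] along the other; /8
  # normalizes to map units per pixel.
  gx <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1)) / 8
  gy <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1)) / 8
  valid <- !is.na(gx) & !is.na(gy)
  gx[!valid] <- NA; gy[!valid] <- NA
  structure(list(gx = gx, gy = gy, mask = valid), class = "vector_field")
}

#' Direction map (degrees) of a vector field
#' @param field A `vector_field`.
#' @return Matrix of directions in (-180, 180]; `NA` off-mask or where the
#'   vector is zero.
#' @export
field_direction <- function(field) {
  d <- rad2deg(atan2(field$gy, field$gx))
  d[!field$mask | (field$gx == 0 & field$gy == 0)] <- NA
  d
}

# 1D Gaussian kernel for a FWHM given in pixels.
gaussian_kernel_1d <- function(fwhm_px) {
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D convolution of a matrix with zero padding, via banded
# multiplication matrices (grids here are small).
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  band <- function(n) {
    B <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- k[off + r + 1L]
    }
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Mask-aware Gaussian smoothing of maps and vector fields
#'
#' Normalized convolution: the Gaussian kernel is renormalized over the
#' in-mask support at every pixel, so constants are preserved on any mask and
#' no off-mask values leak in. Vector fields are smoothed componentwise.
#' `fwhm_mm = 0` is the identity.
#'
#' @param data Numeric matrix (`NA` = off-mask) or a `vector_field`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (`>= 0`).
#' @param pixel_mm Pixel size in mm (default 0.33).
#' @return Smoothed object of the same kind; mask unchanged.
#' @export
smooth_map_or_field <- function(data, fwhm_mm, pixel_mm = 0.33) {
  stopifnot(fwhm_mm >= 0, pixel_mm > 0)
  if (inherits(data, "vector_field")) {
    out <- data
    out$gx <- smooth_map_or_field(data$gx, fwhm_mm, pixel_mm)
    out$gy <- smooth_map_or_field(data$gy, fwhm_mm, pixel_mm)
    return(out)
  }
  if (fwhm_mm == 0) return(data)
  k <- gaussian_kernel_1d(fwhm_mm / pixel_mm)
  mask <- !is.na(data)
  num <- data
  num[!mask] <- 0
  num <- conv_sep(num, k)
  den <- conv_sep(mask * 1, k)
  out <- num / den
  out[!mask] <- NA
  out
}

#' Sign of a vector field projected onto a direction
#'
#' @param field A `vector_field`.
#' @param direction_deg Direction in degrees (CCW from +x).
#' @return Integer matrix in \{-1, 0, +1\}; `NA` off-mask.
#' @export
sign_map <- function(field, direction_deg) {
  u <- unit_vec(direction_deg)
  s <- sign(field$gx * u[1] + field$gy * u[2])
  s[!field$mask] <- NA
  s
}

#' Detect tonotopic gradient reversals
#'
#' For each pixel and each of 180 equidistant orientations theta in
#' 0..179 degrees, the gradient vectors at the two neighbors straddling the
#' pixel along theta (nearest pixel at +/- one unit step) are projected onto
#' theta; a reversal at theta is a strict sign change between the two
#' projections. The per-pixel count of reversal orientations (0-180) is
#' thresholded at `criterion` to give the reversal mask. Reversal pixels are
#' denominated `low` (`-1`) if the preferred frequency is a local minimum
#' along the across-reversal axis (the axial mean orientation of the flanking
#' gradients), `high` (`+1`) if a local maximum, `0` otherwise.
#'
#' @param field A `vector_field` (smooth it first as required; individual
#'   hemisphere maps typically use 6-mm FWHM).
#' @param preferred_map Preferred-frequency map (Cam) used for denomination.
#' @param criterion Minimum number of reversal orientations (default 10).
#' @return A list of class `reversal_map` with `count` (integer matrix),
#'   `mask` (logical), `denomination` (integer matrix -1/0/+1, `NA` outside
#'   the reversal mask) and `criterion`.
#' @export
detect_reversals <- function(field, preferred_map, criterion = 10) {
  if (criterion < 1 || criterion > 180) stop("detect_reversals: criterion must be in [1, 180]")
  nx <- nrow(field$gx); ny <- ncol(field$gx)
  gx <- field$gx; gy <- field$gy
  count <- matrix(0L, nx, ny)

  shift_mat <- function(m, dx, dy) {
    out <- matrix(NA_real_, nx, ny)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }

  s2 <- matrix(0, nx, ny)   # accumulated sin/cos of doubled reversal
  c2 <- matrix(0, nx, ny)   # orientations, for the across-reversal axis

  thetas <- 0:179
  for (th in thetas) {
    u <- unit_vec(th)
    dx <- round(u[1]); dy <- round(u[2])
    p_plus <- shift_mat(gx, dx, dy) * u[1] + shift_mat(gy, dx, dy) * u[2]
    p_minus <- shift_mat(gx, -dx, -dy) * u[1] + shift_mat(gy, -dx, -dy) * u[2]
    rev_th <- !is.na(p_plus) & !is.na(p_minus) & (p_plus * p_minus < 0)
    count <- count + rev_th
    s2 <- s2 + rev_th * sin(deg2rad(2 * th))
    c2 <- c2 + rev_th * cos(deg2rad(2 * th))
  }
  rmask <- field$mask & (count >= criterion)

  # bilinear sample of a map at fractional coordinates (NA if any
  # contributing pixel is off the grid or undefined)
  bilin <- function(map, xi, yi) {
    if (xi < 1 || yi < 1 || xi > nx || yi > ny) return(NA_real_)
    x0 <- floor(xi); y0 <- floor(yi)
    x1 <- min(x0 + 1, nx); y1 <- min(y0 + 1, ny)
    fx <- xi - x0; fy <- yi - y0
    (1 - fx) * (1 - fy) * map[x0, y0] + fx * (1 - fy) * map[x1, y0] +
      (1 - fx) * fy * map[x0, y1] + fx * fy * map[x1, y1]
  }

  denom <- matrix(NA_integer_, nx, ny)
  if (any(rmask)) {
    # across-reversal axis per pixel: axial mean (angle doubling) of the
    # orientations along which reversals were detected, pooled over a small
    # neighborhood (the pooling is count-weighted, which stabilizes the
    # axis at band-flank pixels where few orientations reverse)
    pool <- gaussian_kernel_1d(3)
    s2p <- conv_sep(s2, pool); c2p <- conv_sep(c2, pool)
    idx <- which(rmask, arr.ind = TRUE)
    step <- 1.0    # sampling distance (pixels) for the extremum test
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      axis <- atan2(s2p[i, j], c2p[i, j]) / 2
      ax <- cos(axis); ay <- sin(axis)
      f0 <- preferred_map[i, j]
      f1 <- bilin(preferred_map, i + step * ax, j + step * ay)
      f2 <- bilin(preferred_map, i - step * ax, j - step * ay)
      if (is.na(f0) || is.na(f1) || is.na(f2)) { denom[i, j] <- 0L; next }
      denom[i, j] <- if (f0 <= f1 && f0 <= f2 && (f0 < f1 || f0 < f2)) -1L
                     else if (f0 >= f1 && f0 >= f2 && (f0 > f1 || f0 > f2)) 1L
                     else 0L
    }
  }
  structure(list(count = count, mask = rmask, denomination = denom,
                 criterion = criterion), class = "reversal_map")
}

# 8-connected component labelling of a logical matrix (iterative flood fill).
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nextlab <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (p - 1L) %% nx + 1L
      j <- (p - 1L) %/% nx + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny) {
          q <- ii + (jj - 1L) * nx
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nextlab
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

# Endpoints of a pixel cluster along its own principal axis (2 x 2 matrix).
cluster_endpoints <- function(xy, axis_deg) {
  u <- unit_vec(axis_deg)
  t <- xy %*% u
  rbind(xy[which.min(t), ], xy[which.max(t), ])
}

#' Cluster reversal pixels and join collinear segments
#'
#' Connected components (8-connectivity) are formed separately for each
#' frequency denomination; each cluster's axial orientation is the first
#' right-singular vector of its centred pixel coordinates. Disconnected but
#' collinear clusters (axes within `collinearity_tol_deg`, closest endpoints
#' within `gap_tol_mm`) are interpreted as one reversal and merged.
#'
#' @param rmap A `reversal_map` from [detect_reversals()].
#' @param collinearity_tol_deg Axial tolerance for joining (default 20).
#' @param gap_tol_mm Maximum endpoint gap for joining, in mm (default 3).
#' @param pixel_mm Pixel size in mm.
#' @return List of clusters; each has `pixels` (n x 2 coordinates),
#'   `orientation_deg` (axial), `size`, `denomination` ("low"/"high").
#' @export
cluster_reversals <- function(rmap, collinearity_tol_deg = 20, gap_tol_mm = 3,
                              pixel_mm = 0.33) {
  clusters <- list()
  for (den in c(-1L, 1L)) {
    m <- rmap$mask & !is.na(rmap$denomination) & rmap$denomination == den
    if (!any(m)) next
    lab <- label_components(m)
    for (l in seq_len(max(lab))) {
      xy <- mask_coords(lab == l)
      ori <- if (nrow(xy) > 1) principal_axis(xy)$axis_deg else 0
      clusters[[length(clusters) + 1L]] <- list(
        pixels = xy, orientation_deg = ori, size = nrow(xy),
        denomination = if (den == -1L) "low" else "high")
    }
  }
  if (length(clusters) < 2) return(clusters)

  gap_px <- gap_tol_mm / pixel_mm
  repeat {
    merged <- FALSE
    n <- length(clusters)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- clusters[[i]]; b <- clusters[[j]]
        if (a$denomination != b$denomination) next
        if (axial_diff(a$orientation_deg, b$orientation_deg) > collinearity_tol_deg) next
        ea <- cluster_endpoints(a$pixels, a$orientation_deg)
        eb <- cluster_endpoints(b$pixels, b$orientation_deg)
        d <- min(sqrt(outer(ea[, 1], eb[, 1], "-")^2 + outer(ea[, 2], eb[, 2], "-")^2))
        if (d > gap_px) next
        xy <- rbind(a$pixels, b$pixels)
        clusters[[i]] <- list(pixels = xy,
                              orientation_deg = principal_axis(xy)$axis_deg,
                              size = nrow(xy), denomination = a$denomination)
        clusters[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}
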