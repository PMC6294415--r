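#' Structural (myelin-sensitive) map conditioning
#'
#' MTR computation, linear removal of nuisance covariates (PD-proxy for B1,
#' cortical curvature, thickness), depth averaging and depth profiles.
#' Depth stacks are arrays `[nx, ny, n_depth]` with depth fractions running
#' from 0 (gray/white border) to 1 (pial surface).
#'
#' @name structural_maps
NULL

#' Magnetization transfer ratio
#'
#' `MTR = (M0 - MSAT) / M0`, elementwise; pixels with `M0 <= 0` are invalid.
#'
#' @param m0_map,msat_map Unsaturated / saturated magnetization maps.
#' @return MTR matrix (`NA` where invalid).
#' @export
mtr <- function(m0_map, msat_map) {
  stopifnot(all(dim(m0_map) == dim(msat_map)))
  out <- (m0_map - msat_map) / m0_map
  out[!is.na(m0_map) & m0_map <= 0] <- NA
  out
}

#' Regress nuisance covariates out of a depth stack
#'
#' Per depth, an ordinary least-squares regression of the map on the
#' covariates (plus intercept) over the mask; the output is the residual
#' plus the fitted intercept, so the map's mean level is preserved for
#' subsequent thresholding. The per-depth R-squared of the regression is
#' reported. Residuals are orthogonal to the covariates, so the operation
#' is idempotent.
#'
#' @param stack Array `[nx, ny, n_depth]` or a single matrix.
#' @param covariates Named list of matrices (e.g. `pd_proxy`, `curvature`,
#'   `thickness`); all must be finite on the mask.
#' @param mask Optional logical matrix (default: pixels finite in the stack
#'   and all covariates).
#' @return List with `stack` (residualized) and `r2` (per-depth vector).
#' @export
residualize <- function(stack, covariates, mask = NULL) {
  single <- length(dim(stack)) == 2 || is.null(dim(stack))
  if (single) stack <- array(stack, c(dim(as.matrix(stack)), 1))
  nd <- dim(stack)[3]
  cov_mat <- do.call(cbind, lapply(covariates, as.vector))
  if (is.null(mask)) {
    mask_v <- rowSums(!is.finite(cov_mat)) == 0 & is.finite(as.vector(stack[, , 1]))
  } else mask_v <- as.vector(mask)
  idx <- which(mask_v)
  if (length(idx) < ncol(cov_mat) + 2)
    stop("residualize: too few in-mask pixels for the covariate model")
  X <- cbind(1, cov_mat[idx, , drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    # identify an offending covariate by leave-one-in rank checks
    nm <- names(covariates)
    stop("residualize: collinear covariates among: ", paste(nm, collapse = ", "))
  }
  out <- stack
  r2 <- numeric(nd)
  for (d in seq_len(nd)) {
    y <- as.vector(stack[, , d])[idx]
    cf <- qr.coef(qrx, y)
    fitted <- drop(X %*% cf)
    res <- y - fitted
    sl <- as.vector(stack[, , d])
    sl[idx] <- res + mean(y)      # mean level preserved for thresholding
    sl[!mask_v] <- NA
    out[, , d] <- sl
    tss <- sum((y - mean(y))^2)
    r2[d] <- if (tss > 0) 1 - sum(res^2) / tss else 0
  }
  list(stack = if (single) out[, , 1] else out, r2 = r2)
}

#' Depth-average a stack over a depth-fraction range
#'
#' Unweighted mean over the depths whose fraction lies in `range`
#' (default the middle five of eleven, 0.3-0.7), followed by optional
#' minimal surface smoothing (default ~2-mm FWHM).
#'
#' @param stack Array `[nx, ny, n_depth]`.
#' @param range Depth-fraction range included (default `c(0.3, 0.7)`).
#' @param depth_fractions Fractions of the stack's depths (default
#'   equidistant 0..1).
#' @param smooth_fwhm_mm Smoothing after averaging (0 = none; default 2).
#' @param pixel_mm Pixel size in mm.
#' @return Matrix.
#' @export
depth_average <- function(stack, range = c(0.3, 0.7),
                          depth_fractions = seq(0, 1, length.out = dim(stack)[3]),
                          smooth_fwhm_mm = 2, pixel_mm = 0.33) {
  use <- which(depth_fractions >= range[1] - 1e-9 &
               depth_fractions <= range[2] + 1e-9)
  if (!length(use)) stop("depth_average: no depths in the requested range")
  m <- apply(stack[, , use, drop = FALSE], c(1, 2), mean)
  if (smooth_fwhm_mm > 0) m <- smooth_map_or_field(m, smooth_fwhm_mm, pixel_mm)
  m
}

#' ROI-mean depth profile
#'
#' Mean of the stack within the ROI at each depth. When a list of stacks
#' (a cohort) is given, the across-hemisphere mean and standard error are
#' returned.
#'
#' @param stack Array `[nx, ny, n_depth]`, or a list of such arrays.
#' @param roi Logical matrix (or list of matrices, one per hemisphere).
#' @param depth_fractions Depth fractions (for labelling).
#' @return Data frame with `depth`, `mean` and (cohort case) `se`.
#' @export
depth_profile <- function(stack, roi,
                          depth_fractions = NULL) {
  if (is.list(stack)) {
    rois <- if (is.list(roi)) roi else rep(list(roi), length(stack))
    profs <- mapply(function(s, r) depth_profile(s, r, depth_fractions)$mean,
                    stack, rois)
    df <- depth_profile(stack[[1]], rois[[1]], depth_fractions)
    data.frame(depth = df$depth, mean = rowMeans(profs),
               se = apply(profs, 1, stats::sd) / sqrt(ncol(profs)))
  } else {
    if (!any(roi)) stop("depth_profile: empty ROI")
    nd <- dim(stack)[3]
    if (is.null(depth_fractions)) depth_fractions <- seq(0, 1, length.out = nd)
    m <- vapply(seq_len(nd), function(d) mean(stack[, , d][roi], na.rm = TRUE), 0)
    data.frame(depth = depth_fractions, mean = m)
  }
}
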