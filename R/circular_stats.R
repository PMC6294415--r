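#' Circular and axial statistics, Hotelling T-squared consistency testing
#'
#' Directional angles are degrees in (-180, 180]; axial orientations (axes,
#' defined modulo 180) are degrees in [0, 180) and are always processed via
#' angle doubling.
#'
#' @name circular_stats
NULL

#' Circular mean with confidence interval
#'
#' Mean direction is the argument of the resultant vector. The confidence
#' interval half-width follows the standard Fisher-style circular CI (the
#' construction used by common circular-statistics toolboxes): with
#' resultant length `R = n * rbar` and `c2 = qchisq(level, 1)`,
#' `t = sqrt(2*n*(2*R^2 - n*c2)/(4*n - c2))` when `rbar < 0.9`, and
#' `t = sqrt(n^2 - (n^2 - R^2)*exp(c2/n))` when `rbar >= 0.9`; the half-width
#' is `acos(t/R)`. When the sample is too dispersed for the construction
#' (`rbar <= sqrt(c2/(2*n))`) the CI is undefined and `NA` is returned with a
#' warning.
#'
#' @param angles_deg Directional angles in degrees, `n >= 2`.
#' @param level Confidence level (default 0.95).
#' @return List with `mean_deg`, `ci_halfwidth_deg`, `rbar` (mean resultant
#'   length) and `n`.
#' @export
circ_mean_ci <- function(angles_deg, level = 0.95) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 2) stop("circ_mean_ci: need at least 2 angles")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  mean_deg <- wrap_angle(rad2deg(atan2(S, C)))
  R <- n * rbar
  c2 <- stats::qchisq(level, df = 1)
  if (rbar <= sqrt(c2 / (2 * n))) {
    warning("circ_mean_ci: resultant length too small; CI undefined")
    hw <- NA_real_
  } else {
    t <- if (rbar < 0.9) sqrt(2 * n * (2 * R^2 - n * c2) / (4 * n - c2))
         else sqrt(n^2 - (n^2 - R^2) * exp(c2 / n))
    hw <- rad2deg(acos(pmin(1, t / R)))
  }
  list(mean_deg = mean_deg, ci_halfwidth_deg = hw, rbar = rbar, n = n)
}

#' Axial mean with confidence interval
#'
#' Orientations are doubled, passed through [circ_mean_ci()], and the mean
#' and CI half-width halved.
#'
#' @param orientations_deg Axial orientations in degrees (modulo 180).
#' @inheritParams circ_mean_ci
#' @return As [circ_mean_ci()], with `mean_deg` in [0, 180).
#' @export
axial_mean_ci <- function(orientations_deg, level = 0.95) {
  res <- circ_mean_ci(2 * orientations_deg, level = level)
  res$mean_deg <- wrap_axial(res$mean_deg / 2)
  res$ci_halfwidth_deg <- res$ci_halfwidth_deg / 2
  res
}

#' One-sample Hotelling T-squared test for 2D vectors
#'
#' Tests whether the population mean of a sample of 2D vectors is zero.
#' `T2 = n * xbar' S^-1 xbar` with sample covariance `S`; the p-value uses
#' `F = (n - 2) / (2 * (n - 1)) * T2` with (2, n - 2) degrees of freedom.
#'
#' @param vectors n x 2 matrix of vectors, `n >= 3`.
#' @return List with `t2`, `p`, `n`.
#' @export
hotelling_t2 <- function(vectors) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 3) stop("hotelling_t2: need at least 3 vectors")
  xbar <- colMeans(vectors)
  S <- stats::cov(vectors)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det_s) || det_s <= 0) stop("hotelling_t2: singular sample covariance")
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det_s
  t2 <- n * drop(t(xbar) %*% Sinv %*% xbar)
  f <- (n - 2) / (2 * (n - 1)) * t2
  p <- stats::pf(f, 2, n - 2, lower.tail = FALSE)
  list(t2 = t2, p = p, n = n)
}

#' Pixelwise consistency of gradient directions across hemispheres
#'
#' Each hemisphere's vector field (already expressed in its own HG frame so
#' directions are comparable) is smoothed, then every pixel with at least 3
#' valid hemispheres is tested against zero with the one-sample Hotelling
#' T-squared test. P-values are FDR-adjusted over the responsive mask with
#' the shared adaptive step-up routine, and the group-average vector field
#' (pixelwise vector mean) is returned alongside.
#'
#' @param fields List of `vector_field` objects sharing one grid.
#' @param responsive_mask Logical matrix; the FDR domain.
#' @param smoothing_fwhm_mm Per-hemisphere smoothing before testing
#'   (default 3).
#' @param q FDR level (default 0.05).
#' @param pixel_mm Pixel size in mm.
#' @param fdr_method Passed to [fdr_select()].
#' @return List with `t2`, `p` (matrices), `significant` (logical matrix),
#'   `mean_field` (a `vector_field`), `n_valid` (matrix).
#' @export
consistency_map <- function(fields, responsive_mask, smoothing_fwhm_mm = 3,
                            q = 0.05, pixel_mm = 0.33, fdr_method = "tsbh") {
  if (length(fields) < 3) stop("consistency_map: need at least 3 hemispheres")
  sm <- lapply(fields, smooth_map_or_field, fwhm_mm = smoothing_fwhm_mm,
               pixel_mm = pixel_mm)
  nx <- nrow(sm[[1]]$gx); ny <- ncol(sm[[1]]$gx)
  H <- length(sm)
  GX <- vapply(sm, function(f) f$gx, matrix(0, nx, ny))
  GY <- vapply(sm, function(f) f$gy, matrix(0, nx, ny))
  dim(GX) <- c(nx * ny, H); dim(GY) <- c(nx * ny, H)
  ok <- is.finite(GX) & is.finite(GY)
  GX[!ok] <- NA; GY[!ok] <- NA
  nval <- rowSums(ok)

  mx <- rowMeans(GX, na.rm = TRUE); my <- rowMeans(GY, na.rm = TRUE)
  # pixelwise covariance terms
  cxx <- rowSums((GX - mx)^2, na.rm = TRUE) / (nval - 1)
  cyy <- rowSums((GY - my)^2, na.rm = TRUE) / (nval - 1)
  cxy <- rowSums((GX - mx) * (GY - my), na.rm = TRUE) / (nval - 1)
  det_s <- cxx * cyy - cxy^2
  t2 <- nval * (mx^2 * cyy - 2 * mx * my * cxy + my^2 * cxx) / det_s
  usable <- nval >= 3 & is.finite(det_s) & det_s > 0
  t2[!usable] <- NA
  f <- (nval - 2) / (2 * (nval - 1)) * t2
  p <- stats::pf(f, 2, nval - 2, lower.tail = FALSE)

  domain <- as.vector(responsive_mask) & !is.na(p)
  signif_v <- rep(FALSE, nx * ny)
  if (any(domain)) signif_v[domain] <- fdr_select(p[domain], q = q, method = fdr_method)

  shape <- function(v) matrix(v, nx, ny)
  mean_mask <- shape(usable)
  mxm <- shape(mx); mym <- shape(my)
  mxm[!mean_mask] <- NA; mym[!mean_mask] <- NA
  list(t2 = shape(t2), p = shape(p), significant = shape(signif_v),
       mean_field = structure(list(gx = mxm, gy = mym, mask = mean_mask),
                              class = "vector_field"),
       n_valid = shape(nval))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used for coverage simulations and
#' synthetic direction cohorts.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (`>= 0`; 0 gives the circular uniform).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop("rvonmises: kappa must be non-negative")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -180, 180)))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(rad2deg(out))
}
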