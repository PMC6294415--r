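#' Voxel tuning-curve analysis: debiased preferred frequency and tuning width
#'
#' Tuning curves are 7 response amplitudes (percent signal change) at the 7
#' stimulus positions expressed on the Cam (ERB-number) scale. Centroids are
#' biased towards the middle of the stimulus range; the debiasing procedure
#' matches each measured curve's (centroid, spread) pair against a bank of
#' hypothetical Gaussian tuning curves and returns the mode of the best
#' match as the unbiased preferred-frequency estimate.
#'
#' @name tuning_analysis
NULL

# Clip betas at zero; rows with no positive weight get all-zero weights.
clip_weights <- function(beta) {
  w <- pmax(beta, 0)
  w[is.na(w)] <- 0
  w
}

#' Tuning-curve centroid
#'
#' `C = sum(max(beta, 0) * F) / sum(max(beta, 0))` with `F` the stimulus
#' positions in Cam. Negative amplitudes are thresholded at zero; curves
#' without any positive amplitude have no defined centroid (`NA`).
#'
#' @param beta Numeric vector of amplitudes, or a matrix (curves in rows).
#' @param freq_cam Stimulus positions in Cam (length = curve length).
#' @return Centroid(s) in Cam.
#' @export
tuning_centroid <- function(beta, freq_cam) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  w <- clip_weights(beta)
  tot <- rowSums(w)
  out <- as.vector(w %*% freq_cam) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Tuning-curve spread
#'
#' Default reading (`form = "sd"`): weighted standard deviation
#' `S = sqrt(sum(w * (F - C)^2) / sum(w))` with `w = max(beta, 0)`.
#' `form = "literal"` evaluates the unweighted-numerator variant
#' `S = sum((F - C)^2) / sum(beta)` (no radical), retained as a
#' configuration option.
#'
#' @inheritParams tuning_centroid
#' @param form `"sd"` (default) or `"literal"`.
#' @return Spread(s) in Cam.
#' @export
tuning_spread <- function(beta, freq_cam, form = c("sd", "literal")) {
  form <- match.arg(form)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  C <- tuning_centroid(beta, freq_cam)
  w <- clip_weights(beta)
  tot <- rowSums(w)
  dev2 <- outer(C, freq_cam, function(c, f) (f - c)^2)
  if (form == "sd") {
    out <- sqrt(rowSums(w * dev2) / tot)
  } else {
    out <- rowSums(dev2) / rowSums(beta)
  }
  out[tot == 0] <- NA_real_
  out
}

#' Bank of hypothetical Gaussian tuning curves
#'
#' Gaussians on the Cam scale with modes spanning the audible range (default
#' 0 to 16.2 kHz in 0.1-Cam steps) and widths (SDs) from 0.4 to 20 ERB_N
#' (geometric grid, 60 steps). Each entry is sampled at the stimulus
#' positions and its centroid and spread computed exactly as for measured
#' curves. Entries are ordered by (mode, width) so that distance ties during
#' matching resolve toward the smaller mode, then the smaller width.
#'
#' @param stim_freqs_hz Stimulus frequencies in Hz.
#' @param mode_step_cam Mode grid step in Cam (default 0.1).
#' @param mode_max_hz Upper end of the mode range in Hz (default 16200).
#' @param width_range ERB_N width range (default `c(0.4, 20)`).
#' @param n_width Number of geometric width steps (default 60).
#' @param scale A [cochlear_scale()].
#' @return A `gaussian_bank` list with `mode`, `width`, `C`, `S`,
#'   `curves` (entries x 7) and `freq_cam`.
#' @export
gaussian_bank <- function(stim_freqs_hz = default_stim_frequencies(),
                          mode_step_cam = 0.1, mode_max_hz = 16200,
                          width_range = c(0.4, 20), n_width = 60,
                          scale = cochlear_scale()) {
  stopifnot(mode_step_cam > 0, n_width >= 2, width_range[1] > 0,
            width_range[2] > width_range[1])
  freq_cam <- hz_to_cam(stim_freqs_hz, scale)
  modes <- seq(0, hz_to_cam(mode_max_hz, scale), by = mode_step_cam)
  widths <- exp(seq(log(width_range[1]), log(width_range[2]),
                    length.out = n_width))
  grid <- expand.grid(width = widths, mode = modes)  # mode slowest => sorted by mode then width
  grid <- grid[order(grid$mode, grid$width), ]
  curves <- exp(-outer(grid$mode, freq_cam, "-")^2 / (2 * grid$width^2))
  C <- tuning_centroid(curves, freq_cam)
  S <- tuning_spread(curves, freq_cam)
  stopifnot(all(is.finite(C)), all(is.finite(S)))
  structure(list(mode = grid$mode, width = grid$width, C = C, S = S,
                 curves = curves, freq_cam = freq_cam,
                 mode_step_cam = mode_step_cam),
            class = "gaussian_bank")
}

# Nearest bank entry in the (C, S) plane for each (C, S) pair; exact
# brute-force search (compiled), first minimum on ties (the bank is
# (mode, width)-ordered, so ties resolve toward smaller mode, then width).
bank_match <- function(C, S, bank) {
  nearest_cs(C, S, bank$C, bank$S)
}

#' Debiased preferred-frequency estimate
#'
#' Pairs each measured curve with the bank entry minimizing
#' `(C - C_b)^2 + (S - S_b)^2` (both coordinates in Cam) and returns that
#' entry's mode. Ties resolve toward the smaller mode, then smaller width.
#'
#' @param beta Amplitude vector, or matrix with curves in rows.
#' @param bank A [gaussian_bank()].
#' @return Debiased mode(s) in Cam; `NA` where the curve has no defined
#'   centroid.
#' @export
debias <- function(beta, bank) {
  if (!inherits(bank, "gaussian_bank")) stop("debias: empty or invalid bank")
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  C <- tuning_centroid(beta, bank$freq_cam)
  S <- tuning_spread(beta, bank$freq_cam)
  bank$mode[bank_match(C, S, bank)]
}

#' Debiased preferred-frequency map from a beta stack
#'
#' Runs the debiasing on every pixel and depth, then averages the debiased
#' estimates over the requested cortical depths (default the middle five of
#' eleven, depth fractions 0.3-0.7). No surface smoothing is applied, to
#' retain maximal spatial detail.
#'
#' @param betas Array `[nx, ny, depth, 7]` of response amplitudes.
#' @param bank A [gaussian_bank()].
#' @param depths_use Indices of depths to average (default `4:8` of 11).
#' @param mask Optional logical matrix restricting the computation.
#' @return Matrix of preferred frequencies in Cam (`NA` where undefined).
#' @export
preferred_frequency_map <- function(betas, bank, depths_use = 4:8, mask = NULL) {
  nx <- dim(betas)[1]; ny <- dim(betas)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  pix <- which(mask)
  acc <- matrix(0, length(pix), length(depths_use))
  for (k in seq_along(depths_use)) {
    d <- depths_use[k]
    B <- matrix(betas[, , d, ], nx * ny, dim(betas)[4])[pix, , drop = FALSE]
    acc[, k] <- debias(B, bank)
  }
  est <- rowMeans(acc, na.rm = TRUE)
  est[!is.finite(est)] <- NA
  out <- matrix(NA_real_, nx, ny)
  out[pix] <- est
  out
}

# Solve min ||y - h*g - o|| over (h, o) for many pixels at once given shared
# basis sums; returns h, o, rss. NA samples enter with zero weight.
profile_linear <- function(Y, W, g) {
  # Y: npix x 7 (NA -> 0), W: npix x 7 indicator, g: length-7 basis
  n1 <- rowSums(W)
  gg <- W %*% (g * g)
  g1 <- W %*% g
  gy <- Y %*% g
  y1 <- rowSums(Y)
  yy <- rowSums(Y^2)
  det <- gg * n1 - g1^2
  h <- (gy * n1 - g1 * y1) / det
  o <- (y1 * gg - g1 * gy) / det
  # constraints: offset <= 0, height >= 0
  redo <- !is.na(o) & o > 0
  h[redo] <- pmax(0, gy[redo] / gg[redo])
  o[redo] <- 0
  h[!is.na(h) & h < 0] <- 0
  o2 <- ifelse(h == 0, pmin(0, y1 / n1), o)
  rss <- yy - 2 * h * gy - 2 * o2 * y1 + h^2 * gg + 2 * h * o2 * g1 + o2^2 * n1
  list(h = h, o = o2, rss = rss)
}

#' Tuning-width map from depth stacks of tuning curves
#'
#' Per pixel and depth, the curve is recentred to its centroid rounded to
#' the nearest stimulus position (integer index shift; vacated samples are
#' missing and excluded), curves are averaged across all depths, the 7
#' aligned sample maps are smoothed spatially (default ~3-mm FWHM), and a
#' 4-parameter Gaussian (mode, width, height, non-positive baseline offset)
#' is fitted to each pixel's aligned curve by least squares. The fit
#' profiles the linear parameters exactly on a dense (mode, width) grid and
#' polishes the solution with a vectorized Gauss-Newton refinement; widths
#' are bounded to [0.4, 20] ERB_N. Degenerate fits (no positive response)
#' are marked invalid.
#'
#' @param betas Array `[nx, ny, depth, 7]`.
#' @param freq_cam Stimulus positions in Cam.
#' @param smoothing_fwhm_mm Spatial smoothing of aligned curves (default 3).
#' @param pixel_mm Pixel size in mm.
#' @param mask Optional logical matrix restricting the computation.
#' @param width_bounds Width bounds in ERB_N (default `c(0.4, 20)`).
#' @param refine Run the Gauss-Newton polish (default `TRUE`).
#' @return List with `width` (ERB_N map), `mode`, `height`, `offset`, `rss`.
#' @export
tuning_width_map <- function(betas, freq_cam, smoothing_fwhm_mm = 3,
                             pixel_mm = 0.33, mask = NULL,
                             width_bounds = c(0.4, 20), refine = TRUE) {
  nx <- dim(betas)[1]; ny <- dim(betas)[2]
  nd <- dim(betas)[3]; nf <- dim(betas)[4]
  ctr <- (nf + 1L) %/% 2L
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)

  # --- recentre and depth-average ---------------------------------------
  sum_al <- array(0, c(nx * ny, nf))
  cnt_al <- array(0L, c(nx * ny, nf))
  for (d in seq_len(nd)) {
    B <- matrix(betas[, , d, ], nx * ny, nf)
    C <- tuning_centroid(B, freq_cam)
    Cf <- ifelse(is.na(C), freq_cam[ctr], C)
    near <- max.col(-abs(outer(Cf, freq_cam, "-")), ties.method = "first")
    near[is.na(C)] <- NA
    shift <- ctr - near
    for (s in sort(unique(shift[!is.na(shift)]))) {
      rows <- which(!is.na(shift) & shift == s)
      src <- seq_len(nf) - s
      okj <- src >= 1 & src <= nf
      vals <- B[rows, src[okj], drop = FALSE]
      okv <- !is.na(vals)
      tgt <- which(okj)
      sum_al[rows, tgt] <- sum_al[rows, tgt] + ifelse(okv, vals, 0)
      cnt_al[rows, tgt] <- cnt_al[rows, tgt] + okv
    }
  }
  avg <- sum_al / cnt_al
  avg[cnt_al == 0] <- NA

  # --- spatial smoothing of each aligned sample map ---------------------
  if (smoothing_fwhm_mm > 0) {
    for (j in seq_len(nf)) {
      m <- matrix(avg[, j], nx, ny)
      m[!mask] <- NA
      avg[, j] <- as.vector(smooth_map_or_field(m, smoothing_fwhm_mm, pixel_mm))
    }
  }

  pix <- which(mask)
  Yna <- avg[pix, , drop = FALSE]
  Wp <- (!is.na(Yna)) * 1
  Y <- Yna; Y[is.na(Y)] <- 0
  enough <- rowSums(Wp) >= 5           # need headroom over the 4 parameters
  npix <- length(pix)

  # --- profiled grid search over (mode, width) --------------------------
  # The objective has two basins for wide curves (the mode shifted by one
  # stimulus spacing, compensated by height and offset), so the best grid
  # point is kept separately for modes below and above the central
  # stimulus; both starts are polished and the better final fit wins.
  modes <- seq(freq_cam[ctr] - 4.5, freq_cam[ctr] + 4.5, by = 0.25)
  widths <- exp(seq(log(width_bounds[1]), log(width_bounds[2]), length.out = 40))
  new_best <- function() list(rss = rep(Inf, npix), m = rep(NA_real_, npix),
                              w = rep(NA_real_, npix), h = rep(NA_real_, npix),
                              o = rep(NA_real_, npix))
  bestL <- new_best(); bestR <- new_best()
  for (m0 in modes) for (w0 in widths) {
    g <- exp(-(freq_cam - m0)^2 / (2 * w0^2))
    fit <- profile_linear(Y, Wp, g)
    if (m0 < freq_cam[ctr]) {
      upd <- is.finite(fit$rss) & fit$rss < bestL$rss
      bestL$rss[upd] <- fit$rss[upd]; bestL$m[upd] <- m0; bestL$w[upd] <- w0
      bestL$h[upd] <- fit$h[upd]; bestL$o[upd] <- fit$o[upd]
    } else {
      upd <- is.finite(fit$rss) & fit$rss < bestR$rss
      bestR$rss[upd] <- fit$rss[upd]; bestR$m[upd] <- m0; bestR$w[upd] <- w0
      bestR$h[upd] <- fit$h[upd]; bestR$o[upd] <- fit$o[upd]
    }
  }
  take <- bestR$rss < bestL$rss
  best <- lapply(names(bestL), function(nm) ifelse(take, bestR[[nm]], bestL[[nm]]))
  names(best) <- names(bestL)

  # --- vectorized Gauss-Newton polish on (mode, width) ------------------
  # The linear parameters are profiled out exactly at every candidate
  # (mode, width); the two nonlinear parameters take damped Gauss-Newton
  # steps with vectorized backtracking (factors 1, 1/2, 1/4, 1/8), each
  # pixel iterating until its fit stops improving.
  if (refine) {
    # profiled solve with pixel-specific bases on a row subset
    solve_at <- function(m, w, Ys, Ws) {
      np <- length(m)
      D <- outer(rep(1, np), freq_cam) - m
      G <- exp(-D^2 / (2 * w^2))
      n1 <- rowSums(Ws); gg <- rowSums(Ws * G^2); g1 <- rowSums(Ws * G)
      gy <- rowSums(Ws * G * Ys); y1 <- rowSums(Ws * Ys)
      det <- gg * n1 - g1^2
      h <- (gy * n1 - g1 * y1) / det
      o <- (y1 * gg - g1 * gy) / det
      redo <- !is.na(o) & o > 0
      h[redo] <- pmax(0, gy[redo] / gg[redo]); o[redo] <- 0
      h[!is.na(h) & h < 0] <- 0
      o[h == 0] <- pmin(0, y1[h == 0] / n1[h == 0])
      list(h = h, o = o, G = G, D = D,
           rss = rowSums((Ws * (Ys - h * G - o))^2))
    }
    # damped Gauss-Newton with an active set: each pixel iterates until its
    # fit stops improving, dropping out of the working set when done
    polish_from <- function(m, w) {
      full <- solve_at(m, w, Y, Wp)
      act <- which(is.finite(full$rss))
      for (it in 1:300) {
        if (!length(act)) break
        Ys <- Y[act, , drop = FALSE]; Ws <- Wp[act, , drop = FALSE]
        cur <- solve_at(m[act], w[act], Ys, Ws)
        r <- Ws * (Ys - cur$h * cur$G - cur$o)
        Jm <- -cur$h * cur$G * cur$D / w[act]^2
        Jw <- -cur$h * cur$G * cur$D^2 / w[act]^3
        a11 <- rowSums(Ws * Jm^2); a12 <- rowSums(Ws * Jm * Jw)
        a22 <- rowSums(Ws * Jw^2)
        b1 <- -rowSums(r * Jm); b2 <- -rowSums(r * Jw)
        detA <- a11 * a22 - a12^2
        dm <- (a22 * b1 - a12 * b2) / detA
        dw <- (a11 * b2 - a12 * b1) / detA
        bad <- !is.finite(dm) | !is.finite(dw) | !is.finite(cur$h) | cur$h <= 0
        dm[bad] <- 0; dw[bad] <- 0
        dm <- pmax(pmin(dm, 2), -2); dw <- pmax(pmin(dw, 2), -2)
        ma <- m[act]; wa <- w[act]
        improved <- rep(FALSE, length(act))
        for (fac in c(1, 0.5, 0.25, 0.125)) {
          m_try <- pmin(max(modes), pmax(min(modes), ma + fac * dm))
          w_try <- pmin(width_bounds[2], pmax(width_bounds[1], wa + fac * dw))
          m_new <- ifelse(improved, ma, m_try)
          w_new <- ifelse(improved, wa, w_try)
          cand <- solve_at(m_new, w_new, Ys, Ws)
          acc <- !improved & is.finite(cand$rss) &
            cand$rss < cur$rss - 1e-11 * (1 + cur$rss)
          if (any(acc)) {
            ma[acc] <- m_new[acc]; wa[acc] <- w_new[acc]
            improved <- improved | acc
          }
        }
        m[act] <- ma; w[act] <- wa
        act <- act[improved]
      }
      final <- solve_at(m, w, Y, Wp)
      list(rss = final$rss, m = m, w = w, h = final$h, o = final$o)
    }
    pL <- polish_from(ifelse(is.finite(bestL$rss), bestL$m, best$m),
                      ifelse(is.finite(bestL$rss), bestL$w, best$w))
    pR <- polish_from(ifelse(is.finite(bestR$rss), bestR$m, best$m),
                      ifelse(is.finite(bestR$rss), bestR$w, best$w))
    take2 <- is.finite(pR$rss) & (!is.finite(pL$rss) | pR$rss < pL$rss)
    best <- lapply(names(pL), function(nm) ifelse(take2, pR[[nm]], pL[[nm]]))
    names(best) <- names(pL)
  }

  # degenerate inputs: flat curves carry no tuning information
  flat <- apply(Yna, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && (max(v) - min(v)) <= 1e-10 * (1 + max(abs(v)))
  })
  invalid <- !enough | flat | !is.finite(best$h) | best$h <= 1e-8
  shape <- function(v) { out <- matrix(NA_real_, nx, ny); out[pix] <- ifelse(invalid, NA, v); out }
  list(width = shape(best$w), mode = shape(best$m), height = shape(best$h),
       offset = shape(best$o), rss = shape(best$rss))
}

#' Split-half reliability of debiased preferred-frequency maps
#'
#' Runs the debiasing on two halves of a dataset and returns the Pearson
#' correlation of the two maps over pixels defined in both.
#'
#' @param betas_a,betas_b Beta arrays `[nx, ny, depth, 7]` for the halves,
#'   on the same grid and mask.
#' @param bank A [gaussian_bank()].
#' @param depths_use Depths averaged per half (default `4:8`).
#' @param mask Optional logical matrix.
#' @return Pearson correlation coefficient.
#' @export
split_half <- function(betas_a, betas_b, bank, depths_use = 4:8, mask = NULL) {
  ma <- preferred_frequency_map(betas_a, bank, depths_use, mask)
  mb <- preferred_frequency_map(betas_b, bank, depths_use, mask)
  ok <- !is.na(ma) & !is.na(mb)
  if (sum(ok) < 3) stop("split_half: fewer than 3 pixels defined in both halves")
  stats::cor(ma[ok], mb[ok])
}
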