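#' GLM estimation of frequency responses from sparse-fMRI trial series
#'
#' The sparse protocol acquires one volume per trial (TR 7.5 s); each trial
#' presents one of the 7 stimulus frequencies or silence. Per-run series are
#' high-pass filtered (0.01 Hz), converted to percent signal change relative
#' to the run average, concatenated, and fitted with an ordinary
#' least-squares GLM containing one indicator regressor per stimulus
#' frequency; the intercept(s) model the silence baseline, so each beta is
#' the condition response relative to silence.
#'
#' @name response_model
NULL

#' Trial table for a sparse acquisition
#'
#' @param conditions Character vector per trial: `"freq_1"` .. `"freq_7"` or
#'   `"silence"`.
#' @param run Run index per trial (integer vector, same length).
#' @return A data.frame of class `trial_table`.
#' @export
trial_table <- function(conditions, run = rep(1L, length(conditions))) {
  stopifnot(length(conditions) == length(run))
  lev <- c(paste0("freq_", 1:7), "silence")
  bad <- setdiff(unique(conditions), lev)
  if (length(bad)) stop("trial_table: unknown conditions: ", paste(bad, collapse = ", "))
  structure(data.frame(condition = factor(conditions, levels = lev),
                       run = as.integer(run)),
            class = c("trial_table", "data.frame"))
}

#' High-pass filter and percent-signal-change conversion
#'
#' Per run: slow drifts are removed by projecting out a discrete cosine
#' basis (components with frequency below `cutoff_hz`, the run mean
#' retained), then the series is converted to percent signal change relative
#' to the run average, `100 * (x - mean) / mean`; runs are concatenated.
#' Voxels with zero mean signal have undefined percent change and are
#' flagged invalid (`NA`).
#'
#' @param series Numeric matrix `[n_trials, n_voxels]` (a vector is treated
#'   as one voxel).
#' @param run Run index per trial.
#' @param tr_s Repetition time in seconds (default 7.5).
#' @param cutoff_hz High-pass cutoff (default 0.01).
#' @return Filtered percent-signal-change matrix, same shape.
#' @export
preprocess_series <- function(series, run = rep(1L, NROW(series)), tr_s = 7.5,
                              cutoff_hz = 0.01) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  stopifnot(nrow(series) == length(run))
  out <- series
  for (r in unique(run)) {
    rows <- which(run == r)
    Y <- series[rows, , drop = FALSE]
    n <- nrow(Y)
    mu <- colMeans(Y)
    # DCT-II basis components below the cutoff (excluding k = 0, the mean)
    kmax <- floor(2 * n * tr_s * cutoff_hz)
    if (kmax >= 1) {
      t0 <- seq_len(n) - 0.5
      B <- sapply(seq_len(kmax), function(k) cos(pi * k * t0 / n))
      B <- qr.Q(qr(B))
      Y <- Y - B %*% (t(B) %*% sweep(Y, 2, mu))
    }
    pct <- 100 * sweep(sweep(Y, 2, mu), 2, mu, "/")
    pct[, mu == 0] <- NA
    out[rows, ] <- pct
  }
  out
}

#' Fit the frequency-response GLM
#'
#' Ordinary least squares with one indicator regressor per stimulus
#' frequency and one intercept per run (the silence baseline). With a
#' balanced single-run design, each beta equals the condition mean minus
#' the silence baseline.
#'
#' @param series Preprocessed matrix `[n_trials, n_voxels]`.
#' @param trials A [trial_table()] (silence trials required).
#' @param per_run_intercept One intercept per run (default `TRUE`).
#' @return A `beta_set` list: `beta` (`n_voxels x 7`), `sigma2`, `dof`,
#'   `xtx_inv_beta` (the 7x7 block of `(X'X)^-1` for the frequency
#'   regressors), `n_trials`.
#' @export
fit_glm <- function(series, trials, per_run_intercept = TRUE) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  stopifnot(nrow(series) == nrow(trials))
  freq_lev <- paste0("freq_", 1:7)
  missing_cond <- freq_lev[!freq_lev %in% trials$condition]
  Xf <- sapply(freq_lev, function(l) as.numeric(trials$condition == l))
  Xi <- if (per_run_intercept && length(unique(trials$run)) > 1)
    sapply(sort(unique(trials$run)), function(r) as.numeric(trials$run == r))
  else matrix(1, nrow(trials), 1)
  X <- cbind(Xf, Xi)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    if (length(missing_cond))
      stop("fit_glm: rank-deficient design; missing conditions: ",
           paste(missing_cond, collapse = ", "))
    stop("fit_glm: rank-deficient design")
  }
  cf <- qr.coef(qrx, series)
  res <- series - X %*% cf
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qrx))
  structure(list(beta = t(cf[seq_len(7), , drop = FALSE]),
                 sigma2 = sigma2, dof = dof,
                 xtx_inv_beta = xtx_inv[1:7, 1:7], n_trials = nrow(X)),
            class = "beta_set")
}

#' Joint sound-versus-silence F-test
#'
#' Tests the joint null that all 7 frequency betas are zero, with
#' `(7, dof)` reference distribution.
#'
#' @param fit A `beta_set` from [fit_glm()].
#' @return List with `f` and `p` vectors (one entry per voxel).
#' @export
sound_f_test <- function(fit) {
  if (fit$dof <= 0) stop("sound_f_test: no residual degrees of freedom")
  Minv <- solve(fit$xtx_inv_beta)
  quad <- rowSums((fit$beta %*% Minv) * fit$beta)
  f <- quad / (7 * fit$sigma2)
  f[fit$sigma2 == 0 & quad > 0] <- Inf
  p <- stats::pf(f, 7, fit$dof, lower.tail = FALSE)
  list(f = f, p = p)
}

#' Select auditory-responsive voxels by adaptive FDR
#'
#' Applies the shared adaptive step-up FDR routine over the candidate
#' domain and returns the rejected (responsive) set.
#'
#' @param p P-value vector or matrix (`NA` = outside the candidate domain).
#' @param q FDR level (default 0.05).
#' @param method FDR variant, see [fdr_select()].
#' @return Logical vector/matrix of selected voxels.
#' @export
select_responsive <- function(p, q = 0.05, method = "tsbh") {
  sel <- fdr_select(as.vector(p), q = q, method = method)
  if (!is.null(dim(p))) dim(sel) <- dim(p)
  sel
}

#' Response-size responsive mask (alternative criterion)
#'
#' The less stringent criterion used for display purposes: a pixel is
#' responsive if at least one stimulus frequency evoked a response larger
#' than `threshold` percent signal change.
#'
#' @param betas Array `[nx, ny, depth, 7]` or matrix `[n, 7]`.
#' @param threshold Percent-signal-change threshold (default 1).
#' @return Logical matrix/vector.
#' @export
response_size_mask <- function(betas, threshold = 1) {
  if (length(dim(betas)) == 4) {
    nx <- dim(betas)[1]; ny <- dim(betas)[2]
    mx <- apply(betas, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    !is.na(mx) & mx > threshold
  } else {
    apply(betas, 1, max, na.rm = TRUE) > threshold
  }
}
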