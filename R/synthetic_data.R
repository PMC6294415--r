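#' Synthetic cortical patches with known tonotopy and core geometry
#'
#' The generator emulates the study geometry of human auditory cortex on a
#' flattened patch: a curvature ridge standing in for Heschl's gyrus (HG), a
#' V-shaped mirror-symmetric tonotopic field whose anterior and posterior
#' gradients form configurable angles (defaults +70 and -70 degrees) with
#' the HG long axis and meet at a low-frequency reversal line parallel to
#' that axis, high-frequency reversal lines at `band_width_mm` on either
#' side (beyond which the field folds back), elongated high-myelin and
#' narrow-tuning (high-selectivity) ellipses, cytoarchitectonic-style label
#' masks, and additive noise on response amplitudes. All geometry is defined
#' in the HG-aligned frame (u = along axis, v = across axis, positive v =
#' anterior) and rotated into the grid.
#'
#' @name synthetic_data
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
# The seed is forced first: a lazily-evaluated seed expression drawing from
# the caller's RNG must advance that stream before the state is saved.
with_seed <- function(seed, expr) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Flat-patch geometry configuration
#'
#' @param grid_shape Grid size in pixels (rows, cols); default `c(120, 120)`.
#' @param pixel_mm Pixel size in mm (default 0.33, the flat-map resolution).
#' @param hg_axis_deg HG long-axis angle in the grid frame, degrees CCW from
#'   the first (x) axis, in [0, 180); default 40.
#' @param hg_ridge List: `offset_mm` (across-axis centre of the ridge),
#'   `width_mm` (Gaussian width of the ridge), `amplitude` (curvature at the
#'   crest; banks get negative curvature).
#' @param mask_semi_mm Semi-axes (along, across) in mm of the elliptic
#'   auditory-responsive mask, centred on the patch.
#' @return A `patch_config` list.
#' @export
patch_config <- function(grid_shape = c(120, 120), pixel_mm = 0.33,
                         hg_axis_deg = 40,
                         hg_ridge = list(offset_mm = 0, width_mm = 4, amplitude = 0.3),
                         mask_semi_mm = c(17, 15)) {
  stopifnot(all(grid_shape > 0), pixel_mm > 0,
            hg_axis_deg >= 0, hg_axis_deg < 180,
            hg_ridge$width_mm > 0)
  structure(list(grid_shape = as.integer(grid_shape), pixel_mm = pixel_mm,
                 hg_axis_deg = hg_axis_deg, hg_ridge = hg_ridge,
                 mask_semi_mm = mask_semi_mm), class = "patch_config")
}

#' Tonotopic ground-truth configuration
#'
#' @param low_reversal_offset_mm Signed across-axis distance of the
#'   low-frequency reversal line from the HG axis (default 0: on the axis).
#' @param anterior_angle_deg,posterior_angle_deg Gradient directions relative
#'   to the HG axis on the anterior/posterior side; signs must differ
#'   (defaults +70, -70).
#' @param cam_range Preferred-frequency span in Cam realized across each
#'   band (default `c(10, 18)`, about 450-1350 Hz; combined with the
#'   along-axis component this keeps the whole field inside the span of the
#'   7 stimulus frequencies, emulating a protocol whose stimuli cover the
#'   mapped range -- see the methods vignette).
#' @param band_width_mm Across-axis distance from the low- to the
#'   high-frequency reversal on each side (default 8).
#' @return A `tonotopy_truth` list.
#' @export
tonotopy_truth <- function(low_reversal_offset_mm = 0,
                           anterior_angle_deg = 70, posterior_angle_deg = -70,
                           cam_range = c(10, 18),
                           band_width_mm = 8) {
  if (sin(deg2rad(anterior_angle_deg)) <= 0)
    stop("tonotopy_truth: anterior angle must point to the anterior (positive) side")
  if (sin(deg2rad(posterior_angle_deg)) >= 0)
    stop("tonotopy_truth: posterior angle must point to the posterior (negative) side")
  stopifnot(band_width_mm > 0, diff(cam_range) >= 0)
  structure(list(low_reversal_offset_mm = low_reversal_offset_mm,
                 anterior_angle_deg = anterior_angle_deg,
                 posterior_angle_deg = posterior_angle_deg,
                 cam_range = cam_range, band_width_mm = band_width_mm),
            class = "tonotopy_truth")
}

#' Core (myelin / selectivity) ground-truth configuration
#'
#' Ellipses are given in the HG frame in mm: centre (along, across),
#' semi-axes (major, minor) and orientation relative to the HG axis.
#'
#' @param myelin_ellipse,selectivity_ellipse Lists with `center_mm`,
#'   `semi_mm`, `orientation_deg`, `effect` (effect size, `> 0`).
#' @param myelin_baseline Baseline myelin level outside the ellipse.
#' @param width_narrow,width_wide Tuning width (ERB_N) inside/outside the
#'   selectivity ellipse (defaults 4 and 9).
#' @return A `core_truth` list.
#' @export
core_truth <- function(myelin_ellipse = list(center_mm = c(0, 0), semi_mm = c(11, 4.5),
                                             orientation_deg = 0, effect = 0.15),
                       selectivity_ellipse = list(center_mm = c(0, 0), semi_mm = c(12, 5),
                                                  orientation_deg = 0, effect = NULL),
                       myelin_baseline = 0.65,
                       width_narrow = 4, width_wide = 9) {
  stopifnot(myelin_ellipse$effect > 0, width_narrow > 0, width_wide > width_narrow)
  structure(list(myelin_ellipse = myelin_ellipse,
                 selectivity_ellipse = selectivity_ellipse,
                 myelin_baseline = myelin_baseline,
                 width_narrow = width_narrow, width_wide = width_wide),
            class = "core_truth")
}

#' Noise and inter-hemisphere variability configuration
#'
#' @param beta_noise_sd SD of additive i.i.d. noise on response amplitudes
#'   (percent-signal-change units; default 0.6, a moderate single-trial-map
#'   noise level relative to the default response height of 2).
#' @param structural_noise_sd SD of additive noise on structural maps
#'   (default 0.02).
#' @param curvature_coupling Weight of the curvature nuisance component added
#'   to structural stacks (default 0.1), so residualization has something to
#'   remove.
#' @param jitter List of inter-hemisphere SDs: `angle_sd_deg` (gradient
#'   angles), `offset_sd_mm` (reversal-line and ellipse-centre offsets),
#'   `effect_sd` (myelin effect size).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return A `noise_model` list.
#' @export
noise_model <- function(beta_noise_sd = 0.6, structural_noise_sd = 0.02,
                        curvature_coupling = 0.1,
                        jitter = list(angle_sd_deg = 8, offset_sd_mm = 1,
                                      effect_sd = 0.02),
                        seed = 1L) {
  stopifnot(beta_noise_sd >= 0, structural_noise_sd >= 0,
            jitter$angle_sd_deg >= 0, jitter$offset_sd_mm >= 0,
            jitter$effect_sd >= 0)
  structure(list(beta_noise_sd = beta_noise_sd,
                 structural_noise_sd = structural_noise_sd,
                 curvature_coupling = curvature_coupling,
                 jitter = jitter, seed = as.integer(seed)),
            class = "noise_model")
}

# HG-frame coordinate grids (u along axis, v across) in mm, plus grid-frame
# pixel coordinates of the patch centre.
patch_frame_coords <- function(patch) {
  nx <- patch$grid_shape[1]; ny <- patch$grid_shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- (matrix(seq_len(nx), nx, ny) - cx) * patch$pixel_mm
  y <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy) * patch$pixel_mm
  A <- deg2rad(patch$hg_axis_deg)
  list(u = x * cos(A) + y * sin(A),
       v = -x * sin(A) + y * cos(A),
       center_px = c(cx, cy))
}

inside_ellipse <- function(u, v, ell) {
  ph <- deg2rad(ell$orientation_deg)
  du <- u - ell$center_mm[1]; dv <- v - ell$center_mm[2]
  a <- du * cos(ph) + dv * sin(ph)
  b <- -du * sin(ph) + dv * cos(ph)
  (a / ell$semi_mm[1])^2 + (b / ell$semi_mm[2])^2 <= 1
}

# Triangular fold: distance d >= 0 folded at W (period 2W).
tri_fold <- function(d, W) W - abs(W - d %% (2 * W))

#' Generate ground-truth maps for one hemisphere
#'
#' Builds the noiseless per-pixel maps (preferred frequency in Cam, tuning
#' width in ERB_N, myelin, curvature, thickness) and the label masks
#' (responsive, HG, TE1.0/TE1.1/TE1.2, anterior/posterior non-core) from the
#' configuration objects. The preferred-frequency field is
#' `cam = cam_min + g*u + s_side*tri(|v - v0|)` in the HG frame, which has
#' uniform gradient direction `anterior_angle_deg` (resp.
#' `posterior_angle_deg`) between the reversal lines, a low-frequency valley
#' at `v = v0` parallel to the HG axis, and mirrored flanks beyond the
#' high-frequency reversals at `v0 +/- band_width_mm`.
#'
#' @param patch A [patch_config()].
#' @param tono A [tonotopy_truth()].
#' @param core A [core_truth()].
#' @param seed Unused placeholder for interface symmetry (the truth maps are
#'   deterministic functions of the configuration).
#' @return A `ground_truth` list with maps, masks, the HG frame
#'   (`center_px`, `hg_axis_deg`) and the realized configuration.
#' @export
generate_truth <- function(patch, tono, core, seed = NULL) {
  fr <- patch_frame_coords(patch)
  u <- fr$u; v <- fr$v
  px <- patch$pixel_mm

  responsive <- (u / patch$mask_semi_mm[1])^2 + (v / patch$mask_semi_mm[2])^2 <= 1

  for (ell in list(core$myelin_ellipse, core$selectivity_ellipse)) {
    ok <- inside_ellipse(u, v, ell) & !responsive
    if (any(ok)) stop("generate_truth: core ellipse extends outside the responsive mask")
  }

  # --- preferred-frequency field ---------------------------------------
  v0 <- tono$low_reversal_offset_mm
  W <- tono$band_width_mm
  span <- diff(tono$cam_range)
  s_a <- span / W                                  # anterior across-axis slope
  th_a <- deg2rad(tono$anterior_angle_deg)
  th_p <- deg2rad(tono$posterior_angle_deg)
  g <- if (s_a == 0) 0 else s_a * cos(th_a) / sin(th_a)   # shared along-axis slope
  s_p <- if (s_a == 0) 0 else -g * tan(th_p)              # posterior slope (continuity)
  d <- abs(v - v0)
  s_side <- ifelse(v >= v0, s_a, s_p)
  # anchor at the medial (u = -semi) end so the field minimum is cam_range[1]
  pref_cam <- tono$cam_range[1] + g * (u + patch$mask_semi_mm[1]) +
    s_side * tri_fold(d, W)
  pref_cam[!responsive] <- NA

  # --- curvature ridge (HG) and thickness ------------------------------
  w <- patch$hg_ridge$width_mm
  vr <- v - patch$hg_ridge$offset_mm
  curvature <- patch$hg_ridge$amplitude * (1 - (vr / w)^2) * exp(-vr^2 / (2 * w^2))
  thickness <- 2.5 + 0.2 * sin(u / 8) - 0.1 * (vr / w)^2 / (1 + (vr / w)^2)

  hg <- responsive & abs(vr) < w

  # --- core marker maps -------------------------------------------------
  sel_in <- inside_ellipse(u, v, core$selectivity_ellipse)
  tuning_width <- matrix(core$width_wide, nrow(u), ncol(u))
  tuning_width[sel_in] <- core$width_narrow
  tuning_width[!responsive] <- NA

  mye_in <- inside_ellipse(u, v, core$myelin_ellipse)
  myelin <- matrix(core$myelin_baseline, nrow(u), ncol(u))
  myelin[mye_in] <- core$myelin_baseline + core$myelin_ellipse$effect
  myelin[!responsive] <- NA

  # --- cytoarchitectonic-style labels along HG -------------------------
  u_third <- patch$mask_semi_mm[1] / 3
  te_band <- responsive & abs(vr) < 1.5 * w
  te11 <- te_band & u < -u_third                  # medial
  te10 <- te_band & abs(u) <= u_third             # central
  te12 <- te_band & u > u_third                   # lateral
  anterior_nc <- responsive & vr >= 1.5 * w
  posterior_nc <- responsive & vr <= -1.5 * w

  structure(list(
    preferred_cam = pref_cam, tuning_width = tuning_width, myelin = myelin,
    curvature = curvature, thickness = thickness,
    masks = list(responsive = responsive, hg = hg, te10 = te10, te11 = te11,
                 te12 = te12, anterior_noncore = anterior_nc,
                 posterior_noncore = posterior_nc),
    center_px = fr$center_px, hg_axis_deg = patch$hg_axis_deg,
    pixel_mm = px,
    realized = list(anterior_angle_deg = tono$anterior_angle_deg,
                    posterior_angle_deg = tono$posterior_angle_deg,
                    low_reversal_offset_mm = v0, band_width_mm = W,
                    cam_range = tono$cam_range,
                    myelin_orientation_deg = core$myelin_ellipse$orientation_deg,
                    selectivity_orientation_deg = core$selectivity_ellipse$orientation_deg),
    config = list(patch = patch, tono = tono, core = core)),
    class = "ground_truth")
}

#' Simulate per-pixel, per-depth response amplitudes (GLM betas)
#'
#' Each pixel's noiseless tuning curve is a Gaussian on the Cam scale with
#' mode equal to the truth preferred frequency and SD equal to the truth
#' tuning width, sampled at the stimulus positions and scaled to
#' `height` percent signal change; each cortical depth receives independent
#' additive Gaussian noise around the same mean.
#'
#' @param truth A `ground_truth`.
#' @param stim_freqs_hz Stimulus frequencies in Hz (default the 7 protocol
#'   values).
#' @param noise A [noise_model()].
#' @param depths Number of cortical depths (default 11).
#' @param height Response height in percent signal change (default 2).
#' @param seed Seed for the noise draws (default `noise$seed`).
#' @param scale A [cochlear_scale()].
#' @return Array `[nx, ny, depths, n_freq]`; `NA` outside the responsive mask.
#' @export
simulate_betas <- function(truth, stim_freqs_hz = default_stim_frequencies(),
                           noise = noise_model(), depths = 11, height = 2,
                           seed = noise$seed, scale = cochlear_scale()) {
  fc <- hz_to_cam(stim_freqs_hz, scale)
  nx <- nrow(truth$preferred_cam); ny <- ncol(truth$preferred_cam)
  nf <- length(fc)
  pf <- as.vector(truth$preferred_cam)
  tw <- as.vector(truth$tuning_width)
  clean <- vapply(fc, function(f) height * exp(-(f - pf)^2 / (2 * tw^2)),
                  numeric(nx * ny))           # (nx*ny) x nf
  betas <- with_seed(seed, {
    arr <- array(NA_real_, c(nx, ny, depths, nf))
    for (d in seq_len(depths)) {
      eps <- if (noise$beta_noise_sd > 0)
        matrix(stats::rnorm(nx * ny * nf, 0, noise$beta_noise_sd), nx * ny, nf)
      else 0
      arr[, , d, ] <- array(clean + eps, c(nx, ny, nf))
    }
    arr
  })
  off <- !truth$masks$responsive
  if (any(off)) {
    idx <- which(off)
    for (d in seq_len(depths)) for (k in seq_len(nf)) {
      sl <- betas[, , d, k]; sl[idx] <- NA; betas[, , d, k] <- sl
    }
  }
  betas
}

# Structural stacks for one hemisphere: PSIR-like depth stack with a depth
# profile (decreasing towards the pial surface, plateau at 0.3-0.7), a
# curvature-coupled nuisance, a PD proxy, and M0/MSAT maps for MTR.
simulate_structural <- function(truth, noise = noise_model(), depths = 11,
                                seed = noise$seed + 1L) {
  nx <- nrow(truth$myelin); ny <- ncol(truth$myelin)
  frac <- seq(0, 1, length.out = depths)
  profile <- 1 - 0.25 * pmax(0, frac - 0.7) / 0.3 - 0.1 * pmax(0, 0.3 - frac) / 0.3
  with_seed(seed, {
    pd <- 1 + 0.05 * truth$curvature / max(abs(truth$curvature)) +
      matrix(stats::rnorm(nx * ny, 0, noise$structural_noise_sd), nx, ny)
    psir <- array(NA_real_, c(nx, ny, depths))
    for (d in seq_len(depths)) {
      psir[, , d] <- truth$myelin * profile[d] +
        noise$curvature_coupling * truth$curvature +
        matrix(stats::rnorm(nx * ny, 0, noise$structural_noise_sd), nx, ny)
    }
    m0 <- matrix(100, nx, ny)
    msat <- m0 * (1 - pmin(0.95, pmax(0.05, truth$myelin, na.rm = FALSE)))
    list(psir = psir, pd_proxy = pd, curvature = truth$curvature,
         thickness = truth$thickness, m0 = m0, msat = msat,
         depth_fractions = frac)
  })
}

#' Simulate a cohort of hemispheres
#'
#' Per-hemisphere jitter (gradient angles, reversal/ellipse offsets, effect
#' sizes) is drawn once per hemisphere. With `null_cohort = TRUE` the
#' configured gradient angles are replaced by uniform random directions
#' (keeping the V geometry degenerate to a single random-direction ramp),
#' for type-I-error testing of the consistency analysis.
#'
#' @param n Number of hemispheres (default 24).
#' @param patch,tono,core Configuration objects (defaults as documented).
#' @param noise A [noise_model()].
#' @param seed Cohort seed (default `noise$seed`).
#' @param null_cohort Replace gradient structure by random-direction ramps.
#' @param betas Also simulate beta stacks (default `TRUE`).
#' @param structural Also simulate structural stacks (default `TRUE`).
#' @param depths Number of cortical depths.
#' @param stim_freqs_hz Stimulus frequencies in Hz.
#' @return List of hemispheres; each has `truth`, and optionally `betas` and
#'   `structural`.
#' @export
simulate_cohort <- function(n = 24, patch = patch_config(),
                            tono = tonotopy_truth(), core = core_truth(),
                            noise = noise_model(), seed = noise$seed,
                            null_cohort = FALSE, betas = TRUE,
                            structural = TRUE, depths = 11,
                            stim_freqs_hz = default_stim_frequencies()) {
  stopifnot(n >= 1)
  jit <- noise$jitter
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(h) list(
      d_ang_a = stats::rnorm(1, 0, jit$angle_sd_deg),
      d_ang_p = stats::rnorm(1, 0, jit$angle_sd_deg),
      d_off = stats::rnorm(1, 0, jit$offset_sd_mm),
      d_eff = stats::rnorm(1, 0, jit$effect_sd),
      null_ang = stats::runif(1, -180, 180),
      sub_seed = sample.int(2^30, 1)))
  })
  lapply(seq_len(n), function(h) {
    dr <- draws[[h]]
    tono_h <- tono
    if (null_cohort) {
      # one uniform random gradient direction: a plane ramp in that direction
      ang <- dr$null_ang
      truth <- generate_truth(patch, tonotopy_truth(
        low_reversal_offset_mm = -1e6,  # push the valley off the patch
        anterior_angle_deg = 90, posterior_angle_deg = -90,
        cam_range = tono$cam_range, band_width_mm = 1e7), core)
      fr <- patch_frame_coords(patch)
      A <- deg2rad(patch$hg_axis_deg + ang)
      span <- diff(tono$cam_range)
      ramp_slope <- span / (2 * tono$band_width_mm)
      # plane ramp in the drawn direction, built directly in the grid frame
      # and centred mid-range so the whole field stays inside the span the
      # stimulus protocol can estimate (as for the structured cohort)
      nxp <- patch$grid_shape[1]; nyp <- patch$grid_shape[2]
      gx <- (matrix(seq_len(nxp), nxp, nyp) - fr$center_px[1]) * patch$pixel_mm
      gy <- (matrix(seq_len(nyp), nxp, nyp, byrow = TRUE) - fr$center_px[2]) * patch$pixel_mm
      ramp <- mean(tono$cam_range) + ramp_slope * (gx * cos(A) + gy * sin(A))
      ramp[!truth$masks$responsive] <- NA
      truth$preferred_cam <- ramp
      truth$realized$anterior_angle_deg <- wrap_angle(ang)
      truth$realized$posterior_angle_deg <- wrap_angle(ang)
    } else {
      tono_h$anterior_angle_deg <- tono$anterior_angle_deg + dr$d_ang_a
      tono_h$posterior_angle_deg <- tono$posterior_angle_deg + dr$d_ang_p
      tono_h$low_reversal_offset_mm <- tono$low_reversal_offset_mm + dr$d_off
      core_h <- core
      core_h$myelin_ellipse$effect <- max(0.01, core$myelin_ellipse$effect + dr$d_eff)
      core_h$myelin_ellipse$center_mm[2] <- core$myelin_ellipse$center_mm[2] + dr$d_off
      core_h$selectivity_ellipse$center_mm[2] <-
        core$selectivity_ellipse$center_mm[2] + dr$d_off
      truth <- generate_truth(patch, tono_h, core_h)
    }
    out <- list(truth = truth)
    if (betas) out$betas <- simulate_betas(truth, stim_freqs_hz, noise,
                                           depths = depths, seed = dr$sub_seed)
    if (structural) out$structural <- simulate_structural(truth, noise,
                                                          depths = depths,
                                                          seed = dr$sub_seed + 1L)
    out
  })
}
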