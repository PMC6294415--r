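#' Pipeline: simulate, analyze per hemisphere, aggregate across the cohort
#'
#' The three stages are plain functions: [run_simulate()] writes a synthetic
#' cohort to disk, [run_analyze()] runs the per-hemisphere analysis chain
#' (responsive mask, preferred-frequency and tuning-width maps, gradient
#' field, reversal detection, HG frame, core and gradient ROIs, ROI
#' statistics) and [run_group()] computes cohort circular statistics and the
#' pixelwise gradient-consistency test.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param stim_freqs_hz Stimulus frequencies (Hz).
#' @param bank Gaussian bank (built on first use when `NULL`).
#' @param depths_use Depths averaged for the preferred-frequency map.
#' @param field_smoothing_fwhm_mm Field smoothing before reversal detection
#'   (default 6, the individual-hemisphere setting; group maps remain robust
#'   down to 2-4).
#' @param tuning_smoothing_fwhm_mm Smoothing of aligned tuning curves
#'   (default 3).
#' @param structural_smoothing_fwhm_mm Smoothing of depth-averaged
#'   structural maps (default 2).
#' @param consistency_smoothing_fwhm_mm Per-hemisphere field smoothing in
#'   the consistency test (default 3).
#' @param reversal_criterion Minimum reversal-orientation count (default 10).
#' @param fdr_q FDR level (default 0.05).
#' @param fdr_method FDR variant (default `"tsbh"`).
#' @param response_threshold Percent-signal-change threshold of the
#'   responsive mask used for beta-stack input (default 1).
#' @param pixel_mm Pixel size (default 0.33).
#' @param spread_form Spread convention, see [tuning_spread()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stim_freqs_hz = default_stim_frequencies(),
                            bank = NULL, depths_use = 4:8,
                            field_smoothing_fwhm_mm = 6,
                            tuning_smoothing_fwhm_mm = 3,
                            structural_smoothing_fwhm_mm = 2,
                            consistency_smoothing_fwhm_mm = 3,
                            reversal_criterion = 10, fdr_q = 0.05,
                            fdr_method = "tsbh", response_threshold = 1,
                            pixel_mm = 0.33, spread_form = "sd") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a cohort and write it to disk
#'
#' One directory per hemisphere with truth maps, label masks and beta /
#' structural stacks in the matrix-text format, plus a cohort manifest CSV
#' and the effective configuration as JSON. Deterministic per seed.
#'
#' @param out_dir Output directory (created; must not already contain a
#'   manifest unless `force`).
#' @param n Number of hemispheres.
#' @param patch,tono,core,noise Generator configurations.
#' @param seed Cohort seed.
#' @param force Overwrite an existing dataset.
#' @param depths Number of cortical depths.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, n = 24, patch = patch_config(),
                         tono = tonotopy_truth(), core = core_truth(),
                         noise = noise_model(), seed = noise$seed,
                         force = FALSE, depths = 11) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !force)
    stop("run_simulate: dataset already exists (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n = n, patch = patch, tono = tono, core = core,
                            noise = noise, seed = seed, depths = depths)
  rows <- lapply(seq_along(cohort), function(h) {
    hd <- file.path(out_dir, sprintf("hemi_%02d", h))
    dir.create(hd, showWarnings = FALSE)
    tr <- cohort[[h]]$truth
    meta <- list(pixel_mm = tr$pixel_mm, hg_axis_deg = tr$hg_axis_deg,
                 seed = seed, realized = tr$realized)
    write_map(tr$preferred_cam, file.path(hd, "preferred_cam"), meta)
    write_map(tr$tuning_width, file.path(hd, "tuning_width"), meta)
    write_map(tr$myelin, file.path(hd, "myelin"), meta)
    write_map(tr$curvature, file.path(hd, "curvature"), meta)
    write_map(tr$thickness, file.path(hd, "thickness"), meta)
    for (nm in names(tr$masks))
      write_map(tr$masks[[nm]], file.path(hd, paste0("mask_", nm)), meta)
    write_map(cohort[[h]]$betas, file.path(hd, "betas"),
              c(meta, list(dim4 = dim(cohort[[h]]$betas))))
    write_map(cohort[[h]]$structural$psir, file.path(hd, "psir"), meta)
    write_map(cohort[[h]]$structural$pd_proxy, file.path(hd, "pd_proxy"), meta)
    data.frame(hemisphere = h, dir = sprintf("hemi_%02d", h),
               anterior_angle_deg = tr$realized$anterior_angle_deg,
               posterior_angle_deg = tr$realized$posterior_angle_deg,
               hg_axis_deg = tr$hg_axis_deg, seed = seed)
  })
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  jsonlite::write_json(list(n = n, seed = seed, depths = depths,
                            pixel_mm = patch$pixel_mm,
                            grid_shape = patch$grid_shape,
                            hg_axis_deg = patch$hg_axis_deg),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

# HG ROI from the curvature ridge: positive-curvature band within the
# responsive mask (manual masks may be passed to analyze_hemisphere instead).
hg_roi_from_curvature <- function(curvature, responsive, frac = 0.05) {
  responsive & curvature > frac * max(curvature[responsive], na.rm = TRUE)
}

#' Analyze one hemisphere
#'
#' Full single-hemisphere chain from a beta stack and structural stacks to
#' ROI statistics. Intermediate maps are returned so stages can be
#' inspected or rerun.
#'
#' @param hemi List with `truth` (grid geometry, curvature, label masks) and
#'   `betas`; optionally `structural`.
#' @param config A [pipeline_config()].
#' @param hg_roi Optional manual HG ROI override (logical matrix).
#' @return List of maps, ROIs and a one-row `stats` data frame.
#' @export
analyze_hemisphere <- function(hemi, config = pipeline_config(),
                               hg_roi = NULL) {
  if (is.null(config$bank))
    config$bank <- gaussian_bank(config$stim_freqs_hz)
  tr <- hemi$truth
  px <- config$pixel_mm
  freq_cam <- config$bank$freq_cam

  # responsive mask from depth-averaged response sizes
  nd <- dim(hemi$betas)[3]
  bavg <- array(0, dim(hemi$betas)[c(1, 2, 4)])
  for (k in seq_len(dim(hemi$betas)[4]))
    bavg[, , k] <- apply(hemi$betas[, , , k], c(1, 2), mean)
  maxresp <- apply(bavg, c(1, 2), max)
  responsive <- !is.na(maxresp) & maxresp > config$response_threshold
  if (!any(responsive))
    stop("analyze_hemisphere: no auditory-responsive pixels")

  pref <- preferred_frequency_map(hemi$betas, config$bank,
                                  depths_use = config$depths_use,
                                  mask = responsive)
  twfit <- tuning_width_map(hemi$betas, freq_cam,
                            smoothing_fwhm_mm = config$tuning_smoothing_fwhm_mm,
                            pixel_mm = px, mask = responsive)

  field <- sobel_field(pref)
  field_sm <- smooth_map_or_field(field, config$field_smoothing_fwhm_mm, px)
  pref_sm <- smooth_map_or_field(pref, config$field_smoothing_fwhm_mm, px)
  rmap <- detect_reversals(field_sm, pref_sm,
                           criterion = config$reversal_criterion)
  clusters <- cluster_reversals(rmap, pixel_mm = px)

  hg <- if (!is.null(hg_roi)) hg_roi
        else hg_roi_from_curvature(tr$curvature, responsive)
  frame <- hg_frame(tr$curvature, hg)

  # structural conditioning -> myelin map
  myelin_map <- NULL
  if (!is.null(hemi$structural)) {
    st <- hemi$structural
    resid <- residualize(st$psir,
                         list(pd_proxy = st$pd_proxy,
                              curvature = st$curvature,
                              thickness = st$thickness),
                         mask = responsive)
    myelin_map <- depth_average(resid$stack,
                                smooth_fwhm_mm = config$structural_smoothing_fwhm_mm,
                                pixel_mm = px)
    myelin_map[!responsive] <- NA
  }

  sel_core <- core_roi(twfit$width, tr$masks, polarity = "below",
                       responsive_mask = responsive)
  mye_core <- if (!is.null(myelin_map))
    core_roi(myelin_map, tr$masks, polarity = "above",
             responsive_mask = responsive) else NULL

  grois <- gradient_rois(clusters, frame, responsive, pixel_mm = px)
  ant_stats <- roi_stats(grois$anterior, frame, field, pixel_mm = px)
  post_stats <- roi_stats(grois$posterior, frame, field, pixel_mm = px)
  sel_stats <- roi_stats(sel_core$roi, frame, field, pixel_mm = px)
  mye_stats <- if (!is.null(mye_core)) roi_stats(mye_core$roi, frame, field,
                                                 pixel_mm = px) else NULL

  low_in_hg <- Filter(function(cl) {
    cl$denomination == "low" &&
      mean(hg[cl$pixels]) > 0.5
  }, clusters)
  rev_ori <- if (length(low_in_hg)) reversal_orientation(low_in_hg, frame)
             else NA_real_

  ov_sel <- overlap_stats(sel_core$roi, grois$anterior, grois$posterior)
  ov_mye <- if (!is.null(mye_core))
    overlap_stats(mye_core$roi, grois$anterior, grois$posterior)
  else list(overlap_anterior = NA, overlap_posterior = NA, overlap_ratio = NA)

  stats_row <- data.frame(
    anterior_dir_deg = ant_stats$mean_direction_deg,
    posterior_dir_deg = post_stats$mean_direction_deg,
    selectivity_axis_deg = sel_stats$axis_deg,
    myelin_axis_deg = if (!is.null(mye_stats)) mye_stats$axis_deg else NA,
    reversal_orientation_deg = rev_ori,
    overlap_sel_anterior = ov_sel$overlap_anterior,
    overlap_sel_posterior = ov_sel$overlap_posterior,
    overlap_sel_ratio = ov_sel$overlap_ratio,
    overlap_mye_anterior = ov_mye$overlap_anterior,
    overlap_mye_posterior = ov_mye$overlap_posterior,
    overlap_mye_ratio = ov_mye$overlap_ratio,
    sel_area_mm2 = sel_stats$area_mm2,
    mye_area_mm2 = if (!is.null(mye_stats)) mye_stats$area_mm2 else NA,
    hg_axis_deg = frame$axis_deg)

  list(responsive = responsive, preferred_cam = pref,
       tuning_width = twfit$width, myelin_map = myelin_map,
       field = field, field_smoothed = field_sm, reversals = rmap,
       clusters = clusters, frame = frame, hg_roi = hg,
       selectivity_core = sel_core, myelin_core = mye_core,
       gradient_rois = grois, stats = stats_row)
}

#' Analyze every hemisphere of a cohort
#'
#' @param cohort A list from [simulate_cohort()] or a dataset directory
#'   written by [run_simulate()].
#' @param config A [pipeline_config()].
#' @return List with `results` (per hemisphere; `NULL` where a hemisphere
#'   failed), `stats` (row-bound data frame), `failed` (indices).
#' @export
run_analyze <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.null(config$bank))
    config$bank <- gaussian_bank(config$stim_freqs_hz)
  results <- vector("list", length(cohort))
  failed <- integer(0)
  for (h in seq_along(cohort)) {
    res <- tryCatch(analyze_hemisphere(cohort[[h]], config),
                    error = function(e) {
                      warning(sprintf("hemisphere %d failed: %s", h,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) failed <- c(failed, h) else results[[h]] <- res
  }
  ok <- !vapply(results, is.null, TRUE)
  stats <- do.call(rbind, lapply(which(ok), function(h)
    cbind(hemisphere = h, results[[h]]$stats)))
  list(results = results, stats = stats, failed = failed)
}

#' Read a cohort dataset written by [run_simulate()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return Cohort list compatible with [run_analyze()].
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(h) {
    hd <- file.path(dir, man$dir[h])
    rd <- function(nm) read_map(file.path(hd, nm))
    masks <- list()
    for (nm in c("responsive", "hg", "te10", "te11", "te12",
                 "anterior_noncore", "posterior_noncore"))
      masks[[nm]] <- rd(paste0("mask_", nm))
    pref <- rd("preferred_cam")
    meta <- attr(pref, "meta")
    truth <- structure(list(
      preferred_cam = pref, tuning_width = rd("tuning_width"),
      myelin = rd("myelin"), curvature = rd("curvature"),
      thickness = rd("thickness"), masks = masks,
      center_px = (dim(pref) + 1) / 2,
      hg_axis_deg = meta$hg_axis_deg, pixel_mm = meta$pixel_mm,
      realized = meta$realized), class = "ground_truth")
    psir <- rd("psir")
    list(truth = truth, betas = rd("betas"),
         structural = list(psir = psir, pd_proxy = rd("pd_proxy"),
                           curvature = truth$curvature,
                           thickness = truth$thickness,
                           depth_fractions = seq(0, 1, length.out = dim(psir)[3])))
  })
}

#' Cohort-level statistics and consistency testing
#'
#' Circular means with 95% CIs of the anterior and posterior gradient
#' directions (directional), the core long axes and the low-reversal
#' orientation (axial), the inter-gradient angle, overlap summaries, and
#' the pixelwise Hotelling consistency test on HG-frame-aligned gradient
#' fields.
#'
#' @param analyzed Output of [run_analyze()] (needs >= 3 hemispheres).
#' @param config A [pipeline_config()].
#' @return A `cohort_report` list with `summary` (data frame: quantity,
#'   mean, CI half-width, kind, n), `stats` (per-hemisphere rows),
#'   `consistency` (see [consistency_map()]).
#' @export
run_group <- function(analyzed, config = pipeline_config()) {
  st <- analyzed$stats
  if (is.null(st) || nrow(st) < 3) stop("run_group: need at least 3 analyzed hemispheres")
  res <- analyzed$results[!vapply(analyzed$results, is.null, TRUE)]

  ent <- function(name, x, kind) {
    x <- x[!is.na(x)]
    ci <- if (kind == "axial") axial_mean_ci(x) else circ_mean_ci(x)
    data.frame(quantity = name, mean_deg = ci$mean_deg,
               ci_halfwidth_deg = ci$ci_halfwidth_deg, kind = kind,
               n = ci$n)
  }
  summary <- rbind(
    ent("anterior_gradient_direction", st$anterior_dir_deg, "directional"),
    ent("posterior_gradient_direction", st$posterior_dir_deg, "directional"),
    ent("selectivity_core_axis", st$selectivity_axis_deg, "axial"),
    if (!all(is.na(st$myelin_axis_deg)))
      ent("myelin_core_axis", st$myelin_axis_deg, "axial"),
    if (!all(is.na(st$reversal_orientation_deg)))
      ent("low_reversal_orientation", st$reversal_orientation_deg, "axial"))
  inter <- mean(angle_diff(st$anterior_dir_deg, st$posterior_dir_deg),
                na.rm = TRUE)

  # HG-frame alignment: rotate each hemisphere's vectors by -axis
  fields <- lapply(res, function(r) {
    a <- deg2rad(-r$frame$axis_deg)
    structure(list(gx = r$field$gx * cos(a) - r$field$gy * sin(a),
                   gy = r$field$gx * sin(a) + r$field$gy * cos(a),
                   mask = r$field$mask), class = "vector_field")
  })
  shared_mask <- Reduce(`&`, lapply(res, function(r) r$responsive))
  cons <- consistency_map(fields, shared_mask,
                          smoothing_fwhm_mm = config$consistency_smoothing_fwhm_mm,
                          q = config$fdr_q, pixel_mm = config$pixel_mm,
                          fdr_method = config$fdr_method)

  structure(list(summary = summary, inter_gradient_angle_deg = inter,
                 stats = st, consistency = cons,
                 overlap_means = colMeans(st[grep("overlap", names(st))],
                                          na.rm = TRUE)),
            class = "cohort_report")
}
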