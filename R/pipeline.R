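# End-to-end pipeline drivers. Each driver reads its inputs, runs the
# stages in order, writes all maps/tables/reports plus a QC block and a
# manifest, and logs per-stage timings.

#' Assemble a run configuration
#'
#' @param mode `"co2"` or `"rest"`.
#' @param bold Path to the 4D BOLD image (NIfTI or ANALYZE).
#' @param tr Repetition time in seconds.
#' @param out Output directory.
#' @param co2 Path to the CO2 trace (required in co2 mode).
#' @param co2_fs Sampling rate for single-column CO2 files.
#' @param mask,parcellation Optional paths to a brain mask / ROI label image
#'   on the BOLD grid.
#' @param motion Optional path to a 6-column motion parameter file.
#' @param fwhm Spatial smoothing FWHM in mm (default 8).
#' @param voxel_shift_window Voxel-wise additional shift window in seconds
#'   (default `c(-5, 30)`), with `voxel_shift_step` (default 1 s).
#' @param fine_halfwidth,fine_step Fine alignment window (defaults 5 s and
#'   0.1 s).
#' @param scale_space_threshold Scale-space peak score threshold (default 15).
#' @param allow_short_co2 Permit a CO2 recording shorter than the BOLD
#'   series (zero-shift fallback; default FALSE).
#' @param seed RNG seed recorded for provenance (the pipelines themselves
#'   are deterministic; default 1).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("co2", "rest"), bold, tr, out,
                       co2 = NULL, co2_fs = NULL, mask = NULL,
                       parcellation = NULL, motion = NULL, fwhm = 8,
                       voxel_shift_window = c(-5, 30), voxel_shift_step = 1,
                       fine_halfwidth = 5, fine_step = 0.1,
                       scale_space_threshold = 15, allow_short_co2 = FALSE,
                       seed = 1) {
  mode <- match.arg(mode)
  if (mode == "co2" && is.null(co2))
    stop("co2 mode requires a CO2 trace file (co2 = ...)")
  stopifnot(tr > 0, fwhm >= 0,
            voxel_shift_window[1] < voxel_shift_window[2], voxel_shift_step > 0)
  structure(as.list(environment()), class = "run_config")
}

stage_log <- function(log, stage, t0, msg = "") {
  dt <- as.numeric(Sys.time()) - t0
  line <- sprintf("[%s] %-18s %6.2f s  %s", format(Sys.time(), "%H:%M:%S"),
                  stage, dt, msg)
  message(line)
  c(log, line)
}

load_common_inputs <- function(config) {
  img <- read_image_4d(config$bold, config$tr)
  sm <- gaussian_smooth(img, config$fwhm)
  mask_arr <- if (!is.null(config$mask)) {
    m <- RNifti::readNifti(config$mask)
    compute_brain_mask(sm, mask = as.array(m))
  } else compute_brain_mask(sm)
  parc <- if (!is.null(config$parcellation)) {
    p <- as.array(RNifti::readNifti(config$parcellation))
    storage.mode(p) <- "integer"
    p
  } else NULL
  motion <- if (!is.null(config$motion)) {
    mp <- read_motion_params(config$motion)
    if (nrow(mp) != img$n_frames)
      stop("motion file has ", nrow(mp), " rows but the BOLD series has ",
           img$n_frames, " frames")
    mp
  } else NULL
  list(img = img, smoothed = sm, mask = mask_arr, parc = parc, motion = motion)
}

#' Run the CO2-inhalation CVR pipeline end-to-end
#'
#' read -> smooth -> mask -> EtCO2 extraction (+switching check) -> temporal
#' alignment -> whole-brain / regional / voxel-wise CVR -> relative maps ->
#' outputs. Writes `cvr_global`, `cvr_voxelshift`, `shiftmap_sec`,
#' `cvr_relative` (NIfTI), `etco2_curve` and `roi_cvr` (CSV),
#' `wholebrain_cvr` and `qc` (JSON), an alignment report, and
#' `manifest.json`.
#'
#' @param config A [run_config()] with `mode = "co2"`.
#' @return The manifest data frame, invisibly, with attribute `"results"`
#'   holding the in-memory results.
#' @export
run_co2 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "co2") stop("config mode is not 'co2'")
  log <- character(0); t0 <- as.numeric(Sys.time())
  inp <- load_common_inputs(config)
  log <- stage_log(log, "load+preprocess", t0,
                   sprintf("%d mask voxels", sum(inp$mask)))
  t0 <- as.numeric(Sys.time())
  trace <- read_co2_trace(config$co2, fs = config$co2_fs)
  etco2 <- extract_etco2(trace, scale_space_threshold = config$scale_space_threshold)
  qc <- attr(etco2, "qc")
  if (qc$switching_flag) warning(qc$switching_message)
  log <- stage_log(log, "extract_etco2", t0,
                   sprintf("peaks %d/%d, baseline %.1f mmHg",
                           qc$n_peaks_scale_space, qc$n_peaks_smooth_cross,
                           etco2$baseline_etco2))
  t0 <- as.numeric(Sys.time())
  wb <- mean_timecourse(inp$smoothed, inp$mask)
  wbcvr <- whole_brain_cvr(etco2, wb, allow_short = config$allow_short_co2)
  al <- wbcvr$alignment
  log <- stage_log(log, "alignment", t0,
                   sprintf("shift %.2f s, partial CC %.3f",
                           wbcvr$shift_used, wbcvr$partial_cc))
  t0 <- as.numeric(Sys.time())
  cvr_g <- voxelwise_cvr_global(etco2, inp$smoothed, inp$mask, wbcvr$shift_used)
  vs <- voxelwise_cvr_shifted(etco2, inp$smoothed, inp$mask, wbcvr$shift_used,
                              delta_range = config$voxel_shift_window,
                              step = config$voxel_shift_step)
  rel <- relative_map(vs$cvr, inp$mask)
  roi <- if (!is.null(inp$parc)) regional_cvr(etco2, inp$smoothed, inp$parc)
         else data.frame(roi_id = integer(), n_voxels = integer(),
                         shift_sec = numeric(), cvr_pct_per_mmHg = numeric(),
                         partial_cc = numeric(), low_n = logical())
  log <- stage_log(log, "cvr_maps", t0, "")
  report <- c("CVR alignment report",
              sprintf("coarse optimum: %d s",
                      al$coarse_profile$shift[which.min(al$coarse_profile$rss)]),
              sprintf("final optimal shift: %.3f s", al$shift_opt),
              sprintf("polynomial (a, b, c): %s",
                      paste(signif(al$poly_coeffs, 6), collapse = ", ")),
              sprintf("partial correlation: %.4f", wbcvr$partial_cc))
  manifest <- write_outputs(
    config$out,
    maps = list(cvr_global = cvr_g, cvr_voxelshift = vs$cvr,
                shiftmap_sec = vs$shift, cvr_relative = rel),
    tables = list(etco2_curve = data.frame(t_sec = etco2$t, etco2_mmHg = etco2$v),
                  roi_cvr = roi,
                  coarse_profile = al$coarse_profile,
                  fine_profile = al$fine_profile),
    json = list(
      wholebrain_cvr = list(cvr_pct_per_mmHg = wbcvr$cvr,
                            shift_sec = wbcvr$shift_used,
                            partial_cc = wbcvr$partial_cc,
                            mean_etco2 = etco2$mean_etco2,
                            baseline_etco2 = etco2$baseline_etco2),
      qc = qc,
      config = config_provenance(config)),
    reports = list(alignment_report = report, log = log),
    template = inp$img)
  attr(manifest, "results") <- list(etco2 = etco2, wholebrain = wbcvr,
                                    cvr_global = cvr_g, voxelshift = vs,
                                    relative = rel, roi = roi)
  invisible(manifest)
}

#' Run the resting-state relative CVR pipeline end-to-end
#'
#' read -> smooth -> mask -> reference-signal construction -> voxel-wise
#' resting-state model -> relative map -> ROI means. Writes
#' `rscvr_relative` (NIfTI), `reference_signal` and `roi_rscvr` (CSV), `qc`
#' (JSON) and `manifest.json`.
#'
#' @param config A [run_config()] with `mode = "rest"`.
#' @return The manifest data frame, invisibly, with attribute `"results"`.
#' @export
run_rest <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "rest") stop("config mode is not 'rest'")
  log <- character(0); t0 <- as.numeric(Sys.time())
  inp <- load_common_inputs(config)
  log <- stage_log(log, "load+preprocess", t0,
                   sprintf("%d mask voxels", sum(inp$mask)))
  t0 <- as.numeric(Sys.time())
  res <- rs_cvr_map(inp$smoothed, inp$mask, motion = inp$motion,
                    parcellation = inp$parc)
  log <- stage_log(log, "rs_cvr", t0, "")
  tabs <- list(reference_signal = data.frame(
    frame = seq_along(res$reference$values) - 1L,
    reference = res$reference$values))
  if (!is.null(res$roi_table)) tabs$roi_rscvr <- res$roi_table
  manifest <- write_outputs(
    config$out,
    maps = list(rscvr_relative = res$relative),
    tables = tabs,
    json = list(qc = list(n_mask_voxels = sum(inp$mask),
                          reference_norm = sqrt(sum(res$reference$values^2))),
                config = config_provenance(config)),
    reports = list(log = log),
    template = inp$img)
  attr(manifest, "results") <- res
  invisible(manifest)
}

# defaults printed into the manifest for provenance
config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  cfg
}
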