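# CVR quantification. With the aligned EtCO2 regressor, the model
# coefficients convert to CVR in % BOLD change per mmHg via
#   CVR = beta1 / (beta0 - beta1 * (mean(EtCO2) - baseline(EtCO2))) * 100 ,
# i.e. the percent change is referenced to the signal level at baseline CO2
# rather than at the mean, with baseline = bottom-25% average of the curve.

#' Convert model coefficients to CVR in %/mmHg
#'
#' @param beta1 Regressor coefficient (signal units per mmHg).
#' @param beta0 Intercept (signal units at mean EtCO2).
#' @param mean_etco2,baseline_etco2 Mean and bottom-25%-average of the EtCO2
#'   curve in mmHg.
#' @return CVR in % BOLD change per mmHg (vectorised; `NA` where the
#'   baseline-signal denominator is non-positive or negligible relative to
#'   `beta0`).
#' @export
cvr_from_betas <- function(beta1, beta0, mean_etco2, baseline_etco2) {
  denom <- beta0 - beta1 * (mean_etco2 - baseline_etco2)
  bad <- !is.finite(denom) | denom <= 0 | abs(denom) < 1e-9 * abs(beta0)
  if (any(bad, na.rm = TRUE))
    warning("non-positive baseline-signal denominator: CVR set to NA at ",
            sum(bad, na.rm = TRUE), " location(s)")
  out <- beta1 / denom * 100
  out[bad] <- NA_real_
  out
}

#' Whole-brain CVR
#'
#' Aligns the EtCO2 curve to the whole-brain mean BOLD time course
#' (two-step search), fits the model at the optimal shift and converts to
#' %/mmHg.
#'
#' @param etco2 An [etco2_curve()].
#' @param bold_wb Whole-brain [mean_timecourse()].
#' @param allow_short Passed to [align_etco2()].
#' @return A `cvr_value`: list with `cvr` (%/mmHg), `beta1`, `beta0`,
#'   `shift_used` (s), `partial_cc`, `mean_etco2`, `baseline_etco2` and the
#'   full `alignment` result.
#' @export
whole_brain_cvr <- function(etco2, bold_wb, allow_short = FALSE) {
  al <- align_etco2(etco2, bold_wb, allow_short = allow_short)
  f <- al$fit
  structure(list(cvr = cvr_from_betas(f$beta1, f$beta0, etco2$mean_etco2,
                                      etco2$baseline_etco2),
                 beta1 = f$beta1, beta0 = f$beta0,
                 shift_used = al$shift_opt, partial_cc = f$partial_cc,
                 mean_etco2 = etco2$mean_etco2,
                 baseline_etco2 = etco2$baseline_etco2,
                 alignment = al),
            class = "cvr_value")
}

#' @export
print.cvr_value <- function(x, ...) {
  cat(sprintf("<cvr_value> %.4g %%/mmHg at shift %.2f s (partial CC %.3f)\n",
              x$cvr, x$shift_used, x$partial_cc))
  invisible(x)
}

#' Regional CVR with per-ROI alignment
#'
#' White matter responds later than gray matter, so the EtCO2 curve is
#' re-aligned to each ROI's mean time course (full two-step search) before
#' the CVR conversion.
#'
#' @param etco2 An [etco2_curve()].
#' @param img Preprocessed [image4d()].
#' @param parcellation 3D integer label array on the BOLD grid (0 =
#'   background).
#' @param min_voxels ROIs below this voxel count are flagged `low_n`
#'   (default 10); they are still computed.
#' @return Data frame with columns `roi_id`, `n_voxels`, `shift_sec`,
#'   `cvr_pct_per_mmHg`, `partial_cc`, `low_n`.
#' @export
regional_cvr <- function(etco2, img, parcellation, min_voxels = 10L) {
  stopifnot(inherits(img, "image4d"))
  if (!identical(dim(parcellation), dim(img$data)[1:3]))
    stop("parcellation grid does not match the BOLD grid")
  labs <- sort(unique(as.integer(parcellation[parcellation > 0])))
  if (length(labs) == 0L) stop("parcellation contains no nonzero labels")
  rows <- lapply(labs, function(l) {
    m <- parcellation == l
    tc <- mean_timecourse(img, m, region = paste0("roi_", l))
    v <- whole_brain_cvr(etco2, tc)
    data.frame(roi_id = l, n_voxels = sum(m), shift_sec = v$shift_used,
               cvr_pct_per_mmHg = v$cvr, partial_cc = v$partial_cc,
               low_n = sum(m) < min_voxels)
  })
  do.call(rbind, rows)
}

# frames x voxels matrix of in-mask series
mask_matrix <- function(img, mask) {
  d <- dim(img$data)
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty")
  list(Y = t(matrix(img$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]), idx = idx)
}

# fit [regressor, ramp, 1] to every column of Y at once
fit_voxels <- function(Y, x) {
  n <- nrow(Y)
  ell <- drift_ramp(n)
  X <- cbind(x - mean(x), ell, 1)
  B <- solve(crossprod(X), crossprod(X, Y))   # 3 x nvox
  list(beta1 = B[1, ], beta2 = B[2, ], beta0 = B[3, ])
}

#' Voxel-wise CVR with the global shift
#'
#' Fits the model at every in-mask voxel against the EtCO2 regressor shifted
#' by the single whole-brain optimal shift, then converts to %/mmHg.
#'
#' @param etco2 An [etco2_curve()].
#' @param img Preprocessed [image4d()].
#' @param mask 3D logical array.
#' @param global_shift Whole-brain optimal shift in seconds (from
#'   [align_etco2()]).
#' @return 3D array of CVR in %/mmHg; `NA` outside the mask and at
#'   zero-variance voxels.
#' @export
voxelwise_cvr_global <- function(etco2, img, mask, global_shift) {
  stopifnot(inherits(img, "image4d"))
  mm <- mask_matrix(img, mask)
  x <- resample_etco2(etco2, global_shift + (seq_len(nrow(mm$Y)) - 1) * img$tr)
  if (sd(x) == 0) stop("constant EtCO2 regressor at the requested shift")
  B <- fit_voxels(mm$Y, x)
  vr <- apply(mm$Y, 2, sd) > 0
  cvr <- suppressWarnings(cvr_from_betas(B$beta1, B$beta0,
                                         etco2$mean_etco2, etco2$baseline_etco2))
  cvr[!vr] <- NA_real_
  out <- array(NA_real_, dim(img$data)[1:3])
  out[mm$idx] <- cvr
  out
}

#' Voxel-wise CVR with per-voxel shift optimisation and shift map
#'
#' Starting from the globally shifted regressor, each voxel's shift is
#' refined over an additional delta in `delta_range` (default -5..+30 s, the
#' window kept narrow so noise cannot pull the fit into distant local
#' minima), choosing the delta with minimal residual (earliest on ties). The
#' returned shift map stores delta in seconds relative to the global shift —
#' the analogue of a bolus-arrival-time map; absolute shift = global +
#' delta.
#'
#' @inheritParams voxelwise_cvr_global
#' @param delta_range Length-2 window of additional shifts in seconds
#'   (default `c(-5, 30)`).
#' @param step Shift step in seconds (default 1, the EtCO2 native rate).
#' @return List with `cvr` (3D, %/mmHg), `shift` (3D, s relative to the
#'   global shift), `shift_absolute` (3D, s) and `boundary` (3D logical,
#'   TRUE where the optimum hit the window edge).
#' @export
voxelwise_cvr_shifted <- function(etco2, img, mask, global_shift,
                                  delta_range = c(-5, 30), step = 1) {
  stopifnot(inherits(img, "image4d"), delta_range[1] < delta_range[2], step > 0)
  mm <- mask_matrix(img, mask)
  Y <- mm$Y
  n <- nrow(Y)
  tf <- (seq_len(n) - 1) * img$tr
  ell <- drift_ramp(n)
  ss_ell <- sum(ell^2)
  Yr <- Y - matrix(colMeans(Y), n, ncol(Y), byrow = TRUE) -
    outer(ell, as.numeric(crossprod(ell, Y)) / ss_ell)
  ss_y <- colSums(Yr^2)
  deltas <- seq(delta_range[1], delta_range[2], by = step)
  best_rss <- rep(Inf, ncol(Y))
  best_delta <- rep(NA_real_, ncol(Y))
  for (d in deltas) {
    x <- resample_etco2(etco2, global_shift + d + tf)
    xr <- x - mean(x) - ell * (sum(ell * x) / ss_ell)
    ss_x <- sum(xr^2)
    rss <- if (ss_x == 0) ss_y else ss_y - as.numeric(crossprod(xr, Yr))^2 / ss_x
    upd <- rss < best_rss   # strict: earliest delta wins ties
    best_rss[upd] <- rss[upd]
    best_delta[upd] <- d
  }
  # final coefficients, one vectorised fit per distinct optimal delta
  beta1 <- beta0 <- rep(NA_real_, ncol(Y))
  for (d in unique(best_delta)) {
    sel <- which(best_delta == d)
    x <- resample_etco2(etco2, global_shift + d + tf)
    if (sd(x) == 0) next
    B <- fit_voxels(Y[, sel, drop = FALSE], x)
    beta1[sel] <- B$beta1
    beta0[sel] <- B$beta0
  }
  vr <- apply(Y, 2, sd) > 0
  cvr <- suppressWarnings(cvr_from_betas(beta1, beta0, etco2$mean_etco2,
                                         etco2$baseline_etco2))
  cvr[!vr] <- NA_real_
  best_delta[!vr] <- NA_real_
  d3 <- dim(img$data)[1:3]
  cvr_map <- shift_map <- abs_map <- array(NA_real_, d3)
  bnd_map <- array(NA, d3)
  cvr_map[mm$idx] <- cvr
  shift_map[mm$idx] <- best_delta
  abs_map[mm$idx] <- global_shift + best_delta
  bnd_map[mm$idx] <- best_delta %in% range(deltas)
  list(cvr = cvr_map, shift = shift_map, shift_absolute = abs_map,
       boundary = bnd_map)
}

#' Normalise a map by its in-mask mean
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array.
#' @return The map divided by the mean of its in-mask, non-`NA` voxels (so
#'   the relative map has in-mask mean 1); out-of-mask voxels are `NA`.
#' @export
relative_map <- function(map, mask) {
  v <- map[mask != 0]
  m <- mean(v, na.rm = TRUE)
  if (!is.finite(m) || abs(m) < .Machine$double.eps * 100)
    stop("in-mask mean is zero: relative map undefined")
  out <- array(NA_real_, dim(map))
  out[mask != 0] <- map[mask != 0] / m
  out
}
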