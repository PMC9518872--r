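# Resting-state relative CVR. Without a gas challenge, spontaneous
# low-frequency fluctuations of arterial CO2 still modulate BOLD; the
# whole-brain BOLD time course, detrended and low-pass filtered, serves as a
# surrogate regressor in place of EtCO2. Only relative (unit-free) CVR is
# available in this mode.

# ideal low-pass projection: keep Fourier bins with |f| <= cutoff (inclusive),
# zero the rest; real input -> real output, and projecting twice = once
lowpass_project <- function(x, tr, cutoff_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f)   # fold to two-sided frequency magnitude
  keep <- f <= cutoff_hz + 1e-12
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Build the resting-state reference signal
#'
#' The whole-brain mean BOLD time course is linearly detrended, low-pass
#' filtered with a 0.1164 Hz cutoff (ideal frequency-domain projection,
#' cutoff bin inclusive — the passband found to maximise spatial agreement
#' between resting-state and CO2 CVR maps), and rescaled to zero mean and a
#' 2-norm of sqrt(N)/2:  s0 = (s - mean(s)) * (sqrt(N)/2) / ||s - mean(s)||.
#'
#' @param bold_wb Whole-brain [mean_timecourse()] with N >= 16 frames.
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.1164).
#' @return A `reference_signal`: list with `values` (length N, mean 0, norm
#'   sqrt(N)/2) and `tr`.
#' @export
build_reference <- function(bold_wb, cutoff_hz = 0.1164) {
  stopifnot(inherits(bold_wb, "mean_timecourse"))
  y <- bold_wb$values
  n <- length(y)
  if (n < 16L) stop("at least 16 frames are required to build a reference signal")
  ell <- drift_ramp(n)
  det <- y - mean(y) - ell * (sum(ell * y) / sum(ell^2))
  if (sqrt(sum(det^2)) < 1e-12 * max(1, sqrt(sum(y^2))))
    stop("whole-brain time course is constant after detrending")
  filt <- lowpass_project(det, bold_wb$tr, cutoff_hz)
  filt <- filt - mean(filt)
  nrm <- sqrt(sum(filt^2))
  # valid resting-state data keep essentially all detrended power below the
  # cutoff; if less than 5% of the RMS survives, the input has no
  # low-frequency content and the rescaled reference would be noise
  if (nrm < 0.05 * sqrt(sum(det^2)))
    stop("almost no signal remains below the ", cutoff_hz,
         " Hz cutoff: cannot rescale the reference signal")
  structure(list(values = filt * (sqrt(n) / 2) / nrm, tr = bold_wb$tr),
            class = "reference_signal")
}

#' @export
print.reference_signal <- function(x, ...) {
  cat(sprintf("<reference_signal> %d frames, TR %.3g s, norm %.4f (= sqrt(N)/2)\n",
              length(x$values), x$tr, sqrt(sum(x$values^2))))
  invisible(x)
}

rs_design <- function(reference, n, motion = NULL) {
  X <- cbind(ref = reference$values, drift = drift_ramp(n), intercept = rep(1, n))
  if (!is.null(motion)) {
    if (nrow(motion) != n)
      stop("motion parameter rows (", nrow(motion),
           ") do not match frame count (", n, ")")
    mc <- scale(unclass(motion), center = TRUE, scale = FALSE)
    keep <- apply(mc, 2, sd) > 0    # drop constant motion columns
    if (any(keep)) X <- cbind(X[, "ref", drop = FALSE], mc[, keep, drop = FALSE],
                              X[, c("drift", "intercept")])
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design (collinear covariates)")
  X
}

#' Fit the resting-state model at one voxel
#'
#' Least squares of the raw voxel series on the reference signal, the six
#' zero-meaned motion covariates (when supplied), a linear trend and an
#' intercept. Relative reactivity is 100 * beta1 / beta0: beta0 is the
#' baseline signal level, so the ratio is the percent modulation per unit
#' reference; its per-voxel scale cancels in the relative map.
#'
#' @param voxel Numeric voxel time series.
#' @param reference A [build_reference()] result.
#' @param motion Optional [read_motion_params()] matrix (N x 6).
#' @return An `rs_glm_fit`: list with `beta1`, `beta_motion`, `beta_trend`,
#'   `beta0` and `rs_cvr` (= 100*beta1/beta0, `NA` when beta0 is ~0).
#' @export
rs_glm_voxel <- function(voxel, reference, motion = NULL) {
  stopifnot(inherits(reference, "reference_signal"))
  n <- length(voxel)
  if (n != length(reference$values)) stop("voxel and reference lengths differ")
  X <- rs_design(reference, n, motion)
  fit <- lm.fit(X, as.numeric(voxel))
  b <- fit$coefficients
  b1 <- unname(b["ref"]); b0 <- unname(b["intercept"])
  rs <- if (!is.finite(b0) || abs(b0) < 1e-9 * max(abs(voxel), 1)) NA_real_
        else 100 * b1 / b0
  structure(list(beta1 = b1,
                 beta_motion = unname(b[grep("_mm$|_rad$", names(b))]),
                 beta_trend = unname(b["drift"]), beta0 = b0, rs_cvr = rs),
            class = "rs_glm_fit")
}

#' Resting-state relative CVR map
#'
#' Builds the reference signal from the whole-brain mean of the
#' (preprocessed) series, fits the resting-state model at every in-mask
#' voxel, and divides by the in-mask mean to give the relative CVR map.
#' When a parcellation is supplied, per-ROI means of the relative map are
#' also returned.
#'
#' @param img Preprocessed (smoothed) [image4d()].
#' @param mask 3D logical array.
#' @param motion Optional motion parameter matrix (N x 6).
#' @param parcellation Optional 3D integer label array.
#' @param cutoff_hz Reference low-pass cutoff in Hz (default 0.1164).
#' @return List with `relative` (3D map, in-mask mean 1), `raw` (3D,
#'   100*beta1/beta0), `reference`, and `roi_table` (or `NULL`).
#' @export
rs_cvr_map <- function(img, mask, motion = NULL, parcellation = NULL,
                       cutoff_hz = 0.1164) {
  stopifnot(inherits(img, "image4d"))
  wb <- mean_timecourse(img, mask)
  ref <- build_reference(wb, cutoff_hz)
  mm <- mask_matrix(img, mask)
  X <- rs_design(ref, nrow(mm$Y), motion)
  B <- solve(crossprod(X), crossprod(X, mm$Y))
  b1 <- B[1, ]
  b0 <- B[nrow(B), ]
  rs <- ifelse(abs(b0) < 1e-9 * pmax(apply(abs(mm$Y), 2, max), 1),
               NA_real_, 100 * b1 / b0)
  raw <- array(NA_real_, dim(img$data)[1:3])
  raw[mm$idx] <- rs
  rel <- relative_map(raw, mask)
  roi <- NULL
  if (!is.null(parcellation)) {
    if (!identical(dim(parcellation), dim(img$data)[1:3]))
      stop("parcellation grid does not match the BOLD grid")
    labs <- sort(unique(as.integer(parcellation[parcellation > 0])))
    roi <- do.call(rbind, lapply(labs, function(l) {
      sel <- parcellation == l & mask != 0
      data.frame(roi_id = l, n_voxels = sum(sel),
                 rs_cvr_relative = mean(rel[sel], na.rm = TRUE))
    }))
  }
  list(relative = rel, raw = raw, reference = ref, roi_table = roi)
}
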