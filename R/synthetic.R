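# Synthetic ground-truth generators. Every pipeline stage is validated
# against phantoms whose true EtCO2 plateaus, shifts, CVR and gain fields
# are known exactly, so recovery can be asserted without any external data.

#' Phantom specification
#'
#' Collects the study conditions emulated by the generators: a block
#' hypercapnia paradigm (60 s room air / 60 s CO2 inhalation), quasi-periodic
#' breathing with variable intervals, and BOLD series that are affine
#' functions of the time-shifted EtCO2 curve plus drift and noise.
#'
#' @param dim Voxel grid (default `c(64, 64, 10)`).
#' @param tr Repetition time in seconds (default 2).
#' @param n_frames BOLD frames (default 210, i.e. a 7 min acquisition).
#' @param baseline_etco2,hyper_etco2 Plateau EtCO2 in mmHg during room-air
#'   and hypercapnic blocks (defaults 40 and 48 — a typical +8 mmHg
#'   challenge from a 5% CO2 mixture).
#' @param block_s Block duration in seconds (default 60).
#' @param breath_period_mean,breath_period_sd Breath period distribution in
#'   seconds (defaults 4 and 0; periods are truncated to the physiological
#'   3–8 s range). The default mean divides the block length so block
#'   transitions fall exactly on breath boundaries and the truth envelope is
#'   an exact square wave.
#' @param partial_breath_rate Fraction of breaths that are shallow
#'   (half-amplitude plateau; default 0).
#' @param inspired_mmHg CO2 partial pressure of inhaled air (trough level,
#'   default 1 mmHg for room air).
#' @param fs_raw Native capnograph sampling rate in Hz (default 100).
#' @param true_shift_s Global recorder-time offset of the BOLD start within
#'   the CO2 recording, in seconds (default 15 — lung-to-brain transit plus
#'   hemodynamic delay).
#' @param cvr True CVR in %/mmHg (scalar, or 3D field on the grid; default
#'   0.3, a typical gray-matter value).
#' @param delay Per-voxel additional delay in seconds relative to the global
#'   shift (scalar or 3D field; default 0).
#' @param drift_pct_per_frame Linear drift amplitude, percent of baseline
#'   signal per frame unit (default 0).
#' @param washin_tau_s Exponential wash-in/wash-out time constant of the
#'   end-tidal response to a block transition, in seconds (default 0 =
#'   instantaneous transitions, keeping the truth an exact square wave; a
#'   physiological value is 5–10 s, i.e. a couple of breaths to
#'   equilibrate). With instantaneous transitions the global shift is only
#'   identifiable to about the EtCO2 sampling interval, so studies of
#'   sub-second shift recovery should set a nonzero wash-in.
#' @param snr Contrast-to-noise ratio: the BOLD block contrast
#'   `a*(cvr/100)*(hyper-baseline)` divided by the white-noise SD (default
#'   `Inf` = noiseless).
#' @param motion_amp Amplitude of the simulated slow head motion in
#'   mm/radians (default 0.05).
#' @param seed RNG seed for reproducibility (default 1).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(64, 64, 10), tr = 2, n_frames = 210,
                         baseline_etco2 = 40, hyper_etco2 = 48, block_s = 60,
                         breath_period_mean = 4, breath_period_sd = 0,
                         partial_breath_rate = 0, inspired_mmHg = 1,
                         fs_raw = 100, true_shift_s = 15, cvr = 0.3,
                         delay = 0, drift_pct_per_frame = 0, washin_tau_s = 0,
                         snr = Inf, motion_amp = 0.05, seed = 1) {
  stopifnot(breath_period_sd >= 0, partial_breath_rate >= 0,
            partial_breath_rate <= 1, fs_raw >= 10, fs_raw <= 200,
            block_s > 0, tr > 0, n_frames >= 2, true_shift_s >= 0, snr > 0,
            washin_tau_s >= 0, motion_amp >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

# plateau level at recorder time t: room air outside the gas paradigm,
# alternating 60 s blocks (room air first) inside it
block_level <- function(t, spec, onset = 0, duration = Inf) {
  u <- t - onset
  inside <- u >= 0 & u < duration
  ifelse(inside & (floor(u / spec$block_s) %% 2) == 1,
         spec$hyper_etco2, spec$baseline_etco2)
}

# block level passed through a first-order exponential wash-in/out
washed_level <- function(times, spec, onset = 0, duration = Inf) {
  if (spec$washin_tau_s == 0) return(block_level(times, spec, onset, duration))
  dt <- 0.1
  tg <- seq(0, max(times) + dt, by = dt)
  target <- block_level(tg, spec, onset, duration)
  k <- exp(-dt / spec$washin_tau_s)
  w <- as.numeric(stats::filter(target * (1 - k), k, method = "recursive",
                                init = target[1]))
  approx(tg, w, xout = times, rule = 2)$y
}

#' Simulate a capnogram with known EtCO2 truth
#'
#' Generates a breath-by-breath CO2 trace: troughs at the inspired CO2
#' level, a smooth symmetric exhalation bump (`sin(pi*phase)^0.5`, broad
#' near the top) reaching the block's plateau EtCO2, breath periods drawn
#' from the spec distribution truncated to 3–8 s, and optional shallow
#' (half-amplitude) partial breaths. The exact plateau-level curve on the
#' 1 Hz grid is returned as ground truth.
#'
#' The capnograph starts before the scanner: the recording begins on room
#' air, the gas paradigm (alternating blocks, room air first) starts at
#' `paradigm_onset_s` — in a combined phantom, the moment the BOLD
#' acquisition starts — and the subject returns to room air when the
#' paradigm ends. The pre/post room-air stretches break the periodicity of
#' the block design, which is what makes the global temporal shift
#' identifiable.
#'
#' @param spec A [phantom_spec()].
#' @param duration_s Recording length in seconds (default: long enough to
#'   cover the BOLD window at the global shift plus the voxel-shift search,
#'   and at least 420 s).
#' @param paradigm_onset_s Recorder time at which the block paradigm starts
#'   (default `spec$true_shift_s`, i.e. the BOLD start).
#' @param paradigm_duration_s Length of the block paradigm (default the
#'   BOLD acquisition length `n_frames * tr`).
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `trace` (a [co2_trace()]), `truth` (list `t`, `v`: the
#'   1 Hz plateau truth), and `breaths` (data.frame of onset, period,
#'   plateau, partial).
#' @export
simulate_capnogram <- function(spec, duration_s = NULL,
                               paradigm_onset_s = spec$true_shift_s,
                               paradigm_duration_s = spec$n_frames * spec$tr,
                               seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(duration_s))
    duration_s <- max(420, spec$true_shift_s + spec$n_frames * spec$tr + 36)
  if (!is.null(seed)) set.seed(seed)
  # breath onsets
  onsets <- numeric(0); periods <- numeric(0); t <- 0
  while (t < duration_s) {
    per <- if (spec$breath_period_sd == 0) spec$breath_period_mean
           else min(max(rnorm(1, spec$breath_period_mean, spec$breath_period_sd), 3), 8)
    onsets <- c(onsets, t); periods <- c(periods, per)
    t <- t + per
  }
  plateau <- washed_level(onsets + periods / 2, spec, paradigm_onset_s,
                          paradigm_duration_s)
  partial <- runif(length(onsets)) < spec$partial_breath_rate
  peak <- ifelse(partial,
                 spec$inspired_mmHg + 0.5 * (plateau - spec$inspired_mmHg),
                 plateau)
  tg <- seq(0, duration_s, by = 1 / spec$fs_raw)
  bi <- findInterval(tg, onsets)
  phase <- (tg - onsets[bi]) / periods[bi]
  p <- spec$inspired_mmHg + (peak[bi] - spec$inspired_mmHg) *
    sqrt(pmax(sin(pi * pmin(phase, 1)), 0))
  truth_t <- seq(0, floor(duration_s))
  list(trace = co2_trace(tg, p, spec$fs_raw),
       truth = list(t = truth_t,
                    v = washed_level(truth_t, spec, paradigm_onset_s,
                                     paradigm_duration_s)),
       breaths = data.frame(onset = onsets, period = periods,
                            plateau = plateau, partial = partial))
}

# rectangular brain region covering the central half of the grid
brain_box <- function(dim) {
  m <- array(FALSE, dim)
  rg <- lapply(dim, function(n) {
    lo <- max(1L, floor(n / 4) + 1L); hi <- min(n, lo + max(1L, floor(n / 2)) - 1L)
    lo:hi
  })
  m[rg[[1]], rg[[2]], rg[[3]]] <- TRUE
  m
}

as_field <- function(x, dim, what) {
  if (length(x) == 1L) array(x, dim)
  else if (length(dim(x)) == 3L && all(dim(x) == dim)) x
  else stop(what, " must be a scalar or an array on the phantom grid")
}

sim_motion <- function(n, tr, amp, seed_offset = 0L) {
  tt <- (seq_len(n) - 1) * tr
  m <- sapply(1:6, function(k)
    amp * sin(2 * pi * tt / (120 + 17 * k) + k) + amp * 0.2 * rnorm(n))
  dimnames(m) <- list(NULL, c("tx_mm", "ty_mm", "tz_mm",
                              "rx_rad", "ry_rad", "rz_rad"))
  class(m) <- c("motion_params", class(m))
  m
}

#' Simulate a CO2-task BOLD phantom
#'
#' Forward model, voxel v at frame i (time i*TR):
#' `S = a_v * (1 + (c_v/100) * (EtCO2(i*TR + s + d_v) - baseline)) +
#'  a_v*(drift/100)*ell_i + a_v*sigma*eps`, where `a_v` is 1000 inside the
#' brain box and ~10 outside, `c_v` the true CVR field in %/mmHg, `s` the
#' global shift, `d_v` the per-voxel delay, and EtCO2(t) the linear
#' interpolation of the 1 Hz truth curve. This makes the regression truth
#' exact: `beta1 = a*c/100` and `beta0 = a + beta1*(mean - baseline)`.
#'
#' @param spec A [phantom_spec()].
#' @param capno Optional result of [simulate_capnogram()] to reuse; one is
#'   generated from `spec` otherwise.
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `img` ([image4d()]), `motion`, `mask` (true brain
#'   mask), and `truth` (list: `cvr_field`, `delay_field`, `s_global`,
#'   `baseline`, `etco2` 1 Hz truth, `capno`).
#' @export
simulate_co2_bold <- function(spec, capno = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(capno)) capno <- simulate_capnogram(spec, seed = seed)
  if (!is.null(seed)) set.seed(seed + 1L)
  d <- spec$dim
  mask <- brain_box(d)
  idx <- which(mask)
  cvr_f <- as_field(spec$cvr, d, "cvr")
  del_f <- as_field(spec$delay, d, "delay")
  n <- spec$n_frames
  tf <- (seq_len(n) - 1) * spec$tr
  need <- spec$true_shift_s + max(del_f[idx]) + tf[n]
  if (need > max(capno$truth$t))
    stop("delay field exceeds the EtCO2 recording coverage (need ",
         round(need), " s, have ", max(capno$truth$t), " s)")
  a <- 1000
  ell <- drift_ramp(n)
  sigma <- if (is.finite(spec$snr))
    (mean(cvr_f[idx]) / 100) * (spec$hyper_etco2 - spec$baseline_etco2) / spec$snr
  else 0
  nvox <- prod(d)
  data <- array(0, c(nvox, n))
  # distinct delays are few in practice; vectorise per delay value
  for (dd in unique(del_f[idx])) {
    sel <- idx[del_f[idx] == dd]
    et <- approx(capno$truth$t, capno$truth$v,
                 xout = spec$true_shift_s + dd + tf, rule = 2)$y
    base_sig <- outer(rep(a, length(sel)),
                      1 + (spec$drift_pct_per_frame / 100) * ell)
    data[sel, ] <- base_sig +
      a * (cvr_f[sel] / 100) %o% (et - spec$baseline_etco2)
  }
  if (sigma > 0)
    data[idx, ] <- data[idx, ] + a * sigma * matrix(rnorm(length(idx) * n),
                                                    length(idx), n)
  bg <- setdiff(seq_len(nvox), idx)
  data[bg, ] <- 10 + 0.5 * matrix(rnorm(length(bg) * n), length(bg), n)
  dim(data) <- c(d, n)
  list(img = image4d(data, voxel_size = c(3, 3, 3), tr = spec$tr),
       motion = sim_motion(n, spec$tr, spec$motion_amp),
       mask = mask,
       truth = list(cvr_field = ifelse(mask, cvr_f, NA_real_),
                    delay_field = ifelse(mask, del_f, NA_real_),
                    s_global = spec$true_shift_s,
                    baseline = spec$baseline_etco2,
                    etco2 = capno$truth, capno = capno))
}

#' Simulate a whole-brain BOLD time course (1D phantom)
#'
#' Single-voxel version of [simulate_co2_bold()]: the same affine forward
#' model applied to a mean time course, convenient for alignment and
#' whole-brain CVR recovery studies.
#'
#' @param spec A [phantom_spec()].
#' @param capno Optional [simulate_capnogram()] result to reuse.
#' @param seed RNG seed for the noise (default `spec$seed`).
#' @return List with `bold` ([mean_timecourse()]), `etco2_truth` (an
#'   [etco2_curve()] on the 1 Hz truth grid) and `truth` (a, cvr, shift,
#'   baseline).
#' @export
simulate_bold_timecourse <- function(spec, capno = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(capno)) capno <- simulate_capnogram(spec, seed = seed)
  if (!is.null(seed)) set.seed(seed + 2L)
  stopifnot(length(spec$cvr) == 1L)
  n <- spec$n_frames
  tf <- (seq_len(n) - 1) * spec$tr
  a <- 1000
  et <- approx(capno$truth$t, capno$truth$v,
               xout = spec$true_shift_s + tf, rule = 2)$y
  y <- a * (1 + (spec$cvr / 100) * (et - spec$baseline_etco2)) +
    a * (spec$drift_pct_per_frame / 100) * drift_ramp(n)
  if (is.finite(spec$snr))
    y <- y + a * (spec$cvr / 100) * (spec$hyper_etco2 - spec$baseline_etco2) /
      spec$snr * rnorm(n)
  list(bold = structure(list(values = y, tr = spec$tr, region = "whole-brain",
                             n_voxels = 1L), class = "mean_timecourse"),
       etco2_truth = etco2_curve(capno$truth$t, capno$truth$v),
       truth = list(a = a, cvr = spec$cvr, shift = spec$true_shift_s,
                    baseline = spec$baseline_etco2))
}

#' Simulate a resting-state BOLD phantom
#'
#' A latent low-frequency signal (sum of sinusoids below the 0.1164 Hz
#' reference-signal passband plus a small pink-noise floor) modulates every
#' brain voxel multiplicatively: `S = a_v * (1 + g_v * latent) +
#' a_v*sigma*eps`. The gain field `g_v` is the ground truth; the relative
#' resting-state CVR map should recover `g_v / mean(g_v)`.
#'
#' @param spec A [phantom_spec()].
#' @param gain Scalar or 3D field of voxel gains (default 1).
#' @param latent_sd Fractional SD of the latent fluctuation (default 0.01,
#'   i.e. ~1% signal fluctuations, typical of low-frequency BOLD).
#' @param freqs Sinusoid frequencies in Hz (default six tones spread over
#'   0.01–0.105 Hz).
#' @param pink_frac SD of the pink-noise floor relative to the sinusoids
#'   (default 0.1).
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `img`, `motion`, `mask`, and `truth` (list:
#'   `gain_field`, `latent`).
#' @export
simulate_rest_bold <- function(spec, gain = 1, latent_sd = 0.01,
                               freqs = c(0.012, 0.023, 0.041, 0.062, 0.085, 0.105),
                               pink_frac = 0.1, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed + 3L)
  d <- spec$dim
  n <- spec$n_frames
  tt <- (seq_len(n) - 1) * spec$tr
  amp <- 1 / seq_along(freqs)
  phases <- runif(length(freqs), 0, 2 * pi)
  latent <- rowSums(sapply(seq_along(freqs),
                           function(k) amp[k] * sin(2 * pi * freqs[k] * tt + phases[k])))
  if (pink_frac > 0) {
    w <- fft(rnorm(n))
    f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) / (n * spec$tr)
    w <- w / sqrt(pmax(f, f[2]))
    pk <- Re(fft(w, inverse = TRUE)) / n
    latent <- latent + pink_frac * sd(latent) * (pk - mean(pk)) / sd(pk)
  }
  latent <- (latent - mean(latent)) / sd(latent) * latent_sd
  mask <- brain_box(d)
  idx <- which(mask)
  g <- as_field(gain, d, "gain")
  a <- 1000
  sigma <- if (is.finite(spec$snr)) mean(g[idx]) * latent_sd / spec$snr else 0
  nvox <- prod(d)
  data <- array(0, c(nvox, n))
  data[idx, ] <- a * (1 + g[idx] %o% latent)
  if (sigma > 0)
    data[idx, ] <- data[idx, ] + a * sigma * matrix(rnorm(length(idx) * n),
                                                    length(idx), n)
  bg <- setdiff(seq_len(nvox), idx)
  data[bg, ] <- 10 + 0.5 * matrix(rnorm(length(bg) * n), length(bg), n)
  dim(data) <- c(d, n)
  list(img = image4d(data, voxel_size = c(3, 3, 3), tr = spec$tr),
       motion = sim_motion(n, spec$tr, spec$motion_amp),
       mask = mask,
       truth = list(gain_field = ifelse(mask, g, NA_real_), latent = latent))
}

#' Simulate a contiguous parcellation of the phantom brain
#'
#' Splits the in-mask voxels into `n_rois` contiguous slabs of near-equal
#' size (ordered along x, then y, then z); label 0 outside the mask.
#'
#' @param mask 3D logical brain mask.
#' @param n_rois Number of regions (>= 1, <= number of in-mask voxels).
#' @return 3D integer label array.
#' @export
simulate_parcellation <- function(mask, n_rois) {
  idx <- which(mask != 0)
  stopifnot(n_rois >= 1, n_rois <= length(idx))
  pos <- arrayInd(idx, dim(mask))
  ord <- order(pos[, 1], pos[, 2], pos[, 3])
  lab <- array(0L, dim(mask))
  chunk <- ceiling(length(idx) / n_rois)
  lab[idx[ord]] <- pmin(((seq_along(idx) - 1L) %/% chunk) + 1L, n_rois)
  lab
}
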