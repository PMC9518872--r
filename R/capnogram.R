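# Capnogram -> 1 Hz EtCO2 envelope.
#
# A capnogram oscillates once per breath: troughs are inhaled air, peaks are
# end-tidal (exhaled) CO2. The EtCO2 curve is the upper envelope. Two peak
# detectors with complementary failure modes are run independently and their
# regularised 1 Hz outputs are combined point-wise by maximum.

# centered moving average with windows shrunk at the ends (preserves
# constants everywhere, including boundaries); w is forced odd
moving_average <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || n == 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# plateau-aware local maxima: a run of equal values is a maximum when both
# neighbouring runs are lower; the earliest sample of the run is reported.
# Runs touching either boundary are never maxima (no two-sided neighbourhood).
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  isx <- seq_len(k)[-c(1L, k)]
  hit <- isx[r$values[isx] > r$values[isx - 1L] & r$values[isx] > r$values[isx + 1L]]
  starts[hit]
}

#' Preprocess a raw CO2 trace
#'
#' Smooths the recording with a 100 ms centered moving-average window, then
#' linearly resamples it onto a uniform 10 Hz grid spanning the recording
#' (times re-zeroed to the first sample). Breathing is slower than 0.3 Hz,
#' so 10 Hz comfortably resolves every breath while averaging down sensor
#' noise.
#'
#' @param trace A [co2_trace()].
#' @return A `co2_trace` at exactly 10 Hz starting at t = 0.
#' @export
preprocess_trace <- function(trace) {
  stopifnot(inherits(trace, "co2_trace"))
  dur <- trace$t[length(trace$t)] - trace$t[1]
  if (dur < 10) stop("CO2 trace shorter than 10 s cannot be processed")
  w <- round(0.1 * trace$fs_native)
  sm <- moving_average(trace$p, w)
  t0 <- trace$t - trace$t[1]
  tg <- seq(0, floor(dur * 10) / 10, by = 0.1)
  pg <- approx(t0, sm, xout = tg, rule = 2)$y
  co2_trace(tg, pg, 10)
}

#' Peak set container
#'
#' @param times Peak times in seconds (strictly increasing).
#' @param values Peak CO2 values in mmHg.
#' @param source Detector tag, `"scale_space"` or `"smooth_cross"`.
#' @return A `peak_set` object.
#' @export
peak_set <- function(times, values, source) {
  stopifnot(length(times) == length(values))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("peak times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 source = source, n = length(times)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (%s)\n", x$n, x$source))
  invisible(x)
}

#' Scale-space peak detection (Algorithm I)
#'
#' Detects all local maxima of the 10 Hz trace by the three-point criterion
#' v(n) = max[v(n-1), v(n), v(n+1)], then smooths the trace at 30
#' progressively wider scales (centered moving average of width 2k+1 samples
#' at iteration k), re-detecting maxima each time. A maximum that survives a
#' smoothing scale credits the nearest original-trace candidate within
#' `credit_tol` samples, accumulating a peak-likelihood score; candidates
#' with score >= `threshold` are kept. Peak times/values are read from the
#' unsmoothed trace. Brief noise spikes die after the first few scales and
#' fall below threshold, while true breath peaks persist. Before scoring,
#' the trace is extended antisymmetrically (point reflection about its
#' endpoints, which continues the breathing oscillation) by more than the
#' widest smoothing half-width, so peaks near the recording boundaries
#' accumulate scores the same way interior peaks do.
#'
#' @param trace Uniform 10 Hz `co2_trace` (output of [preprocess_trace()]).
#' @param n_iter Number of smoothing scales (default 30).
#' @param threshold Minimum peak-likelihood score (default 15, i.e. half the
#'   scales).
#' @param credit_tol Max drift, in samples, between a smoothed maximum and
#'   the candidate it credits (default 2).
#' @return A `peak_set` with `source = "scale_space"`.
#' @export
scale_space_peaks <- function(trace, n_iter = 30L, threshold = 15L, credit_tol = 2L) {
  stopifnot(inherits(trace, "co2_trace"))
  if (abs(trace$fs_native - 10) > 1e-9) stop("scale_space_peaks expects a 10 Hz trace")
  n0 <- length(trace$p)
  # antisymmetric (point-reflected) extension by more than the widest
  # smoothing half-width: continues the breathing oscillation so peaks near
  # the recording boundaries are scored like interior ones
  H <- min(2L * n_iter + 1L, n0 - 1L)
  p <- c(2 * trace$p[1] - trace$p[(H + 1L):2L], trace$p,
         2 * trace$p[n0] - trace$p[(n0 - 1L):(n0 - H)])
  cand <- local_maxima(p)
  cand <- cand[cand > H + 1L & cand < H + n0]   # inside, endpoints excluded
  if (length(cand) == 0L)
    return(peak_set(numeric(0), numeric(0), "scale_space"))
  score <- integer(length(cand))
  for (k in seq_len(n_iter)) {
    sm <- moving_average(p, 2L * k + 1L)
    mx <- local_maxima(sm)
    if (length(mx) == 0L) next
    # nearest candidate for each surviving maximum
    j <- findInterval(mx, cand)
    jlo <- pmax(j, 1L)
    jhi <- pmin(j + 1L, length(cand))
    dlo <- abs(mx - cand[jlo])
    dhi <- abs(cand[jhi] - mx)
    nearest <- ifelse(dlo <= dhi, jlo, jhi)
    ok <- pmin(dlo, dhi) <= credit_tol
    hit <- unique(nearest[ok])
    score[hit] <- score[hit] + 1L
  }
  keep <- cand[score >= threshold] - H
  peak_set(trace$t[keep], trace$p[keep], "scale_space")
}

#' Smooth-cross peak detection (Algorithm II)
#'
#' Computes a 10 s moving average of the 10 Hz trace; the crossings between
#' the trace and its moving average partition the recording into
#' breath-by-breath segments. Within each maximal run where the original
#' trace lies at or above the moving average, one peak is emitted at the
#' segment argmax (earliest sample on ties). Runs whose maximum sits on the
#' very first or last sample of the recording carry no complete breath and
#' are dropped.
#'
#' @param trace Uniform 10 Hz `co2_trace`.
#' @return A `peak_set` with `source = "smooth_cross"`.
#' @export
smooth_cross_peaks <- function(trace) {
  stopifnot(inherits(trace, "co2_trace"))
  if (abs(trace$fs_native - 10) > 1e-9) stop("smooth_cross_peaks expects a 10 Hz trace")
  n <- length(trace$p)
  dur <- trace$t[n] - trace$t[1]
  if (dur <= 10) stop("smooth-cross detection needs a trace longer than 10 s")
  ma <- moving_average(trace$p, 101L)   # 10 s at 10 Hz
  above <- trace$p >= ma
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(0)
  for (seg in which(r$values)) {
    s <- starts[seg]; e <- ends[seg]
    a <- s + which.max(trace$p[s:e]) - 1L
    if (a == 1L || a == n) next
    idx <- c(idx, a)
  }
  peak_set(trace$t[idx], trace$p[idx], "smooth_cross")
}

#' Median-filter peak values and interpolate to 1 Hz
#'
#' Breath intervals vary across subjects, so detected peaks form an
#' irregular time series. Peak values are passed through a five-point median
#' filter (windows shrink at the ends) to suppress partial-breath outliers
#' while keeping the breath-time grid, then linearly interpolated onto the
#' integer-second grid `[0, t_end]`; values before the first and after the
#' last peak hold the nearest peak value.
#'
#' @param peaks A `peak_set` with at least one peak.
#' @param t_end End of the 1 Hz grid in seconds.
#' @return List with `t` (0..t_end) and `v` (mmHg).
#' @export
regularize_peaks <- function(peaks, t_end) {
  stopifnot(inherits(peaks, "peak_set"))
  if (peaks$n == 0L) stop("cannot regularise an empty peak set")
  v <- peaks$values
  if (peaks$n >= 3L) {
    k <- min(5L, peaks$n - (1L - peaks$n %% 2L))  # largest odd <= min(5, n)
    v <- as.numeric(runmed(v, k, endrule = "median"))
  }
  tg <- seq(0, floor(t_end))
  vg <- if (peaks$n == 1L) rep(v, length(tg))
        else approx(peaks$times, v, xout = tg, rule = 2)$y
  list(t = tg, v = vg)
}

#' Combine two 1 Hz envelope series by point-wise maximum
#'
#' Each detector can locally underestimate the envelope; the EtCO2 curve is
#' the upper envelope of the trace, so the higher of the two values is taken
#' at every grid point.
#'
#' @param a,b Lists with identical 1 Hz grids `t` and values `v`.
#' @return An [etco2_curve()].
#' @export
combine_envelopes <- function(a, b) {
  if (length(a$t) != length(b$t) || any(a$t != b$t))
    stop("envelope grids do not match")
  etco2_curve(a$t, pmax(a$v, b$v))
}

#' EtCO2 curve container with summary statistics
#'
#' @param t Times in seconds, uniform 1 s spacing.
#' @param v EtCO2 values in mmHg.
#' @return An `etco2_curve`: list with `t`, `v`, `mean_etco2` (arithmetic
#'   mean) and `baseline_etco2` (mean of the lowest ceiling(25%) of values —
#'   the bottom-25% average is used instead of the minimum so a single deep
#'   breath cannot drag the baseline down).
#' @export
etco2_curve <- function(t, v) {
  stopifnot(length(t) == length(v), length(t) >= 2L)
  if (any(abs(diff(t) - 1) > 1e-9)) stop("EtCO2 curve must be sampled at 1 Hz")
  n_low <- ceiling(0.25 * length(v))
  baseline <- mean(sort(v)[seq_len(n_low)])
  structure(list(t = as.numeric(t), v = as.numeric(v),
                 mean_etco2 = mean(v), baseline_etco2 = baseline),
            class = "etco2_curve")
}

#' @export
print.etco2_curve <- function(x, ...) {
  cat(sprintf("<etco2_curve> %d s at 1 Hz, mean %.2f mmHg, baseline %.2f mmHg\n",
              length(x$v) - 1L, x$mean_etco2, x$baseline_etco2))
  invisible(x)
}

#' Extract the EtCO2 curve from a raw CO2 recording
#'
#' Full capnogram module: preprocess to 10 Hz, run both peak detectors,
#' median-filter and interpolate each to 1 Hz, and combine by point-wise
#' maximum. A detector contributing fewer than 3 peaks is dropped; if both
#' fail the capnogram is unusable. A QC record (peak counts, fraction of the
#' grid where the detectors disagree by more than 2 mmHg, CO2-switching
#' flag) is attached as attribute `"qc"`.
#'
#' @param trace Raw [co2_trace()] of at least 30 s.
#' @param scale_space_threshold Peak-likelihood score threshold for the
#'   scale-space detector (default 15 of 30 scales).
#' @return An [etco2_curve()] with attribute `qc`.
#' @export
extract_etco2 <- function(trace, scale_space_threshold = 15L) {
  stopifnot(inherits(trace, "co2_trace"))
  if (trace$t[length(trace$t)] - trace$t[1] < 30)
    stop("CO2 recording shorter than 30 s is unusable")
  pp <- preprocess_trace(trace)
  t_end <- pp$t[length(pp$t)]
  pkA <- scale_space_peaks(pp, threshold = scale_space_threshold)
  pkB <- smooth_cross_peaks(pp)
  okA <- pkA$n >= 3L
  okB <- pkB$n >= 3L
  if (!okA && !okB)
    stop("unusable capnogram: fewer than 3 peaks found by both algorithms")
  serA <- if (okA) regularize_peaks(pkA, t_end) else NULL
  serB <- if (okB) regularize_peaks(pkB, t_end) else NULL
  if (okA && okB) {
    curve <- combine_envelopes(serA, serB)
    disagree <- mean(abs(serA$v - serB$v) > 2)
  } else {
    ser <- if (okA) serA else serB
    curve <- etco2_curve(ser$t, ser$v)
    disagree <- NA_real_
    warning("only the ", if (okA) "scale-space" else "smooth-cross",
            " detector produced a usable peak set")
  }
  sw <- check_co2_switching(curve)
  attr(curve, "qc") <- list(
    n_peaks_scale_space = pkA$n,
    n_peaks_smooth_cross = pkB$n,
    disagreement_fraction = disagree,
    switching_flag = sw$flag,
    switching_message = sw$message)
  curve
}

#' Warn about possible CO2 switching
#'
#' When a subject's lung CO2 responds too slowly to a hypercapnic challenge,
#' exhaled CO2 can transiently fall below the inhaled level, so the trace
#' envelope no longer represents end-tidal CO2. No algorithm can detect the
#' inversion itself; it is however associated with an unusually low baseline
#' EtCO2, so curves with baseline below 25 mmHg (strict) are flagged for
#' visual review. Detection only — nothing is auto-corrected.
#'
#' @param curve An [etco2_curve()].
#' @return List with `flag` (logical) and `message`.
#' @export
check_co2_switching <- function(curve) {
  stopifnot(inherits(curve, "etco2_curve"))
  flag <- curve$baseline_etco2 < 25
  msg <- if (flag)
    sprintf(paste0("baseline EtCO2 %.1f mmHg is unusually low (< 25 mmHg): ",
                   "inspect the raw CO2 trace for possible CO2 switching"),
            curve$baseline_etco2)
  else "baseline EtCO2 within normal range"
  list(flag = flag, message = msg)
}
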