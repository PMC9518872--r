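test_that("preprocessing preserves constants, ramps, and attenuates a sine as the boxcar predicts", {
  # constant
  tt <- seq(0, 30, by = 0.02)
  pc <- preprocess_trace(co2_trace(tt, rep(40, length(tt)), 50))
  expect_equal(pc$fs_native, 10)
  expect_equal(diff(pc$t), rep(0.1, length(pc$t) - 1))
  expect_equal(pc$p, rep(40, length(pc$p)))

  # linear ramp 0 -> 60 mmHg over 60 s survives in the interior
  tt <- seq(0, 60, by = 0.02)
  pr <- preprocess_trace(co2_trace(tt, tt, 50))
  interior <- pr$t > 1 & pr$t < 59
  expect_lt(max(abs(pr$p[interior] - pr$t[interior])), 0.01)

  # 200 Hz sine: interior 10 Hz samples match the boxcar-attenuated sine
  fs <- 200; period <- 4
  tt <- seq(0, 60, by = 1 / fs)
  tr <- co2_trace(tt, 30 + 20 * sin(2 * pi * tt / period), fs)
  pp <- preprocess_trace(tr)
  w <- round(0.1 * fs); if (w %% 2 == 0) w <- w + 1
  att <- mean(cos(2 * pi * (-(w %/% 2):(w %/% 2)) / fs / period))
  interior <- pp$t > 1 & pp$t < 59
  expect_lt(max(abs(pp$p[interior] -
                    (30 + att * 20 * sin(2 * pi * pp$t[interior] / period)))), 0.2)

  expect_error(preprocess_trace(co2_trace(c(0, 5), c(40, 40), 10)), "10 s")
})

test_that("both peak detectors match the brute-force per-period argmax oracle on a noiseless sine", {
  tr <- sine_trace(duration = 60, period = 4)
  orc <- oracle_period_argmax(tr, 4)
  expect_length(orc$times, 15)
  pa <- scale_space_peaks(tr)
  pb <- smooth_cross_peaks(tr)
  expect_equal(pa$times, orc$times)
  expect_equal(pa$values, orc$values)
  expect_equal(pb$times, orc$times)
  expect_equal(pb$values, orc$values)
})

test_that("constant traces yield empty peak sets", {
  tt <- seq(0, 60, by = 0.1)
  flat <- co2_trace(tt, rep(40, length(tt)), 10)
  expect_equal(scale_space_peaks(flat)$n, 0)
  expect_equal(smooth_cross_peaks(flat)$n, 0)
})

test_that("a single-sample spike in a trough is rejected by the scale-space score", {
  tr <- sine_trace(duration = 60, period = 4)
  p <- tr$p
  spike_i <- which.min(abs(tr$t - 31))  # mid-trough (t = 31 s)
  p[spike_i] <- p[spike_i] + 5
  spiked <- co2_trace(tr$t, p, 10)
  pa <- scale_space_peaks(spiked)
  expect_false(any(abs(pa$times - tr$t[spike_i]) < 0.5))
  expect_equal(pa$n, 15)
})

test_that("smooth-cross tracks a step change in cycle amplitude", {
  tt <- seq(0, 120, by = 0.1)
  lev <- ifelse(tt < 60, 40, 50)
  p <- (lev - 1) * (0.5 - 0.5 * cos(2 * pi * tt / 4)) + 1
  pk <- smooth_cross_peaks(co2_trace(tt, p, 10))
  first <- pk$values[pk$times < 55]
  second <- pk$values[pk$times > 65]
  expect_true(all(abs(first - 40) < 0.5))
  expect_true(all(abs(second - 50) < 0.5))
})

test_that("median filtering absorbs partial-breath outliers and interpolation is linear with held ends", {
  pk <- peak_set(times = c(2, 6, 10, 14, 18), values = c(40, 40, 12, 40, 40),
                 source = "scale_space")
  reg <- regularize_peaks(pk, 20)
  expect_true(all(reg$v == 40))

  single <- peak_set(30, 40, "scale_space")
  reg1 <- regularize_peaks(single, 60)
  expect_equal(reg1$v, rep(40, 61))

  lin <- peak_set(c(0, 4, 8), c(40, 44, 48), "smooth_cross")
  reg2 <- regularize_peaks(lin, 8)
  expect_equal(reg2$v[reg2$t == 2], 42)
  expect_equal(reg2$v[reg2$t == 6], 46)

  expect_error(regularize_peaks(peak_set(numeric(0), numeric(0), "x"), 10), "empty")
})

test_that("envelope combination is an elementwise max with correct summary statistics", {
  g <- list(t = 0:7, v = c(30, 30, 30, 40, 40, 40, 40, 40))
  expect_equal(combine_envelopes(g, g)$v, g$v)       # idempotence
  a <- list(t = 0:1, v = c(38, 40)); b <- list(t = 0:1, v = c(40, 38))
  expect_equal(combine_envelopes(a, b)$v, c(40, 40))
  cv <- combine_envelopes(g, g)
  expect_equal(cv$baseline_etco2, 30)  # lowest ceiling(0.25*8) = 2 values
  expect_equal(cv$mean_etco2, 36.25)
  expect_error(combine_envelopes(a, g), "grids")
})

test_that("extraction recovers block plateaus on the standard capnogram", {
  spec <- phantom_spec()
  cap <- simulate_capnogram(spec, duration_s = 420, paradigm_onset_s = 0,
                            paradigm_duration_s = 420)
  et <- extract_etco2(cap$trace)
  blk <- floor(et$t / 60)
  for (b in 0:6) {
    sel <- blk == b
    expect_lt(abs(mean(et$v[sel]) - mean(cap$truth$v[sel])), 0.5)
  }
  qc <- attr(et, "qc")
  expect_gt(qc$n_peaks_scale_space, 90)
  expect_gt(qc$n_peaks_smooth_cross, 90)
  expect_false(qc$switching_flag)
})

test_that("extraction tolerates 10% partial breaths within 1 mmHg per block", {
  spec <- phantom_spec(partial_breath_rate = 0.1, breath_period_sd = 0.4, seed = 7)
  cap <- simulate_capnogram(spec, duration_s = 420, paradigm_onset_s = 0,
                            paradigm_duration_s = 420)
  et <- extract_etco2(cap$trace)
  blk <- floor(et$t / 60)
  for (b in 0:6) {
    sel <- blk == b
    expect_lt(abs(mean(et$v[sel]) - mean(cap$truth$v[sel])), 1)
  }
})

test_that("structureless noise is reported as unusable or QC-flagged", {
  set.seed(42)
  tt <- seq(0, 120, by = 0.1)
  noise <- co2_trace(tt, 40 + rnorm(length(tt), sd = 0.3), 10)
  res <- tryCatch(extract_etco2(noise), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "unusable")
  } else {
    qc <- attr(res, "qc")
    # noise peaks carry no breath structure: detectors disagree or counts explode
    expect_true(qc$disagreement_fraction > 0.05 || qc$n_peaks_scale_space > 200)
  }
})

test_that("the envelope dominates the running mean and stays within trace range", {
  spec <- phantom_spec(breath_period_sd = 0.4, seed = 5)
  cap <- simulate_capnogram(spec, duration_s = 420, paradigm_onset_s = 0,
                            paradigm_duration_s = 420)
  et <- extract_etco2(cap$trace)
  pp <- preprocess_trace(cap$trace)
  ma10 <- approx(pp$t, stats::filter(pp$p, rep(1 / 101, 101), sides = 2),
                 xout = et$t, rule = 2)$y
  ok <- !is.na(ma10)
  expect_gte(mean(et$v[ok] >= ma10[ok]), 0.95)
  expect_true(all(et$v >= min(pp$p) & et$v <= max(pp$p)))
  # max-combination dominance over each single-detector envelope
  t_end <- pp$t[length(pp$t)]
  serA <- regularize_peaks(scale_space_peaks(pp), t_end)
  serB <- regularize_peaks(smooth_cross_peaks(pp), t_end)
  expect_true(all(et$v >= serA$v - 1e-12))
  expect_true(all(et$v >= serB$v - 1e-12))
})

test_that("CO2 switching warning uses a strict 25 mmHg threshold on the baseline", {
  mk <- function(base) etco2_curve(0:9, rep(base, 10))
  expect_false(check_co2_switching(mk(40))$flag)
  expect_true(check_co2_switching(mk(24.9))$flag)
  expect_false(check_co2_switching(mk(25))$flag)
})
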