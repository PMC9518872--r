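# shared fixture builders (everything generated in code, nothing on disk)

# uniform 10 Hz sinusoidal "breathing" trace: offset + amp * sin(2*pi*t/period)
sine_trace <- function(duration = 60, period = 4, amp = 20, offset = 30, fs = 10) {
  tt <- seq(0, duration, by = 1 / fs)
  co2_trace(tt, offset + amp * sin(2 * pi * tt / period), fs)
}

# brute-force oracle: one argmax per full period of a noiseless periodic trace
oracle_period_argmax <- function(trace, period) {
  n_per <- floor((trace$t[length(trace$t)] - trace$t[1]) / period)
  idx <- vapply(seq_len(n_per), function(k) {
    sel <- which(trace$t >= (k - 1) * period & trace$t < k * period)
    sel[which.max(trace$p[sel])]
  }, integer(1))
  list(times = trace$t[idx], values = trace$p[idx])
}

# small co2-task phantom with wash-in enabled (used by alignment/CVR tests)
tiny_co2_phantom <- function(dim = c(10, 10, 4), n_frames = 150, ...) {
  spec <- phantom_spec(dim = dim, n_frames = n_frames, washin_tau_s = 8, ...)
  simulate_co2_bold(spec)
}

truth_curve <- function(ph) etco2_curve(ph$truth$etco2$t, ph$truth$etco2$v)
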