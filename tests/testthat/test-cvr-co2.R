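test_that("the beta-to-CVR conversion evaluates exactly and guards its denominator", {
  expect_equal(cvr_from_betas(0.02, 10, 45, 40), 0.02 / (10 - 0.1) * 100)
  expect_equal(cvr_from_betas(0, 10, 45, 40), 0)
  expect_warning(v <- cvr_from_betas(2, 10, 45, 40), "denominator")  # 10 - 2*5 = 0
  expect_true(is.na(v))
  # algebraic inversion of the forward model: beta1 = a*c/100,
  # beta0 = a + beta1*(mean - baseline)  =>  CVR = c
  a <- 1000; c0 <- 0.3; m <- 44; b <- 40
  beta1 <- a * c0 / 100
  beta0 <- a + beta1 * (m - b)
  expect_equal(cvr_from_betas(beta1, beta0, m, b), c0)
})

test_that("whole-brain CVR recovers the phantom truth and is drift- and scale-invariant", {
  spec <- phantom_spec(true_shift_s = 50, cvr = 0.25, n_frames = 150, washin_tau_s = 8)
  sim <- simulate_bold_timecourse(spec)
  wb <- whole_brain_cvr(sim$etco2_truth, sim$bold)
  expect_lt(abs(wb$cvr - 0.25), 5e-3)
  expect_lt(abs(wb$shift_used - 50), 0.1)

  # adding a linear drift leaves CVR essentially unchanged
  specd <- phantom_spec(true_shift_s = 50, cvr = 0.25, n_frames = 150,
                        washin_tau_s = 8, drift_pct_per_frame = 0.1)
  simd <- simulate_bold_timecourse(specd)
  wbd <- whole_brain_cvr(simd$etco2_truth, simd$bold)
  expect_lt(abs(wbd$cvr - wb$cvr), 1e-3)

  # global intensity scaling cancels in the ratio
  scaled <- sim$bold
  scaled$values <- 3.7 * scaled$values
  wbs <- whole_brain_cvr(sim$etco2_truth, scaled)
  expect_lt(abs(wbs$cvr - wb$cvr) / wb$cvr, 1e-6)

  # BOLD with no CO2 dependence: CVR and partial CC near zero
  set.seed(13)
  null_bold <- structure(list(values = 1000 + rnorm(150), tr = 2,
                              region = "whole-brain", n_voxels = 1L),
                         class = "mean_timecourse")
  wbn <- whole_brain_cvr(sim$etco2_truth, null_bold)
  expect_lt(abs(wbn$cvr), 0.05)
  expect_lt(abs(wbn$partial_cc), 0.25)
})

test_that("regional CVR re-aligns per ROI and recovers delay differences", {
  d <- c(10, 10, 4)
  del <- array(0, d); del[6:10, , ] <- 4
  ph <- tiny_co2_phantom(dim = d, delay = del, cvr = 0.3)
  et <- truth_curve(ph)
  parc <- array(0L, d)
  parc[ph$mask & ph$truth$delay_field == 0] <- 1L
  parc[ph$mask & ph$truth$delay_field == 4] <- 2L
  tab <- regional_cvr(et, ph$img, parc)
  expect_equal(nrow(tab), 2)
  expect_lt(max(abs(tab$cvr_pct_per_mmHg - 0.3)), 1e-3)
  expect_lt(abs((tab$shift_sec[2] - tab$shift_sec[1]) - 4), 0.2)
  expect_false(any(tab$low_n))

  # ROI = whole mask reproduces the whole-brain result
  parc_wb <- array(0L, d); parc_wb[ph$mask] <- 1L
  ph0 <- tiny_co2_phantom(dim = d, cvr = 0.3)
  et0 <- truth_curve(ph0)
  tab_wb <- regional_cvr(et0, ph0$img, parc_wb)
  wb <- whole_brain_cvr(et0, mean_timecourse(ph0$img, ph0$mask))
  expect_equal(tab_wb$cvr_pct_per_mmHg, wb$cvr)
  expect_equal(tab_wb$shift_sec, wb$shift_used)

  # single-voxel ROI is flagged but still computed
  parc1 <- array(0L, d)
  parc1[which(ph0$mask)[1]] <- 1L
  tab1 <- regional_cvr(et0, ph0$img, parc1)
  expect_true(tab1$low_n)
  expect_true(is.finite(tab1$cvr_pct_per_mmHg))

  expect_error(regional_cvr(et0, ph0$img, array(0L, d)), "no nonzero labels")
})

test_that("voxel-wise CVR with the global shift recovers a spatial pattern", {
  d <- c(10, 10, 4)
  cf <- array(0.1, d); cf[1:5, , ] <- 0.3
  ph <- tiny_co2_phantom(dim = d, cvr = cf)
  et <- truth_curve(ph)
  map <- voxelwise_cvr_global(et, ph$img, ph$mask, ph$truth$s_global)
  expect_lt(max(abs(map[ph$mask] - ph$truth$cvr_field[ph$mask])), 1e-3)
  expect_true(all(is.na(map[!ph$mask])))

  # constant-voxel series yields NA, no crash
  img2 <- ph$img
  flat_vox <- which(ph$mask)[1]
  pos <- arrayInd(flat_vox, d)
  img2$data[pos[1], pos[2], pos[3], ] <- 500
  map2 <- voxelwise_cvr_global(et, img2, ph$mask, ph$truth$s_global)
  expect_true(is.na(map2[pos[1], pos[2], pos[3]]))
})

test_that("voxel-wise shift map recovers two-compartment delays exactly at 1 s step", {
  d <- c(12, 12, 4)
  del <- array(0, d); del[7:12, , ] <- 6
  ph <- tiny_co2_phantom(dim = d, delay = del)
  et <- truth_curve(ph)
  vs <- voxelwise_cvr_shifted(et, ph$img, ph$mask, ph$truth$s_global)
  expect_equal(vs$shift[ph$mask], ph$truth$delay_field[ph$mask])
  expect_lt(max(abs(vs$cvr[ph$mask] - 0.3)), 1e-3)
  expect_equal(vs$shift_absolute[ph$mask],
               ph$truth$s_global + ph$truth$delay_field[ph$mask])
  expect_false(any(vs$boundary[ph$mask]))
  # uniform-delay phantom gives a constant map
  ph0 <- tiny_co2_phantom(dim = d)
  vs0 <- voxelwise_cvr_shifted(truth_curve(ph0), ph0$img, ph0$mask,
                               ph0$truth$s_global)
  expect_equal(unique(vs0$shift[ph0$mask]), 0)
})

test_that("delays beyond the search window clamp to its edge with a boundary flag", {
  d <- c(6, 6, 4)
  ph <- tiny_co2_phantom(dim = d, delay = 40, true_shift_s = 15, n_frames = 120)
  et <- truth_curve(ph)
  vs <- voxelwise_cvr_shifted(et, ph$img, ph$mask, ph$truth$s_global)
  expect_true(all(vs$shift[ph$mask] == 30))
  expect_true(all(vs$boundary[ph$mask]))
})

test_that("the voxel-wise shift scan agrees bitwise with a brute-force reimplementation", {
  d <- c(4, 4, 2)
  del <- array(0, d); del[3:4, , ] <- 6
  ph <- tiny_co2_phantom(dim = d, delay = del, snr = 10, seed = 17)
  et <- truth_curve(ph)
  gs <- ph$truth$s_global
  vs <- voxelwise_cvr_shifted(et, ph$img, ph$mask, gs)

  # independent straightforward scan: per voxel, per delta, full lm() fit
  n <- ph$img$n_frames
  tf <- (0:(n - 1)) * ph$img$tr
  ell <- seq_len(n) - (n + 1) / 2
  for (vox in which(ph$mask)) {
    pos <- arrayInd(vox, d)
    y <- ph$img$data[pos[1], pos[2], pos[3], ]
    best <- NULL
    for (dd in -5:30) {
      x <- approx(et$t, et$v, xout = gs + dd + tf, rule = 2)$y
      fit <- lm(y ~ I(x - mean(x)) + ell)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) best <- list(rss = rss, delta = dd,
                                                        b1 = coef(fit)[2],
                                                        b0 = coef(fit)[1])
    }
    expect_identical(vs$shift[pos[1], pos[2], pos[3]], as.numeric(best$delta))
    cvr_bf <- cvr_from_betas(unname(best$b1), unname(best$b0),
                             et$mean_etco2, et$baseline_etco2)
    expect_equal(vs$cvr[pos[1], pos[2], pos[3]], cvr_bf, tolerance = 1e-10)
  }
})

test_that("relative maps normalise to unit in-mask mean", {
  d <- c(4, 4, 2)
  mask <- array(TRUE, d)
  cm <- array(5, d)
  expect_equal(relative_map(cm, mask), array(1, d))
  half <- array(c(1, 3), d)
  rel <- relative_map(half, mask)
  expect_equal(sort(unique(as.numeric(rel))), c(0.5, 1.5))
  expect_equal(mean(rel[mask]), 1, tolerance = 1e-6)
  expect_error(relative_map(array(0, d), mask), "zero")
})
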