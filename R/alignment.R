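# Temporal alignment of the EtCO2 curve to a BOLD time course.
#
# EtCO2 is measured at the mouth, BOLD in the brain; the transit plus
# hemodynamic delay is found by shifting the EtCO2 curve against the BOLD
# series and minimising the residual of the linear model
#   BOLD_t = beta1 * etco2(t + s, zero-meaned) + beta2 * ell_t + beta0
# where ell is the linearly ascending zero-mean ramp -(N-1)/2 .. (N-1)/2
# absorbing scanner drift. The search is two-step: a 1 s coarse scan over
# all feasible shifts, then a 0.1 s scan over +-5 s around the coarse
# optimum with a quadratic fit of the residual profile, whose vertex gives
# sub-grid resolution.

drift_ramp <- function(n) seq_len(n) - (n + 1) / 2

frame_times <- function(bold) (seq_along(bold$values) - 1) * bold$tr

# EtCO2 value at arbitrary recorder times; beyond-range requests hold the
# terminal values (used only at extreme fine-grid shifts, with a warning
# from the caller).
resample_etco2 <- function(etco2, times) {
  approx(etco2$t, etco2$v, xout = times, rule = 2)$y
}

#' Fit the alignment GLM
#'
#' Least-squares fit of a BOLD time course on the zero-meaned regressor, a
#' linear drift ramp and an intercept. Also computes the partial correlation
#' between BOLD and the regressor after residualising both against intercept
#' and drift — the pipeline's data-quality index.
#'
#' @param bold A [mean_timecourse()] (or numeric vector).
#' @param regressor Numeric vector on the frame grid (same length).
#' @return A `glm_fit`: list with `beta1` (signal units per mmHg), `beta2`
#'   (drift, signal units per frame unit), `beta0` (intercept), `rss`,
#'   `partial_cc` and `n`.
#' @export
glm_fit <- function(bold, regressor) {
  y <- if (inherits(bold, "mean_timecourse")) bold$values else as.numeric(bold)
  x <- as.numeric(regressor)
  n <- length(y)
  if (length(x) != n) stop("BOLD and regressor lengths differ")
  if (n < 4L) stop("at least 4 time points are required")
  if (sd(x) == 0) stop("constant regressor: fit rejected")
  ell <- drift_ramp(n)
  xc <- x - mean(x)
  X <- cbind(reg = xc, drift = ell, intercept = rep(1, n))
  fit <- lm.fit(X, y)
  res <- fit$residuals
  # partial correlation: residualise both signals against [1, ell]
  yr <- y - mean(y) - ell * (sum(ell * y) / sum(ell^2))
  xr <- xc - ell * (sum(ell * xc) / sum(ell^2))
  pcc <- sum(xr * yr) / sqrt(sum(xr^2) * sum(yr^2))
  structure(list(beta1 = unname(fit$coefficients["reg"]),
                 beta2 = unname(fit$coefficients["drift"]),
                 beta0 = unname(fit$coefficients["intercept"]),
                 rss = sum(res^2), partial_cc = pcc, n = n),
            class = "glm_fit")
}

# residual sum of squares of the full model at each candidate shift,
# via projection algebra (identical to refitting the GLM at every shift)
shift_rss <- function(etco2, bold, shifts) {
  y <- bold$values
  n <- length(y)
  tf <- frame_times(bold)
  ell <- drift_ramp(n)
  ss_ell <- sum(ell^2)
  yr <- y - mean(y) - ell * (sum(ell * y) / ss_ell)
  ss_y <- sum(yr^2)
  vapply(shifts, function(s) {
    x <- resample_etco2(etco2, s + tf)
    xr <- x - mean(x) - ell * (sum(ell * x) / ss_ell)
    ss_x <- sum(xr^2)
    if (ss_x == 0) return(ss_y)
    ss_y - sum(xr * yr)^2 / ss_x
  }, numeric(1))
}

max_feasible_shift <- function(etco2, bold) {
  d_et <- etco2$t[length(etco2$t)] - etco2$t[1]
  d_bold <- (length(bold$values) - 1) * bold$tr
  d_et - d_bold
}

#' Coarse shift search at 1 s steps
#'
#' Scans every integer shift from 0 to (EtCO2 duration - BOLD duration):
#' BOLD frame i is regressed on the EtCO2 value at recorder time s + i*TR
#' (linear interpolation), and the shift minimising the residual sum of
#' squares is returned (smallest shift on ties).
#'
#' @param etco2 An [etco2_curve()].
#' @param bold A [mean_timecourse()].
#' @param allow_short If `TRUE`, a recording shorter than the BOLD series is
#'   fitted at shift 0 with the EtCO2 curve end-padded by its last value (a
#'   loud warning is emitted); otherwise this is an error.
#' @return List with `shift` (s) and `profile` (data.frame shift, rss).
#' @export
coarse_shift_search <- function(etco2, bold, allow_short = FALSE) {
  stopifnot(inherits(etco2, "etco2_curve"), inherits(bold, "mean_timecourse"))
  smax <- max_feasible_shift(etco2, bold)
  if (smax < 0) {
    if (!allow_short)
      stop("EtCO2 recording (", max(etco2$t), " s) is shorter than the BOLD series; ",
           "rerun with allow_short = TRUE (--allow-short-co2) to force a zero-shift fit ",
           "with end-padded EtCO2")
    warning("EtCO2 shorter than BOLD: fitting at shift 0 with EtCO2 end-padded ",
            "by its final value; shift estimate unavailable")
    smax <- 0
  }
  shifts <- seq(0, floor(smax), by = 1)
  rss <- shift_rss(etco2, bold, shifts)
  best <- shifts[which.min(rss)]   # which.min takes the first (smallest shift) on ties
  list(shift = best, profile = data.frame(shift = shifts, rss = rss))
}

#' Fine shift search at 0.1 s steps with quadratic interpolation
#'
#' Evaluates the model residual over `s_coarse` +- 5 s in 0.1 s steps
#' (clipped below at shift 0; shifts past the end of the recording reuse
#' its terminal value, with a warning), fits the residual profile to a
#' second-degree polynomial, and takes the vertex of a convex fit — clamped
#' into the fitted band — as the final optimal shift. The polynomial is
#' fitted to the profile points within `fit_halfwidth` of the grid argmin:
#' a quadratic describes the residual profile only near its minimum, and
#' fitting the whole window would let the profile's asymmetric far field
#' bias the vertex. If the local fit is not convex the grid argmin is used
#' instead.
#'
#' @param etco2 An [etco2_curve()].
#' @param bold A [mean_timecourse()].
#' @param s_coarse Coarse optimum in seconds.
#' @param halfwidth,step Fine window halfwidth and step in seconds
#'   (defaults 5 and 0.1).
#' @param fit_halfwidth Halfwidth, in seconds, of the band around the grid
#'   argmin used for the polynomial fit (default 2).
#' @return An `alignment_result`: list with `shift_opt`, `coarse_profile`
#'   (if attached by [align_etco2()]), `fine_profile`, `poly_coeffs`
#'   (c(a, b, c) of a*s^2 + b*s + c) and `fit` (the [glm_fit()] at the
#'   optimum, including `partial_cc`).
#' @export
fine_shift_search <- function(etco2, bold, s_coarse, halfwidth = 5, step = 0.1,
                              fit_halfwidth = 2) {
  stopifnot(inherits(etco2, "etco2_curve"), inherits(bold, "mean_timecourse"))
  smax <- max(max_feasible_shift(etco2, bold), 0)
  grid <- seq(s_coarse - halfwidth, s_coarse + halfwidth, by = step)
  grid <- round(grid, 10)
  grid <- grid[grid >= 0]
  if (any(grid > smax))
    warning("fine-grid shifts beyond the EtCO2 recording end hold its terminal value")
  if (length(grid) < 5L) {
    warning("fewer than 5 feasible fine-grid shifts: falling back to the coarse optimum")
    s_opt <- s_coarse
    prof <- data.frame(shift = grid, rss = shift_rss(etco2, bold, grid))
    pc <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  } else {
    rss <- shift_rss(etco2, bold, grid)
    prof <- data.frame(shift = grid, rss = rss)
    s_min <- grid[which.min(rss)]
    band <- abs(grid - s_min) <= fit_halfwidth + 1e-9
    gb <- grid[band]; rb <- rss[band]
    qf <- lm(rb ~ gb + I(gb^2))
    a <- unname(coef(qf)[3]); b <- unname(coef(qf)[2]); c0 <- unname(coef(qf)[1])
    pc <- c(a = a, b = b, c = c0)
    if (is.finite(a) && a > 0) {
      s_opt <- min(max(-b / (2 * a), gb[1]), gb[length(gb)])
    } else {
      warning("residual profile not convex near its minimum: using grid argmin")
      s_opt <- s_min
    }
  }
  reg <- resample_etco2(etco2, s_opt + frame_times(bold))
  structure(list(shift_opt = s_opt, fine_profile = prof, poly_coeffs = pc,
                 fit = glm_fit(bold, reg)),
            class = "alignment_result")
}

#' Two-step temporal alignment of EtCO2 to BOLD
#'
#' Composition of [coarse_shift_search()] and [fine_shift_search()]. The
#' partial correlation at the optimum is the dataset quality index.
#'
#' @inheritParams coarse_shift_search
#' @return An `alignment_result` with `shift_opt`, `coarse_profile`,
#'   `fine_profile`, `poly_coeffs` and `fit`.
#' @export
align_etco2 <- function(etco2, bold, allow_short = FALSE) {
  coarse <- coarse_shift_search(etco2, bold, allow_short = allow_short)
  res <- fine_shift_search(etco2, bold, coarse$shift)
  res$coarse_profile <- coarse$profile
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> optimal shift %.2f s, partial CC %.3f\n",
              x$shift_opt, x$fit$partial_cc))
  invisible(x)
}
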