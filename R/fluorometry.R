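## State-probability-weighted fluorescence model:
##   dF ~ F(C) P(C) + F(O) P(O) + F(CD) P(CD) + F(OD) P(OD)
## with per-state scaling factors in [-1, +1], plus the three empirical
## procedures that estimate the factors from measured trace kinetics:
##   * transient signals: F(O) = +/-1 by polarity, F(OD) from the
##     sustained/peak amplitude ratio;
##   * sustained signals: F(OD) = +/-1 by polarity, F(O) from the
##     (RT_F - RT_AI)/(RT_DI - RT_AI) statistic via a model-derived
##     calibration curve;
##   * F(CD) from the off-relaxation time after return to conditioning pH
##     via a second calibration curve (the F(CD)/F(OD) ratio sets the off
##     kinetics); F(C) only if the three-factor model leaves a large
##     residual.

#' Per-state fluorescence scaling factors
#'
#' @param F_C,F_O,F_CD,F_OD dimensionless factors in `[-1, +1]` weighting
#'   the occupancy of each functional state in the modelled fluorescence.
#' @return An object of class `vcf_factors`.
#' @export
fluorescence_factors <- function(F_C = 0, F_O = 0, F_CD = 0, F_OD = 0) {
  v <- c(F_C = F_C, F_O = F_O, F_CD = F_CD, F_OD = F_OD)
  if (any(!is.finite(v)) || any(abs(v) > 1))
    stop("scaling factors must lie in [-1, +1]")
  structure(as.list(v), class = "vcf_factors")
}

#' @export
print.vcf_factors <- function(x, ...) {
  cat(sprintf("F(C) = %+.3f  F(O) = %+.3f  F(CD) = %+.3f  F(OD) = %+.3f\n",
              x$F_C, x$F_O, x$F_CD, x$F_OD))
  pat <- attr(x, "pattern")
  if (!is.null(pat)) cat("pattern:", pat, "\n")
  w <- attr(x, "warnings")
  if (length(w)) cat("warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}

#' Synthesize a dF trace from state probabilities
#'
#' Pointwise linear combination of the four state probabilities weighted by
#' the scaling factors, baseline-subtracted so that the pre-stimulus value
#' is zero (the factors are identifiable only up to this convention).
#'
#' @param trajectory an [integrate_gates()] result.
#' @param factors a [fluorescence_factors()] object.
#' @param baseline_end end of the pre-stimulus baseline window (s); by
#'   default the start of the stimulation pulse of the stored protocol.
#' @return numeric dF vector, one value per trajectory sample.
#' @export
synthesize_dF <- function(trajectory, factors, baseline_end = NULL) {
  stopifnot(inherits(trajectory, "asic_trajectory"),
            inherits(factors, "vcf_factors"))
  dF <- factors$F_C * trajectory$P_C + factors$F_O * trajectory$P_O +
    factors$F_CD * trajectory$P_CD + factors$F_OD * trajectory$P_OD
  if (is.null(baseline_end)) {
    proto <- attr(trajectory, "protocol")
    baseline_end <- if (!is.null(proto)) protocol_pulse_window(proto)[1]
    else trajectory$time[1]
  }
  i <- trajectory$time <= baseline_end
  if (!any(i)) i <- 1L
  dF - mean(dF[i])
}

#' Single-state dF panel
#'
#' Model-generated fluorescence with scaling factor -1 for the indicated
#' state or gate pair (+1 for C, whose occupancy falls upon acidification),
#' for each of C, O, CD, OD, O+OD and CD+OD.
#'
#' @param model an [channel_model()].
#' @param protocol a [ph_protocol()].
#' @return data frame with columns `state`, `time`, `dF`.
#' @export
single_state_panel <- function(model, protocol = pulse_protocol()) {
  traj <- integrate_gates(model, protocol)
  fac <- list(
    C = fluorescence_factors(F_C = 1),
    O = fluorescence_factors(F_O = -1),
    CD = fluorescence_factors(F_CD = -1),
    OD = fluorescence_factors(F_OD = -1),
    `O+OD` = fluorescence_factors(F_O = -1, F_OD = -1),
    `CD+OD` = fluorescence_factors(F_CD = -1, F_OD = -1))
  out <- do.call(rbind, lapply(names(fac), function(st) {
    data.frame(state = st, time = traj$time,
               dF = synthesize_dF(traj, fac[[st]]))
  }))
  attr(out, "trajectory") <- traj
  out
}

## Monotone piecewise-linear inversion of a calibration curve. Out-of-range
## statistics clip to the nearest endpoint with a warning flag.
invert_calibration <- function(curve, value) {
  ord <- order(curve$ordinate)
  lo <- min(curve$ordinate); hi <- max(curve$ordinate)
  clipped <- value < lo || value > hi
  v <- min(max(value, lo), hi)
  est <- approx(curve$ordinate[ord], curve$abscissa[ord], xout = v,
                ties = "ordered")$y
  list(value = est, clipped = clipped)
}

check_monotone <- function(grid, stat, direction, what) {
  d <- diff(stat) * direction
  bad <- which(d < -1e-9)
  if (length(bad)) {
    stop(sprintf("calibration '%s' is not monotone over [%g, %g]",
                 what, grid[bad[1]], grid[bad[1] + 1L]))
  }
}

new_calibration <- function(abscissa, ordinate, statistic) {
  structure(list(abscissa = abscissa, ordinate = ordinate,
                 statistic = statistic),
            class = "vcf_calibration")
}

#' Calibration curve relating F(O) to the onset-kinetics statistic
#'
#' For each value of `F(O)` on the grid (with `F(OD)` fixed at 1, the
#' sustained pattern), a dF trace is synthesized and the statistic
#' `(RT_F - RT_AI) / (RT_DI - RT_AI)` is computed, where `RT_AI` is the
#' current-onset rise time, `RT_DI` the current decay time and `RT_F` the
#' dF onset rise time. The statistic is ~0 when the fluorescence tracks
#' the activation gate and ~1 when it tracks desensitization; it must be
#' monotone decreasing in `F(O)` for the curve to be invertible.
#'
#' @param model an [channel_model()].
#' @param protocol a [ph_protocol()]; factor estimation conventionally uses
#'   the pH 6.0 pulse protocol.
#' @param grid `F(O)` values in `[0, 1]` (the `F(OD)` branch sign is
#'   applied at estimation time; the statistic is invariant to a global
#'   sign flip of the trace).
#' @return A `vcf_calibration` with fields `abscissa`, `ordinate`.
#' @export
calibrate_FO <- function(model, protocol = pulse_protocol(),
                         grid = seq(0, 1, by = 0.1)) {
  stopifnot(all(grid >= 0), all(grid <= 1))
  traj <- integrate_gates(model, protocol)
  win <- protocol_pulse_window(attr(traj, "protocol"))
  I <- simulate_current(traj, model)
  RT_AI <- rise_time(traj$time, I, win)
  RT_DI <- decay_time(traj$time, I, win)
  if (is.na(RT_AI) || is.na(RT_DI) || RT_DI <= RT_AI)
    stop("current kinetics undefined: cannot build F(O) calibration")
  stat <- vapply(grid, function(fo) {
    dF <- synthesize_dF(traj, fluorescence_factors(F_O = fo, F_OD = 1))
    RT_F <- rise_time(traj$time, dF, win)
    (RT_F - RT_AI) / (RT_DI - RT_AI)
  }, numeric(1))
  check_monotone(grid, stat, -1, "F(O) vs onset statistic")
  new_calibration(grid, stat, "(RT_F - RT_AI)/(RT_DI - RT_AI)")
}

#' Calibration curve relating F(CD)/F(OD) to the off-relaxation time
#'
#' For each ratio on the grid a dF trace with `F(OD) = 1` and
#' `F(CD) = ratio` is synthesized and the off-relaxation time `RT_F_off`
#' (decay of the dF deviation after the return to conditioning pH) is
#' measured. The off kinetics depend only on the `F(CD)/F(OD)` ratio:
#' the curve is scale-invariant in the overall factor magnitude.
#'
#' @inheritParams calibrate_FO
#' @param grid `F(CD)/F(OD)` ratio values in `[0, 1]`.
#' @return A `vcf_calibration`.
#' @export
calibrate_FCD <- function(model, protocol = pulse_protocol(),
                          grid = seq(0, 1, by = 0.1)) {
  stopifnot(all(grid >= 0), all(grid <= 1))
  traj <- integrate_gates(model, protocol)
  win <- protocol_pulse_window(attr(traj, "protocol"))
  off_win <- c(win[2], max(traj$time))
  stat <- vapply(grid, function(r) {
    dF <- synthesize_dF(traj, fluorescence_factors(F_CD = r, F_OD = 1))
    decay_time(traj$time, dF, off_win)
  }, numeric(1))
  if (any(is.na(stat)))
    stop("off-relaxation undefined on the calibration grid")
  check_monotone(grid, stat, +1, "F(CD)/F(OD) vs RT_F_off")
  new_calibration(grid, stat, "RT_F_off")
}

#' Build the calibration set for factor estimation
#'
#' Bundles, for one (model, protocol) pair: the model trajectory, the
#' current kinetics, and the two calibration curves used by
#' [estimate_factors()]. Calibrations are conventionally built at
#' stimulation pH 6.0; rebuild with another protocol to estimate factors
#' for recordings at other pH values.
#'
#' @inheritParams calibrate_FO
#' @param fo_grid,fcd_grid grids passed to [calibrate_FO()] and
#'   [calibrate_FCD()].
#' @return An object of class `vcf_calibrations`.
#' @export
vcf_calibrations <- function(model, protocol = pulse_protocol(),
                             fo_grid = seq(0, 1, by = 0.1),
                             fcd_grid = seq(0, 1, by = 0.1)) {
  traj <- integrate_gates(model, protocol)
  win <- protocol_pulse_window(protocol)
  I <- simulate_current(traj, model)
  structure(list(
    model = model, protocol = protocol, trajectory = traj,
    pulse_window = win,
    RT_AI = rise_time(traj$time, I, win),
    RT_DI = decay_time(traj$time, I, win),
    fo = calibrate_FO(model, protocol, fo_grid),
    fcd = calibrate_FCD(model, protocol, fcd_grid)),
    class = "vcf_calibrations")
}

## Model sustained/peak ratio for a candidate (F_O, F_OD) pair on the
## calibration trajectory (linear in the factors, so no re-simulation).
model_sust_peak <- function(cal, F_O, F_OD) {
  dF <- synthesize_dF(cal$trajectory,
                      fluorescence_factors(F_O = F_O, F_OD = F_OD))
  peak_sustained(cal$trajectory$time, dF, cal$pulse_window)$ratio_sust_peak
}

#' Estimate the per-state scaling factors of a recording
#'
#' Implements the empirical decision tree. Transient pattern
#' (`|peak| > 1.1 |sustained|`): `F(O)` is set to +/-1 by the polarity of
#' the signal and `|F(OD)|` is solved so that the model's sustained/peak
#' ratio matches the measured one (1-D search, tolerance 1e-3). Sustained
#' pattern: `F(OD)` is set to +/-1 by polarity and `F(O)` is read off the
#' inverted onset-statistic calibration (clipped to the calibrated branch
#' with a warning if outside). In both cases `F(CD)` is the inverted
#' off-relaxation calibration applied to `RT_F_off`, scaled by `F(OD)`.
#' `F(C)` stays 0 unless a recording is supplied and the three-factor
#' model leaves a normalized RMS residual above 10\% of the peak, in which
#' case it is fitted within `[-1, 1]`.
#'
#' @param metrics a [analyze_recording()] kinetics summary.
#' @param calibrations a [vcf_calibrations()] set built under the
#'   recording's protocol.
#' @param polarity +1 or -1; defaults to the sign of the measured peak.
#' @param recording optionally the recording itself, enabling the residual
#'   rule for `F(C)`.
#' @param noise_floor peak amplitude below which estimation aborts with a
#'   "no signal" error.
#' @return A [fluorescence_factors()] object with attributes `pattern`
#'   (`"transient"` or `"sustained"`) and `warnings`.
#' @export
estimate_factors <- function(metrics, calibrations, polarity = NULL,
                             recording = NULL, noise_floor = 0) {
  stopifnot(inherits(metrics, "kinetics_summary"),
            inherits(calibrations, "vcf_calibrations"))
  if (!is.finite(metrics$peak_F) || abs(metrics$peak_F) <= noise_floor)
    stop("no signal: peak dF amplitude below the noise floor")
  if (is.null(polarity)) polarity <- sign(metrics$peak_F)
  stopifnot(polarity %in% c(-1, 1))
  warnings <- character(0)
  cal <- calibrations

  if (isTRUE(metrics$transient)) {
    pattern <- "transient"
    F_O <- polarity
    target <- metrics$ratio_sust_peak
    obj <- function(f) {
      r <- model_sust_peak(cal, F_O, f)
      (r - target)^2
    }
    opt <- optimize(obj, interval = c(-1, 1), tol = 1e-4)
    F_OD <- opt$minimum
    if (sqrt(opt$objective) > 0.05)
      warnings <- c(warnings, "sustained/peak ratio not fully reproduced")
  } else {
    pattern <- "sustained"
    F_OD <- polarity
    ## the statistic uses the cell's own current kinetics when defined,
    ## the model's otherwise
    RT_AI <- if (is.finite(metrics$RT_I_on)) metrics$RT_I_on else cal$RT_AI
    RT_DI <- if (is.finite(metrics$DT_I)) metrics$DT_I else cal$RT_DI
    stat <- (metrics$RT_F_on - RT_AI) / (RT_DI - RT_AI)
    inv <- invert_calibration(cal$fo, stat)
    if (inv$clipped)
      warnings <- c(warnings, "onset statistic outside calibrated range")
    F_O <- polarity * inv$value
  }

  if (is.finite(metrics$RT_F_off)) {
    inv <- invert_calibration(cal$fcd, metrics$RT_F_off)
    if (inv$clipped)
      warnings <- c(warnings, "RT_F_off outside calibrated range")
    F_CD <- inv$value * F_OD
  } else {
    F_CD <- 0
  }

  F_C <- 0
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "vcf_recording"))
    if (length(recording$time) != nrow(cal$trajectory))
      stop("recording and calibration protocol lengths differ")
    fit3 <- synthesize_dF(cal$trajectory,
                          fluorescence_factors(F_O = F_O, F_CD = F_CD,
                                               F_OD = F_OD))
    scale <- abs(metrics$peak_F)
    resid3 <- sqrt(mean((recording$dF_over_F - fit3 *
                           dF_scale(recording, fit3))^2)) / scale
    if (resid3 > 0.10) {
      obj <- function(fc) {
        m <- synthesize_dF(cal$trajectory,
                           fluorescence_factors(F_C = fc, F_O = F_O,
                                                F_CD = F_CD, F_OD = F_OD))
        mean((recording$dF_over_F - m * dF_scale(recording, m))^2)
      }
      F_C <- optimize(obj, interval = c(-1, 1), tol = 1e-4)$minimum
      warnings <- c(warnings, "residual rule triggered: F(C) fitted")
    }
  }

  out <- fluorescence_factors(F_C = F_C, F_O = min(max(F_O, -1), 1),
                              F_CD = min(max(F_CD, -1), 1),
                              F_OD = min(max(F_OD, -1), 1))
  attr(out, "pattern") <- pattern
  attr(out, "warnings") <- warnings
  out
}

## Least-squares amplitude mapping model -> measured trace (the dF model is
## proportional: recordings carry an arbitrary overall gain).
dF_scale <- function(recording, model_trace) {
  d <- sum(model_trace^2)
  if (d == 0) return(1)
  sum(recording$dF_over_F * model_trace) / d
}
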