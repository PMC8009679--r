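## Kinetics and amplitude statistics of current / dF/F time series:
## 10-90% rise times, 90-10% decay times, peak vs sustained amplitudes,
## Hill fits of pH-response curves, and the kinetics correlation rule.

## Centered moving average of odd half-width, with shrinking windows at the
## edges. Symmetric under time reversal, which makes the rise/decay mirror
## identity structural.
centered_ma <- function(x, n) {
  if (n <= 1L) return(x)
  half <- (n - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Amplitude at an extremum, re-estimated as the local mean around the
## argmax: the raw maximum of a noisy (even smoothed) trace is biased high
## by the largest noise excursion, which would inflate the 90% threshold
## and with it the rise time, proportionally to the trace time constant.
## A local linear fit evaluated at the argmax removes that bias (and is
## exact for trends ending at the window edge) at negligible curvature cost.
local_extremum <- function(dev, k, half) {
  lo <- max(1L, k - half)
  hi <- min(length(dev), k + half)
  x <- (lo:hi) - k
  y <- dev[lo:hi]
  if (length(y) < 3L) return(dev[k])
  mx <- mean(x)
  my <- mean(y)
  vx <- sum((x - mx)^2)
  b <- if (vx > 0) sum((x - mx) * (y - my)) / vx else 0
  my - b * mx
}

## Crossing time of d (rising from ~0 toward its extremum at the segment
## end) through threshold th > 0: the midpoint of the first passage above
## and the last passage from below, both linearly interpolated. On a clean
## monotone trace the two passages coincide; under noise the first passage
## alone is biased early (the largest noise excursion reaches the
## threshold first), while the midpoint is symmetric.
crossing_up <- function(time, d, th) {
  above <- d >= th
  if (!any(above)) return(NA_real_)
  k1 <- which(above)[1]
  t1 <- if (k1 == 1L) time[1] else {
    f <- (th - d[k1 - 1L]) / (d[k1] - d[k1 - 1L])
    time[k1 - 1L] + f * (time[k1] - time[k1 - 1L])
  }
  below <- which(!above)
  if (!length(below)) return(t1)
  k2 <- below[length(below)]
  t2 <- if (k2 == length(d)) time[k2] else {
    f <- (th - d[k2]) / (d[k2 + 1L] - d[k2])
    time[k2] + f * (time[k2 + 1L] - time[k2])
  }
  (t1 + t2) / 2
}

#' 10--90\% rise time of a signal
#'
#' Locates the extremum of the deviation from the baseline (the value at
#' the window start) and returns the time between the first crossings of
#' 10\% and 90\% of that amplitude, interpolated linearly between samples.
#' Works for either polarity. Traces are smoothed with a short centered
#' moving average before the threshold search so that noisy crossings do
#' not bias the result.
#'
#' @param time time vector (s), strictly increasing.
#' @param x signal vector, same length as `time`.
#' @param window `c(t_start, t_end)` delimiting the rise.
#' @param noise_floor minimal amplitude for a defined result; below it the
#'   function returns `NA` (flagged undefined), not an error.
#' @param smooth width (samples) of the centered smoothing window.
#' @return Rise time in seconds, or `NA` if undefined.
#' @examples
#' t <- seq(0, 10, 0.001)
#' rise_time(t, 1 - exp(-t), c(0, 10))  # ~ ln 9
#' @export
rise_time <- function(time, x, window = range(time), noise_floor = 0,
                      smooth = 5) {
  i <- which(time >= window[1] & time <= window[2])
  if (length(i) < 3L) return(NA_real_)
  tt <- time[i]
  xs <- centered_ma(x[i], smooth)
  dev <- xs - xs[1]
  k <- which.max(abs(dev))
  amp <- local_extremum(dev, k, 2L * smooth)
  if (!is.finite(amp) || abs(amp) <= noise_floor || amp == 0)
    return(NA_real_)
  ## crossings are searched on the rising segment up to the extremum, so a
  ## transient trace's later decay does not enter the onset measurement
  d <- dev[1:k] * sign(amp)
  t10 <- crossing_up(tt[1:k], d, 0.1 * abs(amp))
  t90 <- crossing_up(tt[1:k], d, 0.9 * abs(amp))
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  max(t90 - t10, 0)
}

## Mirror of crossing_up for d relaxing from its maximum toward 0.
crossing_down <- function(time, d, th) {
  below <- d <= th
  if (!any(below)) return(NA_real_)
  k1 <- which(below)[1]
  t1 <- if (k1 == 1L) time[1] else {
    f <- (d[k1 - 1L] - th) / (d[k1 - 1L] - d[k1])
    time[k1 - 1L] + f * (time[k1] - time[k1 - 1L])
  }
  above <- which(!below)
  if (!length(above)) return(t1)
  k2 <- above[length(above)]
  t2 <- if (k2 == length(d)) time[k2] else {
    f <- (d[k2] - th) / (d[k2] - d[k2 + 1L])
    time[k2] + f * (time[k2 + 1L] - time[k2])
  }
  (t1 + t2) / 2
}

#' 90--10\% decay time of a signal
#'
#' Mirror of [rise_time()] on the falling phase from the peak: the peak is
#' the extremum of the deviation from the window-start baseline, the
#' reference level of the decay is the value at the window end, and the
#' returned time is that between the first passages below 90\% and 10\% of
#' the peak-to-reference amplitude, interpolated between samples. If the
#' window holds no interior peak (the signal is monotone across it), the
#' window is read as starting at the peak when the signal magnitude relaxes
#' toward the end (e.g. an exponential decay sampled from its maximum);
#' a signal that moves away from baseline without returning -- the
#' sustained-plateau pattern of a non-desensitizing mutant -- yields `NA`
#' (flagged undefined), not an error.
#'
#' @inheritParams rise_time
#' @return Decay time in seconds, or `NA` if undefined.
#' @examples
#' t <- seq(0, 30, 0.001)
#' decay_time(t, exp(-t / 2), c(0, 30))  # ~ 2 * ln 9
#' @export
decay_time <- function(time, x, window = range(time), noise_floor = 0,
                       smooth = 5) {
  i <- which(time >= window[1] & time <= window[2])
  if (length(i) < 3L) return(NA_real_)
  tt <- time[i]
  xs <- centered_ma(x[i], smooth)
  n <- length(xs)
  e <- xs - xs[1]
  k <- which.max(abs(e))
  ret <- xs[k] - xs[n]
  if (abs(e[k]) > noise_floor && k > 1L && abs(ret) > 0.05 * abs(e[k])) {
    ## interior peak followed by a return toward the end level
    seg <- k:n
  } else if (abs(xs[1]) - abs(xs[n]) > noise_floor) {
    ## no interior peak but the magnitude relaxes: decay-only window
    seg <- seq_len(n)
    k <- 1L
  } else {
    return(NA_real_)
  }
  ref <- local_extremum(xs, n, 2L * smooth)
  amp <- local_extremum(xs, k, 2L * smooth) - ref
  if (!is.finite(amp) || abs(amp) <= noise_floor || amp == 0)
    return(NA_real_)
  d <- (xs[seg] - ref) * sign(amp)
  td <- tt[seg]
  t90 <- crossing_down(td, d, 0.9 * abs(amp))
  t10 <- crossing_down(td, d, 0.1 * abs(amp))
  if (is.na(t90) || is.na(t10)) return(NA_real_)
  max(t10 - t90, 0)
}

#' Peak and sustained amplitude of a pulse response
#'
#' Peak is the signed extremum within the window; sustained is the mean
#' over the final 10\% of the window. The response is classified transient
#' when `|peak| > 1.1 |sustained|`.
#'
#' @inheritParams rise_time
#' @param window `c(t_start, t_end)` of the stimulation pulse.
#' @return list with `peak`, `sustained`, `transient` (logical, `NA` for a
#'   flat/absent signal) and `ratio_sust_peak` (signed sustained/peak).
#' @export
peak_sustained <- function(time, x, window, noise_floor = 0) {
  i <- which(time >= window[1] & time <= window[2])
  if (length(i) == 0L) stop("empty pulse window")
  xx <- x[i]
  peak <- xx[which.max(abs(xx))]
  tail_start <- window[2] - 0.1 * (window[2] - window[1])
  sustained <- mean(x[time >= tail_start & time <= window[2]])
  if (abs(peak) <= noise_floor) {
    return(list(peak = peak, sustained = sustained, transient = NA,
                ratio_sust_peak = NA_real_))
  }
  list(peak = peak, sustained = sustained,
       transient = abs(peak) > 1.1 * abs(sustained),
       ratio_sust_peak = sustained / peak)
}

#' Normalize a raw fluorescence trace to dF/F
#'
#' `(F(t) - F0) / F0` with `F0` the mean over the baseline window.
#'
#' @param raw_F raw fluorescence vector.
#' @param time time vector, same length.
#' @param baseline_window `c(t_start, t_end)` of the pre-stimulus baseline.
#' @return dF/F vector.
#' @export
normalize_fluorescence <- function(raw_F, time, baseline_window) {
  i <- which(time >= baseline_window[1] & time <= baseline_window[2])
  if (length(i) == 0L) stop("empty baseline window")
  F0 <- mean(raw_F[i])
  if (!is.finite(F0) || F0 <= 0)
    stop("baseline fluorescence must be positive")
  (raw_F - F0) / F0
}

#' Hill fit of a pH-response curve
#'
#' Fits `I = Imax / (1 + (10^-pH50 / 10^-pH)^nH)` (response growing with
#' acidity) or the analogous steady-state-desensitization form (response
#' decreasing with acidity) by Levenberg-Marquardt least squares. The
#' midpoint is initialized at the pH of half-maximal response and `nH` at
#' 1, with `nH` bounded in (0, 10].
#'
#' @param pH pH values (>= 4 points spanning the transition).
#' @param amplitude response amplitudes.
#' @param decreasing `TRUE` for the SSD form, `FALSE` for activation,
#'   `"auto"` (default) to choose by the sign of the pH--amplitude trend.
#' @return object of class `hill_fit` with fields `pH50`, `nH`, `Imax`,
#'   `rms_residual`, `decreasing`.
#' @export
hill_fit <- function(pH, amplitude, decreasing = "auto") {
  stopifnot(length(pH) == length(amplitude))
  if (length(pH) < 4L) stop("need at least 4 points for a Hill fit")
  if (diff(range(amplitude)) <= .Machine$double.eps^0.5 * max(abs(amplitude), 1))
    stop("flat data: Hill fit unidentifiable")
  if (identical(decreasing, "auto"))
    decreasing <- stats::cor(pH, amplitude) > 0
  ## signed exponent: response = Imax / (1 + 10^(sgn * nH * (pH - pH50)))
  sgn <- if (decreasing) -1 else 1
  half <- min(amplitude) + diff(range(amplitude)) / 2
  p50_init <- pH[which.min(abs(amplitude - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      amplitude ~ Imax / (1 + 10^(sgn * nH * (pH - pH50))),
      start = list(Imax = max(abs(amplitude)), pH50 = p50_init, nH = 1),
      lower = c(Imax = 0, pH50 = min(pH) - 1, nH = 1e-3),
      upper = c(Imax = Inf, pH50 = max(pH) + 1, nH = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  structure(list(pH50 = unname(cf["pH50"]), nH = unname(cf["nH"]),
                 Imax = unname(cf["Imax"]),
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 decreasing = decreasing),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): pH50 %.3f, nH %.3f, Imax %.4g, rms %.3g\n",
              if (x$decreasing) "SSD form" else "activation form",
              x$pH50, x$nH, x$Imax, x$rms_residual))
  invisible(x)
}

#' Correlation rule for dF vs current kinetics
#'
#' Ordinary least-squares regression (with intercept) of the fluorescence
#' rise time on the current rise time across cells. The kinetics are
#' classified as correlated when the slope lies in `[0.75, 1.33]`
#' (boundaries inclusive).
#'
#' @param rt_pairs data frame (or matrix) with columns `RT_I` and `RT_F`,
#'   one row per cell; at least 3 rows with positive rise times.
#' @return object of class `correlation_result` with `slope`, `intercept`,
#'   `n_points` and `classification` (`"correlated"`/`"not_correlated"`).
#' @export
correlation_classification <- function(rt_pairs) {
  rt_pairs <- as.data.frame(rt_pairs)
  if (!all(c("RT_I", "RT_F") %in% names(rt_pairs)))
    stop("'rt_pairs' needs columns 'RT_I' and 'RT_F'")
  rt_pairs <- rt_pairs[stats::complete.cases(rt_pairs[c("RT_I", "RT_F")]), ]
  if (nrow(rt_pairs) < 3L) stop("need at least 3 (RT_I, RT_F) pairs")
  if (any(rt_pairs$RT_I <= 0) || any(rt_pairs$RT_F <= 0))
    stop("rise times must be positive")
  if (stats::var(rt_pairs$RT_I) == 0)
    stop("zero variance in RT_I: slope undefined")
  cf <- coef(lm(RT_F ~ RT_I, data = rt_pairs))
  slope <- unname(cf["RT_I"])
  structure(list(slope = slope, intercept = unname(cf["(Intercept)"]),
                 n_points = nrow(rt_pairs),
                 classification = if (slope >= 0.75 && slope <= 1.33)
                   "correlated" else "not_correlated"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("RT_F ~ RT_I: slope %.3f (n = %d) -> %s\n", x$slope,
              x$n_points, x$classification))
  invisible(x)
}

#' Signal-specificity ratio of a fluorescence component
#'
#' Ratio of the peak |dF/F| evoked by acidification from the desensitized
#' state to the peak |dF/F| evoked from the closed state (conditioning at
#' mildly acidic pH desensitizes the channels without opening them). The
#' lower the ratio, the more state-specific the signal.
#'
#' @param desensitized_start,closed_start [generate_recording()]-style
#'   recordings whose metadata carries the pulse window.
#' @return dimensionless ratio.
#' @export
specificity_ratio <- function(desensitized_start, closed_start) {
  pk <- function(rec) {
    win <- c(rec$meta$pulse_start, rec$meta$pulse_end)
    peak_sustained(rec$time, rec$dF_over_F, win)$peak
  }
  p_closed <- pk(closed_start)
  if (abs(p_closed) == 0) stop("zero closed-state signal: ratio undefined")
  abs(pk(desensitized_start)) / abs(p_closed)
}

#' Trailing simple moving average
#'
#' `D_t = (1/n) sum of the last n samples`, with shrinking windows at the
#' start so the output has the length of the input. This is the smoother
#' conventionally applied to molecular-dynamics distance time series.
#'
#' @param x numeric vector.
#' @param n window length (>= 1).
#' @return smoothed vector, same length as `x`.
#' @examples
#' moving_average(c(0, 3, 6), 3)  # 0, 1.5, 3
#' @export
moving_average <- function(x, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be >= 1")
  n <- as.integer(n)
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - n + 1L, 1L)
  (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
}

#' Extract the kinetics summary of a recording
#'
#' Computes the full set of kinetics and amplitude statistics used
#' throughout the analysis: current onset rise time and decay time within
#' the pulse window, fluorescence onset rise time, fluorescence
#' off-relaxation time after the return to conditioning pH, peak and
#' sustained dF/F, the transient/sustained pattern flag, and the derived
#' ratios.
#'
#' @param recording a recording (see [generate_recording()]); its metadata
#'   must carry `pulse_start` and `pulse_end`.
#' @param noise_floor_I,noise_floor_F amplitude floors below which kinetics
#'   are flagged undefined (`NA`).
#' @param smooth smoothing width passed to [rise_time()]/[decay_time()].
#' @return object of class `kinetics_summary`: a list with fields
#'   `RT_I_on`, `DT_I`, `RT_F_on`, `RT_F_off`, `peak_F`, `sustained_F`,
#'   `transient`, `ratio_RTF_RTI`, `ratio_sust_peak`.
#' @export
analyze_recording <- function(recording, noise_floor_I = 0,
                              noise_floor_F = 0, smooth = 5) {
  stopifnot(inherits(recording, "vcf_recording"))
  m <- recording$meta
  win <- c(m$pulse_start, m$pulse_end)
  off_win <- c(m$pulse_end, max(recording$time))
  RT_I_on <- rise_time(recording$time, recording$current, win,
                       noise_floor = noise_floor_I, smooth = smooth)
  DT_I <- decay_time(recording$time, recording$current, win,
                     noise_floor = noise_floor_I, smooth = smooth)
  RT_F_on <- rise_time(recording$time, recording$dF_over_F, win,
                       noise_floor = noise_floor_F, smooth = smooth)
  RT_F_off <- decay_time(recording$time, recording$dF_over_F, off_win,
                         noise_floor = noise_floor_F, smooth = smooth)
  ps <- peak_sustained(recording$time, recording$dF_over_F, win,
                       noise_floor = noise_floor_F)
  structure(list(RT_I_on = RT_I_on, DT_I = DT_I, RT_F_on = RT_F_on,
                 RT_F_off = RT_F_off, peak_F = ps$peak,
                 sustained_F = ps$sustained, transient = ps$transient,
                 ratio_RTF_RTI = RT_F_on / RT_I_on,
                 ratio_sust_peak = ps$ratio_sust_peak),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(paste0("Kinetics: RT_I %.3g s, DT_I %.3g s, RT_F_on %.3g s, ",
                     "RT_F_off %.3g s\n  peak dF/F %.4g, sustained %.4g (%s)\n"),
              x$RT_I_on, x$DT_I, x$RT_F_on, x$RT_F_off, x$peak_F,
              x$sustained_F,
              if (isTRUE(x$transient)) "transient" else "sustained"))
  invisible(x)
}
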