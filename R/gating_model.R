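## Two-gate Hodgkin-Huxley-style kinetic model of ASIC1a gating.
##
## Each gate (activation `a`, sensitization `s`) is a first-order process
## whose steady state is a Hill function of proton concentration and whose
## time constant interpolates between an alkaline and an acidic limit. The
## gates are independent; their product rule defines the four functional
## states C, O, CD, OD. Only the open state conducts.

#' Parameters of one gate
#'
#' A gate is a first-order process `da/dt = (a_inf(pH) - a) / tau(pH)`.
#' Its steady state `a_inf` follows a Hill function of proton concentration
#' (midpoint `pH50`, coefficient `hill_n`) and its time constant `tau(pH)`
#' interpolates between `tau_alkaline` and `tau_acidic` with its own Hill
#' midpoint `tau_pH50` and coefficient `tau_hill_n`.
#'
#' @param pH50 midpoint of the steady-state curve (pH units).
#' @param hill_n Hill coefficient in proton concentration (> 0).
#' @param tau_alkaline time constant in the alkaline limit (s, > 0).
#' @param tau_acidic time constant in the acidic limit (s, > 0).
#' @param tau_pH50 midpoint of the time-constant transition (pH units).
#' @param tau_hill_n Hill coefficient of the time-constant transition (> 0).
#' @return An object of class `asic_gate`.
#' @examples
#' g <- gate_parameters(7.0, 1, 1, 0.1, 7.0, 2)
#' gate_steady_state(6.0, g)
#' @export
gate_parameters <- function(pH50, hill_n, tau_alkaline, tau_acidic,
                            tau_pH50 = pH50, tau_hill_n = hill_n) {
  stopifnot(is.numeric(pH50), length(pH50) == 1L, is.finite(pH50))
  if (!is.finite(hill_n) || hill_n <= 0) stop("'hill_n' must be > 0")
  if (!is.finite(tau_alkaline) || tau_alkaline <= 0)
    stop("'tau_alkaline' must be > 0")
  if (!is.finite(tau_acidic) || tau_acidic <= 0)
    stop("'tau_acidic' must be > 0")
  if (!is.finite(tau_pH50)) stop("'tau_pH50' must be finite")
  if (!is.finite(tau_hill_n) || tau_hill_n <= 0)
    stop("'tau_hill_n' must be > 0")
  structure(list(pH50 = pH50, hill_n = hill_n,
                 tau_alkaline = tau_alkaline, tau_acidic = tau_acidic,
                 tau_pH50 = tau_pH50, tau_hill_n = tau_hill_n),
            class = "asic_gate")
}

#' Steady-state open probability of a gate
#'
#' `x^n / (x^n + K^n)` with `x = 10^-pH` and `K = 10^-pH50`: monotone
#' non-decreasing with acidity, equal to 1/2 at `pH = pH50`.
#'
#' @param pH pH value(s).
#' @param gate an [gate_parameters()] object.
#' @return Probabilities in `[0, 1]`, same length as `pH`.
#' @export
gate_steady_state <- function(pH, gate) {
  stopifnot(inherits(gate, "asic_gate"))
  ## computed in log10 space to avoid under/overflow at extreme pH
  z <- gate$hill_n * (gate$pH50 - pH)    # log10((x/K)^n)
  1 / (1 + 10^(-z))
}

#' pH-dependent time constant of a gate
#'
#' Hill interpolation between the two limits:
#' `tau_acidic + (tau_alkaline - tau_acidic) * K'^m / (x^m + K'^m)` with
#' `x = 10^-pH`, `K' = 10^-tau_pH50`, `m = tau_hill_n`. Bounded by the two
#' limits and equal to their mean at `pH = tau_pH50`.
#'
#' @inheritParams gate_steady_state
#' @return Time constants in seconds, same length as `pH`.
#' @export
gate_time_constant <- function(pH, gate) {
  stopifnot(inherits(gate, "asic_gate"))
  z <- gate$tau_hill_n * (gate$tau_pH50 - pH)  # log10((x/K')^m)
  w <- 1 / (1 + 10^z)                          # K'^m / (x^m + K'^m)
  gate$tau_acidic + (gate$tau_alkaline - gate$tau_acidic) * w
}

#' Four-state two-gate channel model
#'
#' Combines an activation and a sensitization gate into the four-state
#' scheme C, O, CD, OD (product rule of two independent gates); only the
#' open state conducts current. The default parameters are calibrated to
#' the qualitative behaviour of ASIC1a: steady-state desensitization
#' alkaline-shifted relative to activation, transient pH 6 currents, slow
#' recovery from desensitization at pH 7.4, and a biphasic peak occupancy
#' of the closed-desensitized state.
#'
#' @param activation,sensitization [gate_parameters()] objects.
#' @param current_scale current per unit open probability (> 0).
#' @param current_sign +1 or -1; inward currents are rendered negative.
#' @return An object of class `asic_model`.
#' @export
channel_model <- function(activation = gate_parameters(6.60, 3.0, 0.30, 0.02,
                                                       6.60, 3.0),
                          sensitization = gate_parameters(7.05, 4.5, 8.0, 1.2,
                                                         7.00, 3.0),
                          current_scale = 1, current_sign = -1) {
  stopifnot(inherits(activation, "asic_gate"),
            inherits(sensitization, "asic_gate"))
  if (!is.finite(current_scale) || current_scale <= 0)
    stop("'current_scale' must be > 0")
  if (!current_sign %in% c(-1, 1)) stop("'current_sign' must be +1 or -1")
  structure(list(activation = activation, sensitization = sensitization,
                 current_scale = current_scale, current_sign = current_sign),
            class = "asic_model")
}

#' @export
print.asic_model <- function(x, ...) {
  cat("Two-gate four-state channel model\n")
  for (g in c("activation", "sensitization")) {
    p <- x[[g]]
    cat(sprintf("  %-13s pH50 %.2f, nH %.2f, tau %.3g -> %.3g s (mid %.2f, n %.2f)\n",
                g, p$pH50, p$hill_n, p$tau_alkaline, p$tau_acidic,
                p$tau_pH50, p$tau_hill_n))
  }
  cat(sprintf("  current: sign %+d, scale %g\n", x$current_sign,
              x$current_scale))
  invisible(x)
}

#' Piecewise pH stimulation protocol
#'
#' An ordered list of segments, each holding a target pH for a duration.
#' Within a segment the bath pH relaxes exponentially toward the target
#' with time constant `fall_time / ln 9`, so that the 10--90\% transit of
#' each transition equals `fall_time`; `fall_time = 0` gives instantaneous
#' steps. The first segment must sit at the conditioning pH, at which the
#' gates are initialized at steady state.
#'
#' @param segments data frame with columns `duration_s` and `pH`.
#' @param conditioning_pH initial equilibrium pH.
#' @param fall_time 10--90\% completion time of each pH transition (s, >= 0).
#' @param dt sampling step (s, > 0).
#' @return An object of class `ph_protocol`.
#' @seealso [pulse_protocol()] for the standard conditioning/pulse/recovery
#'   layout.
#' @export
ph_protocol <- function(segments, conditioning_pH = 7.4, fall_time = 0.2,
                        dt = 0.001) {
  segments <- as.data.frame(segments)
  if (!all(c("duration_s", "pH") %in% names(segments)))
    stop("'segments' needs columns 'duration_s' and 'pH'")
  if (nrow(segments) < 1L || any(segments$duration_s <= 0))
    stop("invalid protocol: segment durations must be > 0")
  if (!is.finite(fall_time) || fall_time < 0)
    stop("invalid protocol: 'fall_time' must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("invalid protocol: 'dt' must be > 0")
  if (abs(segments$pH[1] - conditioning_pH) > 1e-12)
    stop("invalid protocol: first segment pH must equal 'conditioning_pH'")
  structure(list(segments = segments, conditioning_pH = conditioning_pH,
                 fall_time = fall_time, dt = dt),
            class = "ph_protocol")
}

#' Standard conditioning / acid pulse / recovery protocol
#'
#' @param test_pH pH of the stimulation pulse.
#' @param conditioning_pH conditioning pH before and after the pulse.
#' @param pre_s,pulse_s,post_s segment durations (s).
#' @param fall_time,dt see [ph_protocol()].
#' @return A `ph_protocol` whose second segment is the stimulation pulse.
#' @export
pulse_protocol <- function(test_pH = 6.0, conditioning_pH = 7.4, pre_s = 2,
                           pulse_s = 10, post_s = 40, fall_time = 0.2,
                           dt = 0.001) {
  ph_protocol(data.frame(duration_s = c(pre_s, pulse_s, post_s),
                         pH = c(conditioning_pH, test_pH, conditioning_pH)),
              conditioning_pH = conditioning_pH, fall_time = fall_time,
              dt = dt)
}

## Segment start times and entry pH values (analytic, segment-recursive).
protocol_breaks <- function(protocol) {
  seg <- protocol$segments
  start <- cumsum(c(0, seg$duration_s))
  n <- nrow(seg)
  entry <- numeric(n)
  entry[1] <- protocol$conditioning_pH
  tau_ex <- protocol$fall_time / log(9)
  if (n > 1) {
    for (k in 2:n) {
      prev <- seg$pH[k - 1]
      e <- if (tau_ex > 0) exp(-seg$duration_s[k - 1] / tau_ex) else 0
      entry[k] <- prev + (entry[k - 1] - prev) * e
    }
  }
  list(start = start[seq_len(n)], end = start[-1L],
       target = seg$pH, entry = entry, tau_ex = tau_ex,
       total = start[n + 1L])
}

#' Evaluate the protocol pH at arbitrary times
#'
#' Analytic segment-wise exponential relaxation; used by [ph_waveform()]
#' and usable as the forcing function of an external ODE solver.
#'
#' @param protocol a [ph_protocol()].
#' @param t times in seconds (vector); values outside `[0, total]` are
#'   clamped to the protocol range.
#' @return pH values, same length as `t`.
#' @export
ph_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "ph_protocol"))
  b <- protocol_breaks(protocol)
  t <- pmin(pmax(t, 0), b$total)
  k <- findInterval(t, b$start, rightmost.closed = FALSE)
  k[k < 1L] <- 1L
  if (b$tau_ex > 0) {
    b$target[k] + (b$entry[k] - b$target[k]) * exp(-(t - b$start[k]) / b$tau_ex)
  } else {
    b$target[k]
  }
}

#' Sampled pH waveform of a protocol
#'
#' @param protocol a [ph_protocol()].
#' @return data frame with columns `time` and `pH`, sampled at `dt` from 0
#'   to the total protocol duration.
#' @export
ph_waveform <- function(protocol) {
  stopifnot(inherits(protocol, "ph_protocol"))
  b <- protocol_breaks(protocol)
  n <- round(b$total / protocol$dt)
  time <- protocol$dt * (0:n)
  data.frame(time = time, pH = ph_value(protocol, time))
}

#' Integrate the two gates along a pH protocol
#'
#' Per-sample exponential update `a <- a_inf + (a - a_inf) * exp(-dt/tau)`
#' per gate, with the Hill coefficients frozen at the midpoint pH of each
#' step (exact for constant pH, second-order accurate during pH ramps,
#' unconditionally stable). Gates start at the steady state of the
#' conditioning pH.
#'
#' @param model an [channel_model()].
#' @param protocol a [ph_protocol()].
#' @return An `asic_trajectory`: a data frame with columns `time`, `pH`,
#'   `a`, `s`, `P_C`, `P_O`, `P_CD`, `P_OD`, carrying the model and
#'   protocol as attributes.
#' @export
integrate_gates <- function(model, protocol) {
  stopifnot(inherits(model, "asic_model"), inherits(protocol, "ph_protocol"))
  dt <- protocol$dt
  wf <- ph_waveform(protocol)
  time <- wf$time
  pH_mid <- ph_value(protocol, pmax(time - dt / 2, 0))
  traj <- data.frame(time = time, pH = wf$pH)
  for (g in c("activation", "sensitization")) {
    gate <- model[[g]]
    target <- gate_steady_state(pH_mid, gate)
    decay <- exp(-dt / gate_time_constant(pH_mid, gate))
    init <- gate_steady_state(protocol$conditioning_pH, gate)
    traj[[if (g == "activation") "a" else "s"]] <-
      recursive_relax(target, decay, init)
  }
  p <- state_probabilities(traj$a, traj$s)
  traj$P_C <- p$P_C; traj$P_O <- p$P_O
  traj$P_CD <- p$P_CD; traj$P_OD <- p$P_OD
  attr(traj, "model") <- model
  attr(traj, "protocol") <- protocol
  class(traj) <- c("asic_trajectory", "data.frame")
  traj
}

#' State probabilities from the two gate variables
#'
#' Product rule of two independent gates: `P_O = a(1-s)`, `P_OD = as`,
#' `P_CD = (1-a)s`, `P_C = (1-a)(1-s)`; the four probabilities sum to 1
#' exactly.
#'
#' @param a,s activation and sensitization gate probabilities in `[0, 1]`.
#' @return list with components `P_C`, `P_O`, `P_CD`, `P_OD`.
#' @export
state_probabilities <- function(a, s) {
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("'a' must lie in [0, 1]")
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("'s' must lie in [0, 1]")
  list(P_C = (1 - a) * (1 - s), P_O = a * (1 - s),
       P_CD = (1 - a) * s, P_OD = a * s)
}

#' Current carried by the open state
#'
#' `current = current_sign * current_scale * P_O(t)`.
#'
#' @param trajectory an [integrate_gates()] result.
#' @param model the [channel_model()]; defaults to the one stored in the
#'   trajectory.
#' @return numeric vector of currents, one per sample.
#' @export
simulate_current <- function(trajectory, model = attr(trajectory, "model")) {
  stopifnot(inherits(trajectory, "asic_trajectory"),
            inherits(model, "asic_model"))
  model$current_sign * model$current_scale * trajectory$P_O
}

## Window (start, end) of the stimulation pulse: the first segment whose
## target differs from the conditioning pH.
protocol_pulse_window <- function(protocol) {
  b <- protocol_breaks(protocol)
  k <- which(abs(b$target - protocol$conditioning_pH) > 1e-12)
  if (length(k) == 0L) stop("protocol has no stimulation segment")
  c(b$start[k[1]], b$end[k[1]])
}

## Replace the pH of the stimulation (second) segment of a template.
with_test_pH <- function(template, test_pH) {
  seg <- template$segments
  if (nrow(seg) < 2L) stop("protocol template needs a stimulation segment")
  seg$pH[2] <- test_pH
  ph_protocol(seg, conditioning_pH = template$conditioning_pH,
              fall_time = template$fall_time, dt = template$dt)
}

ph_response <- function(pH, amplitude, fit, statistic) {
  structure(list(pH = pH, amplitude = amplitude, fit = fit,
                 statistic = statistic),
            class = "ph_response")
}

#' @export
print.ph_response <- function(x, ...) {
  cat(sprintf("pH-response curve (%s), %d points\n", x$statistic,
              length(x$pH)))
  if (!is.null(x$fit))
    cat(sprintf("  Hill fit: pH50 %.3f, nH %.2f\n", x$fit$pH50, x$fit$nH))
  invisible(x)
}

#' pH dependence of peak current activation
#'
#' For each pH on the grid, runs the stimulation protocol from the
#' conditioning pH, records the peak current magnitude during the pulse,
#' normalizes to the grid maximum and fits a Hill curve.
#'
#' @param model an [channel_model()].
#' @param pH_grid stimulation pH values (within (4, 9)).
#' @param protocol_template protocol whose second segment is the test pulse.
#' @return A `ph_response` object with fields `pH`, `amplitude` (normalized)
#'   and `fit` (a [hill_fit()] result).
#' @export
activation_curve <- function(model, pH_grid,
                             protocol_template = pulse_protocol(post_s = 2)) {
  stopifnot(all(pH_grid > 4), all(pH_grid < 9))
  peaks <- vapply(pH_grid, function(ph) {
    proto <- with_test_pH(protocol_template, ph)
    traj <- integrate_gates(model, proto)
    win <- protocol_pulse_window(proto)
    i <- traj$time >= win[1] & traj$time <= win[2]
    max(abs(simulate_current(traj, model)[i]))
  }, numeric(1))
  if (max(peaks) <= 0) stop("all-zero amplitudes: cannot normalize")
  amp <- peaks / max(peaks)
  fit <- hill_fit(pH_grid, amp, decreasing = FALSE)
  ph_response(pH_grid, amp, fit, "peak current activation")
}

#' Steady-state desensitization (SSD) curve of the model
#'
#' For each conditioning pH on the grid, the model is equilibrated at the
#' resting pH, conditioned for `conditioning_s` seconds at the grid pH, and
#' then stimulated at `test_pH`. Peak current magnitudes are normalized to
#' the most alkaline conditioning value and fitted with the SSD form of the
#' Hill equation (decreasing with conditioning acidity).
#'
#' @param model an [channel_model()].
#' @param conditioning_grid conditioning pH values.
#' @param test_pH stimulation pH (default 6.0).
#' @param conditioning_s conditioning duration (s).
#' @param resting_pH pH at which the gates start at equilibrium.
#' @param pulse_s,fall_time,dt protocol settings.
#' @return A `ph_response` object.
#' @export
ssd_curve <- function(model, conditioning_grid, test_pH = 6.0,
                      conditioning_s = 50, resting_pH = 7.4, pulse_s = 10,
                      fall_time = 0.2, dt = 0.001) {
  peaks <- vapply(conditioning_grid, function(cond) {
    proto <- ph_protocol(
      data.frame(duration_s = c(1, conditioning_s, pulse_s, 1),
                 pH = c(resting_pH, cond, test_pH, resting_pH)),
      conditioning_pH = resting_pH, fall_time = fall_time, dt = dt)
    traj <- integrate_gates(model, proto)
    b <- protocol_breaks(proto)
    i <- traj$time >= b$start[3] & traj$time <= b$end[3]
    max(abs(simulate_current(traj, model)[i]))
  }, numeric(1))
  ref <- peaks[which.max(conditioning_grid)]
  if (ref <= 0 || diff(range(peaks)) <= 0)
    stop("degenerate (flat) SSD response: cannot fit")
  amp <- peaks / ref
  fit <- hill_fit(conditioning_grid, amp, decreasing = TRUE)
  ph_response(conditioning_grid, amp, fit, "current SSD")
}

occupancy_of <- function(traj, state) {
  switch(state,
         C = traj$P_C, O = traj$P_O, CD = traj$P_CD, OD = traj$P_OD,
         `O+OD` = traj$P_O + traj$P_OD,
         `CD+OD` = traj$P_CD + traj$P_OD,
         stop("unknown state '", state, "'"))
}

asic_states <- c("C", "O", "CD", "OD", "O+OD", "CD+OD")

#' Peak state occupancy across a pH grid
#'
#' Peak occupancy of each state (and of the two gate sums O+OD and CD+OD)
#' during an acidic pulse, normalized per state across the grid. The peak
#' is measured after the solution exchange is complete (window offset by
#' ten fall times) so that the conditioning occupancy does not mask the
#' response.
#'
#' @param model an [channel_model()].
#' @param pH_grid stimulation pH values.
#' @param protocol_template protocol whose second segment is the test
#'   pulse; the default uses a 20 s pulse.
#' @return data frame with columns `state`, `pH`, `peak`, `normalized`.
#' @export
state_peak_curves <- function(model, pH_grid,
                              protocol_template = pulse_protocol(pulse_s = 20,
                                                                 post_s = 2)) {
  res <- lapply(pH_grid, function(ph) {
    proto <- with_test_pH(protocol_template, ph)
    traj <- integrate_gates(model, proto)
    win <- protocol_pulse_window(proto)
    i <- traj$time >= win[1] + 10 * proto$fall_time & traj$time <= win[2]
    vapply(asic_states, function(st) max(occupancy_of(traj, st)[i]),
           numeric(1))
  })
  peaks <- do.call(rbind, res)
  out <- do.call(rbind, lapply(seq_along(asic_states), function(j) {
    pk <- peaks[, j]
    data.frame(state = asic_states[j], pH = pH_grid, peak = pk,
               normalized = pk / max(pk))
  }))
  rownames(out) <- NULL
  out
}

#' Rise time of state occupancies upon acidification
#'
#' 10--90\% rise time of each state's occupancy during the pulse, computed
#' with [rise_time()]. States whose occupancy change stays below
#' `noise_floor` are reported as `NA` (undefined), not as an error.
#'
#' @inheritParams state_peak_curves
#' @param states which occupancies to analyse.
#' @param noise_floor minimum occupancy excursion for a defined rise time.
#' @return data frame with columns `state`, `pH`, `rise_time`.
#' @export
occupancy_rise_times <- function(model, pH_grid,
                                 protocol_template = pulse_protocol(post_s = 2),
                                 states = c("O", "OD", "CD", "O+OD", "CD+OD"),
                                 noise_floor = 1e-4) {
  out <- do.call(rbind, lapply(pH_grid, function(ph) {
    proto <- with_test_pH(protocol_template, ph)
    traj <- integrate_gates(model, proto)
    win <- protocol_pulse_window(proto)
    rt <- vapply(states, function(st) {
      rise_time(traj$time, occupancy_of(traj, st), win,
                noise_floor = noise_floor)
    }, numeric(1))
    data.frame(state = states, pH = ph, rise_time = rt)
  }))
  rownames(out) <- NULL
  out
}
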