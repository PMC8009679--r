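test_that("gate steady state follows the Hill closed form", {
  g <- gate_parameters(7.0, 1, 1, 0.1)
  expect_equal(gate_steady_state(7.0, g), 0.5)
  expect_equal(gate_steady_state(6.0, g), 10 / 11, tolerance = 1e-10)
  g3 <- gate_parameters(6.6, 3, 1, 0.1)
  expect_equal(gate_steady_state(6.6, g3), 0.5)
  expect_gte(gate_steady_state(3.0, g3), 0.9999)
  ## monotone non-decreasing with acidity
  ph <- seq(9, 4, by = -0.1)
  expect_true(all(diff(gate_steady_state(ph, g3)) >= 0))
})

test_that("gate time constant interpolates between its two limits", {
  g <- gate_parameters(7.05, 4.5, 8, 1.2, tau_pH50 = 7.0, tau_hill_n = 3)
  expect_equal(gate_time_constant(9, g), 8, tolerance = 1e-3)
  expect_equal(gate_time_constant(4, g), 1.2, tolerance = 1e-3)
  expect_equal(gate_time_constant(7.0, g), (8 + 1.2) / 2)
  tau <- gate_time_constant(seq(9, 4, by = -0.25), g)
  expect_true(all(tau >= 1.2 & tau <= 8))
})

test_that("gate parameter validation rejects degenerate inputs", {
  expect_error(gate_parameters(7, -1, 1, 1), "hill_n")
  expect_error(gate_parameters(7, 1, 0, 1), "tau_alkaline")
  expect_error(gate_parameters(7, 1, 1, Inf), "tau_acidic")
  expect_error(channel_model(current_scale = -2), "current_scale")
})

test_that("pH waveform relaxes exponentially with the 10-90% fall time", {
  p <- pulse_protocol(fall_time = 0.2, post_s = 2)
  wf <- ph_waveform(p)
  ## internal time constant fall_time / ln 9: fit from two samples
  i <- wf$time > 2 & wf$time < 2.5
  lg <- log(wf$pH[i] - 6.0)
  tau_fit <- -1 / coef(lm(lg ~ wf$time[i]))[2]
  expect_equal(unname(tau_fit), 0.2 / log(9), tolerance = 1e-6)
  ## long segment converges to its target
  expect_equal(wf$pH[max(which(wf$time <= 12))], 6.0, tolerance = 1e-6)
  ## fall_time = 0 gives piecewise-constant pH
  p0 <- pulse_protocol(fall_time = 0, post_s = 2)
  expect_true(all(ph_waveform(p0)$pH %in% c(7.4, 6.0)))
  expect_error(pulse_protocol(fall_time = -1), "fall_time")
  expect_error(ph_protocol(data.frame(duration_s = 1, pH = 7.0),
                           conditioning_pH = 7.4), "first segment")
})

test_that("integrator matches the analytic solution at constant pH", {
  m <- default_model
  ps <- ph_protocol(data.frame(duration_s = c(1, 5), pH = c(7.4, 6.3)),
                    fall_time = 0)
  traj <- integrate_gates(m, ps)
  i <- traj$time >= 1
  for (g in c("activation", "sensitization")) {
    gate <- m[[g]]
    yinf <- gate_steady_state(6.3, gate)
    y0 <- gate_steady_state(7.4, gate)
    tau <- gate_time_constant(6.3, gate)
    y <- yinf + (y0 - yinf) * exp(-(traj$time[i] - 1) / tau)
    got <- if (g == "activation") traj$a[i] else traj$s[i]
    expect_lt(max(abs(got - y)), 1e-8)
  }
  ## conditioning equilibrium: no drift before the pH change
  pre <- traj$time < 1
  expect_lt(max(abs(diff(traj$a[pre]))), 1e-10)
  expect_lt(max(abs(diff(traj$s[pre]))), 1e-10)
})

test_that("state probabilities conserve and factorize at every sample", {
  traj <- std_trajectory()
  expect_lt(max(abs(traj$P_C + traj$P_O + traj$P_CD + traj$P_OD - 1)), 1e-9)
  expect_lt(max(abs(traj$P_O * traj$P_CD - traj$P_C * traj$P_OD)), 1e-12)
  expect_true(all(traj$P_C >= 0 & traj$P_C <= 1))
  expect_true(all(traj$P_O >= 0 & traj$P_O <= 1))
})

test_that("state probability arithmetic and domain checks", {
  expect_equal(state_probabilities(1, 0),
               list(P_C = 0, P_O = 1, P_CD = 0, P_OD = 0))
  expect_equal(state_probabilities(0.5, 0.5),
               list(P_C = 0.25, P_O = 0.25, P_CD = 0.25, P_OD = 0.25))
  expect_equal(state_probabilities(0.8, 0.5),
               list(P_C = 0.1, P_O = 0.4, P_CD = 0.1, P_OD = 0.4))
  expect_error(state_probabilities(1.2, 0.5), "\\[0, 1\\]")
  expect_error(state_probabilities(0.5, -0.1), "\\[0, 1\\]")
})

test_that("exponential integrator agrees with an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  m <- default_model
  p <- short_protocol
  traj <- integrate_gates(m, p)
  deriv <- function(t, y, parms) {
    ph <- ph_value(p, t)
    list(c((gate_steady_state(ph, m$activation) - y[1]) /
             gate_time_constant(ph, m$activation),
           (gate_steady_state(ph, m$sensitization) - y[2]) /
             gate_time_constant(ph, m$sensitization)))
  }
  y0 <- c(gate_steady_state(7.4, m$activation),
          gate_steady_state(7.4, m$sensitization))
  sol <- deSolve::lsoda(y0, traj$time, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  a <- sol[, 2]; s <- sol[, 3]
  expect_lt(max(abs(a * (1 - s) - traj$P_O)), 1e-3)
  expect_lt(max(abs(a * s - traj$P_OD)), 1e-3)
  expect_lt(max(abs((1 - a) * s - traj$P_CD)), 1e-3)
  expect_lt(max(abs((1 - a) * (1 - s) - traj$P_C)), 1e-3)
})

test_that("halving dt changes state probabilities by < 1e-4", {
  m <- default_model
  t1 <- integrate_gates(m, pulse_protocol(post_s = 5))
  t2 <- integrate_gates(m, pulse_protocol(post_s = 5, dt = 0.0005))
  i <- match(round(t1$time, 6), round(t2$time, 6))
  for (st in c("P_C", "P_O", "P_CD", "P_OD"))
    expect_lt(max(abs(t2[[st]][i] - t1[[st]])), 1e-4)
})

test_that("current is the scaled open-state probability", {
  traj <- std_trajectory()
  m <- default_model
  I <- simulate_current(traj, m)
  expect_equal(I, -traj$P_O)
  m2 <- channel_model(current_scale = 2)
  expect_equal(simulate_current(traj, m2), 2 * I)
  expect_equal(which.max(abs(I)), which.max(traj$P_O))
  ## closed channel carries no current
  z <- traj; z$P_O <- 0 * z$P_O
  expect_true(all(simulate_current(z, m) == 0))
})

test_that("activation is right-shifted relative to SSD and saturates", {
  ac <- cached("act_curve",
               activation_curve(default_model, seq(8.0, 5.0, by = -0.25)))
  sc <- cached("ssd_curve",
               ssd_curve(default_model, seq(7.8, 6.4, by = -0.1)))
  expect_lt(ac$fit$pH50, sc$fit$pH50)   # SSD alkaline-shifted
  expect_lt(ac$amplitude[1], 0.01)      # no activation at pH 8
  expect_equal(max(ac$amplitude), 1)
  ## SSD reference and saturation
  expect_gt(sc$amplitude[abs(sc$pH - 7.4) < 1e-9], 0.95)
  expect_lt(sc$amplitude[abs(sc$pH - 6.5) < 1e-9], 0.05)
  expect_true(all(diff(sc$amplitude) <= 1e-6))  # monotone with acidity
})

test_that("state peak curves: biphasic CD, monotone activation gate", {
  pc <- cached("peak_curves",
               state_peak_curves(default_model, seq(8.0, 5.0, by = -0.25)))
  cd <- pc[pc$state == "CD", ]
  k <- which.max(cd$normalized)
  expect_gt(k, 1)
  expect_lt(k, nrow(cd))
  expect_gt(cd$normalized[k], cd$normalized[1])
  expect_gt(cd$normalized[k], cd$normalized[nrow(cd)])
  oo <- pc[pc$state == "O+OD", ]
  expect_true(all(diff(oo$normalized) >= -1e-9))
  for (st in unique(pc$state))
    expect_equal(max(pc$normalized[pc$state == st]), 1)
})

test_that("occupancy rise times accelerate with stimulation acidity", {
  rt <- cached("occ_rt",
               occupancy_rise_times(default_model, c(6.5, 6.0, 5.5)))
  rt_of <- function(st, ph) rt$rise_time[rt$state == st & rt$pH == ph]
  expect_gt(rt_of("O", 6.5), rt_of("O", 5.5))
  expect_gt(rt_of("OD", 6.0), rt_of("O", 6.0))
  expect_gt(rt_of("OD", 6.5), rt_of("OD", 5.5))
})

test_that("occupancy rise time reduces to tau ln 9 for a pure gate step", {
  g <- gate_parameters(6.6, 3, 0.1, 0.1)   # constant tau = 0.1 s
  m <- channel_model(activation = g)
  rt <- occupancy_rise_times(m, 5.0,
                             pulse_protocol(test_pH = 5, fall_time = 0,
                                            post_s = 1),
                             states = "O+OD")
  expect_equal(rt$rise_time, 0.1 * log(9), tolerance = 0.002)
})

test_that("model and protocol survive a JSON round trip", {
  tmp <- tempfile(fileext = ".json")
  write_channel_model(default_model, tmp)
  m2 <- read_channel_model(tmp)
  expect_equal(m2, default_model)
  tmp2 <- tempfile(fileext = ".json")
  write_ph_protocol(std_protocol, tmp2)
  p2 <- read_ph_protocol(tmp2)
  expect_equal(p2$segments$pH, std_protocol$segments$pH)
  expect_equal(p2$fall_time, std_protocol$fall_time)
  expect_equal(p2$dt, std_protocol$dt)
})
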