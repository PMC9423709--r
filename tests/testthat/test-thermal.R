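tp <- thermal_params()

test_that("temperature factor phi has the right anchors and decade law", {
  expect_equal(phi(6.3, tp), 1)
  expect_equal(phi(16.3, tp), 3)
  expect_equal(phi(36.3, tp), 27)
  for (T in seq(-10, 40, by = 7.3)) {
    expect_equal(phi(T + 10, tp), 3 * phi(T, tp))
    expect_gt(phi(T, tp), 0)
  }
  expect_true(all(diff(phi(seq(0, 45, 0.5), tp)) > 0))
})

test_that("Curie-Weiss capacitance: limits, anchor value, pole", {
  expect_equal(membrane_capacitance(20, thermal_params(k = 0)), 0.824)
  expect_equal(membrane_capacitance(47.8, tp), 1.824)
  # monotone increasing below the Curie temperature
  Ts <- seq(-20, 49, by = 0.5)
  expect_true(all(diff(membrane_capacitance(Ts, tp)) > 0))
  expect_equal(membrane_capacitance(tp$T_ref, tp),
               tp$C0 + tp$k / (tp$Tc - tp$T_ref))
  expect_error(membrane_capacitance(50, tp), "Curie")
  expect_error(membrane_capacitance(55, tp), "Curie")
})

test_that("thermal_params validates its ranges", {
  expect_error(thermal_params(Tc = 5), "T_ref")
  expect_warning(thermal_params(Tc = 45, T_ref = 6.3, k = 2.2), NA)
  expect_warning(thermal_params(Tc = 30.5), "31")
  expect_error(thermal_params(C0 = -1))
})

test_that("capacitive current: zeros, literal value, symmetry, linearity", {
  expect_equal(capacitive_current(-70, 0, tp), 0)
  expect_equal(capacitive_current(28, 5, tp), 0)   # vm = Vs
  expect_equal(capacitive_current(-70, 1, tp), 3.13e-3 * 1 * (-98))
  # odd in (vm - Vs), linear in dT/dt
  for (dv in c(1, 13.7, 40)) {
    expect_equal(capacitive_current(28 + dv, 2, tp),
                 -capacitive_current(28 - dv, 2, tp))
  }
  for (rate in c(-2, 0.5, 3)) {
    expect_equal(capacitive_current(-50, rate, tp),
                 rate * capacitive_current(-50, 1, tp))
  }
})

test_that("fractional capacitive-current mode scales by the capacitance", {
  tpf <- thermal_params(cap_mode = "fractional")
  Cm <- membrane_capacitance(20, tpf)
  expect_equal(capacitive_current(-70, 1, tpf, Cm),
               3.13e-3 * Cm * (-98))
})

test_that("rectangular protocol: plateau, ramps, baseline outside", {
  p <- temperature_protocol("rectangular", baseline = 6.3,
                            segments = list(c(3, 6, 10)), edge_ramp = 0.1)
  ev <- protocol_eval(p, c(0, 2.9, 4.5, 3.05, 6.05, 8))
  expect_equal(ev$T_degC, c(6.3, 6.3, 16.3, 11.3, 11.3, 6.3))
  # ramp slope 10 degC / 0.1 s = 0.1 degC/ms
  expect_equal(ev$dT_dt_degC_ms, c(0, 0, 0, 0.1, -0.1, 0))
})

test_that("constant protocol is flat with zero rate", {
  p <- temperature_protocol("constant", baseline = 16.3)
  ev <- protocol_eval(p, seq(0, 10, by = 0.5))
  expect_true(all(ev$T_degC == 16.3))
  expect_true(all(ev$dT_dt_degC_ms == 0))
})

test_that("dT/dt integrates to the temperature difference on any protocol", {
  protos <- list(
    temperature_protocol("rectangular", baseline = 6.3,
                         segments = list(c(3, 6, 10), c(9, 12, 20),
                                         c(15, 18, 30))),
    temperature_protocol("saturating", baseline = 6.3,
                         segments = list(c(2, 8, 15)), tau = 1.5))
  for (p in protos) {
    t <- seq(0, 20, by = 1e-4)
    # midpoint quadrature of the analytic rate (degC/ms over t in s);
    # protocol kinks fall on grid points, so every cell is smooth inside
    mid <- (t[-1] + t[-length(t)]) / 2
    rate_s <- protocol_eval(p, mid)$dT_dt_degC_ms * 1000
    integ <- cumsum(rate_s * diff(t))
    Tt <- protocol_eval(p, t)$T_degC
    expect_lt(max(abs(integ - (Tt[-1] - Tt[1]))), 1e-6)
  }
})

test_that("saturating protocol is continuous and approaches its plateau", {
  p <- temperature_protocol("saturating", baseline = 6.3,
                            segments = list(c(1, 20, 10)), tau = 0.8)
  ev <- protocol_eval(p, seq(0, 20, by = 1e-3))
  expect_lt(max(abs(diff(ev$T_degC))), 0.02)    # no jumps
  expect_lt(abs(ev$T_degC[ev$t_s == 10] - 16.3), 10 * exp(-9 / 0.8) + 1e-6)
  expect_true(all(ev$T_degC >= 6.3 - 1e-12))
})

test_that("protocols violating the Curie temperature are rejected", {
  p <- temperature_protocol("rectangular", baseline = 6.3,
                            segments = list(c(1, 3, 45)))
  expect_error(check_protocol(p, tp, 5), "Curie")
  ok <- temperature_protocol("rectangular", baseline = 6.3,
                             segments = list(c(1, 3, 30)))
  expect_true(check_protocol(ok, tp, 5))
})

test_that("malformed protocol segments are rejected", {
  expect_error(temperature_protocol("rectangular",
                                    segments = list(c(3, 2, 10))), "offset")
  expect_error(temperature_protocol("rectangular",
                                    segments = list(c(1, 4, 5), c(3, 6, 5))),
               "overlap")
})
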