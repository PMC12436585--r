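test_that("systolic flux integrates to the stroke volume for both shapes", {
  for (shape in c("HALF_SINE", "TRAPEZOID")) {
    wf <- make_waveform(70, 73500, 0.35, shape)
    expect_equal(wf$period, 60 / 70)
    vol <- stats::integrate(wf$inlet_flux, 0, wf$t_sys,
                            subdivisions = 2000, rel.tol = 1e-9)$value
    expect_lt(abs(vol - 73500) / 73500, 0.001)
    ## flux nonnegative in systole, identically zero in diastole
    ts <- seq(0, wf$period, length.out = 500)
    q <- wf$inlet_flux(ts)
    expect_true(all(q >= 0))
    expect_true(all(q[ts > wf$t_sys] == 0))
    ## periodicity
    expect_equal(wf$inlet_flux(ts + 3 * wf$period), q, tolerance = 1e-9)
  }
})

test_that("half-sine peak equals the closed-form pi/2 SV/T_sys", {
  wf <- make_waveform(70, 73500, 0.35, "HALF_SINE")
  peak_expected <- pi / 2 * 73500 / wf$t_sys
  expect_equal(wf$inlet_flux(wf$t_sys / 2), peak_expected, tolerance = 1e-9)
  ## and the closed form is consistent with quadrature of the profile
  vol <- stats::integrate(function(t) peak_expected * sin(pi * t / wf$t_sys),
                          0, wf$t_sys, rel.tol = 1e-10)$value
  expect_equal(vol, 73500, tolerance = 1e-6)
})

test_that("waveform parameter validation fails fast", {
  expect_error(make_waveform(stroke_volume = 0), "stroke_volume")
  expect_error(make_waveform(heart_rate = 0), "heart_rate")
  expect_error(make_waveform(systolic_fraction = 0.6), "systolic_fraction")
  expect_error(make_waveform(systolic_fraction = 0.1), "systolic_fraction")
})

test_that("the orifice diameter rule subtracts 6 mm", {
  expect_equal(goa_from_valve(23), 17)
  expect_equal(goa_from_valve(29), 23)
  expect_error(goa_from_valve(6.0), "6.0 mm")
})

test_that("inlet condition switches kind exactly at the valve transitions", {
  wf <- make_waveform()
  sc <- valve_schedule(wf)
  expect_identical(inlet_condition_at(wf$t_sys / 2, wf, sc)$kind, "FLUX")
  expect_equal(inlet_condition_at(wf$t_sys / 2, wf, sc)$value,
               wf$inlet_flux(wf$t_sys / 2))
  mid_dia <- (wf$t_sys + wf$period) / 2
  expect_identical(inlet_condition_at(mid_dia, wf, sc)$kind, "PRESSURE")
  ## closed-interval convention: the closing instant is already diastolic
  expect_identical(inlet_condition_at(wf$t_sys, wf, sc)$kind, "PRESSURE")
  expect_identical(inlet_condition_at(wf$period, wf, sc)$kind, "FLUX")
  expect_error(inlet_condition_at(-1, wf, sc), ">= 0")
})

test_that("Windkessel equilibrium and relaxation match the analytic solution", {
  wkp <- wk2_params()
  expect_equal(wkp$R, 0.121); expect_equal(wkp$C, 9.37)
  Q <- 85000; RC <- wkp$R * wkp$C
  ## equilibrium: P0 = QR stays put
  st <- wk2_state(Q * wkp$R)
  for (i in 1:50) st <- wk2_advance(st, Q, 1e-2, wkp)
  expect_equal(st$pressure, Q * wkp$R, tolerance = 1e-12)
  ## decay from P0 > 0 with Q = 0: pure exponential with time constant RC
  st <- wk2_state(10000)
  for (i in 1:100) st <- wk2_advance(st, 0, 1e-2, wkp)
  expect_equal(st$pressure, 10000 * exp(-1 / RC), tolerance = 1e-10)
  expect_error(wk2_advance(st, 0, -1, wkp), "dt")
  expect_error(wk2_params(R = -1), "positive")
})

test_that("Windkessel step error halves (or better) when dt halves", {
  ## varying inflow; the piecewise-constant-Q exponential scheme is first
  ## order, so halving dt must at least halve the error vs the reference
  wkp <- wk2_params()
  Qfun <- function(t) 60000 * (1 + sin(2 * pi * t / 0.857))
  run <- function(dt) {
    st <- wk2_state(5000)
    n <- round(1 / dt)
    for (k in seq_len(n)) st <- wk2_advance(st, Qfun((k - 0.5) * dt), dt, wkp)
    st$pressure
  }
  ref <- run(1e-5)
  e1 <- abs(run(4e-3) - ref)
  e2 <- abs(run(2e-3) - ref)
  expect_lt(e2, 0.55 * e1)
})

test_that("mean Windkessel pressure over a converged cycle is (mean Q) R", {
  wkp <- wk2_params()
  wf <- make_waveform()
  dt <- 1e-3
  n <- round(wf$period / dt)
  st <- wk2_state(wf$stroke_volume / wf$period * wkp$R)
  ## let transients die out, then record one cycle
  for (k in seq_len(10 * n)) st <- wk2_advance(st, wf$inlet_flux(k * dt), dt, wkp)
  ps <- numeric(n); qs <- numeric(n)
  for (k in seq_len(n)) {
    t <- (10 * n + k) * dt
    st <- wk2_advance(st, wf$inlet_flux(t), dt, wkp)
    ps[k] <- st$pressure; qs[k] <- wf$inlet_flux(t)
  }
  expect_lt(abs(mean(ps) - mean(qs) * wkp$R) / (mean(qs) * wkp$R), 0.02)
})

test_that("waveform table exports the periodic schedule", {
  wf <- make_waveform()
  df <- waveform_table(wf, n = 100)
  expect_named(df, c("t", "Q_in", "P_inlet", "Q_cor", "valve"))
  expect_true(all(df$valve[df$Q_in > 0] == "OPEN"))
  ## per-cycle coronary volume is the configured fraction of stroke volume
  vol_cor <- sum(df$Q_cor) * wf$period / 100
  expect_equal(vol_cor, 0.04 * wf$stroke_volume, tolerance = 0.02)
})
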