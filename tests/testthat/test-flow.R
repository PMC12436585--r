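test_that("each cycle ingests one stroke volume and conserves mass", {
  res <- rf_baseline()
  h <- res$history
  bal <- check_mass_balance(h)
  expect_equal(nrow(bal), 3L)
  ## net cycle imbalance is a tiny fraction of the stroke volume
  expect_true(all(abs(bal$imbalance_frac) < 0.01))
  ## per-cycle inflow volume equals the prescribed stroke volume
  for (cyc in 2:3)
    expect_lt(abs(bal$inflow_volume[cyc] - h$stroke_native) /
                h$stroke_native, 0.01)
})

test_that("cycle-to-cycle summaries converge below the 5% criterion", {
  h <- rf_baseline()$history
  expect_true(h$converged)
  d <- h$deltas
  last <- nrow(d)
  expect_lt(d$d_peak[last], 0.05)
  expect_lt(d$d_tpg[last], 0.05)
  ## start-up transient decays: deltas nonincreasing after the first pair
  ## (ordering is immaterial once both are below the criterion)
  expect_true(all(diff(d$d_peak) <= 0 | d$d_peak[-1] < 0.05))
})

test_that("a single cycle cannot be judged for convergence", {
  m <- build_root_mesh(root_parameters(), 3, "2d")
  wf <- make_waveform()
  cfg <- solver_config(dt = 4e-3, cycles = 1, nonlinear_tolerance = 2e-3,
                       max_nonlinear_iters = 5, snapshot_stride = 8)
  h <- run_cycles(m, wf, valve_spec(23), config = cfg)
  expect_true(h$insufficient_cycles)
  expect_true(is.na(h$converged))
})

test_that("the closed valve admits no transvalvular flow", {
  h <- rf_baseline()$history
  wf <- make_waveform()
  s <- h$series
  dia <- (s$t %% wf$period) > wf$t_sys
  expect_lt(max(abs(s$Q_valve[dia])), 1e-6 * max(s$Q_valve))
  ## diastolic coronary draw is fed entirely from the aortic side
  expect_equal(s$Q_out[dia], -s$Q_cor[dia], tolerance = 1e-6)
  ## and the sealed ventricular side exchanges nothing through the inlet
  expect_lt(max(abs(s$Q_in[dia])), 1e-6 * max(s$Q_in))
})

test_that("valve constraints expose the orifice geometry", {
  m <- rf_baseline()$mesh
  vs <- m$valve$spec
  cl <- valve_constraints(m, vs, "CLOSED")
  expect_setequal(cl$nodes, m$valve$closed_nodes)
  expect_identical(cl$open_area, 0)
  op <- valve_constraints(m, vs, "OPEN")
  expect_setequal(op$nodes, m$valve$annulus_nodes)
  ## open width within one facet of the GOA (2-D planar measure)
  expect_lt(abs(op$open_area - m$valve$goa_diameter), 2 * m$h)
  ## fully open limit: GOA equal to the lumen leaves no annulus ring
  mfull <- build_root_mesh(root_parameters(), 2.5, "2d",
                           valve = valve_spec(23 + 6))
  opf <- valve_constraints(mfull, mfull$valve$spec, "OPEN")
  ## only wall-rim nodes may remain constrained
  wall <- boundary_nodes(mfull, "WALL")
  expect_true(all(opf$nodes %in% wall))
  expect_error(valve_constraints(build_fixture_mesh("CHANNEL", c(4, 2), 1),
                                 vs, "OPEN"), "valve")
})

test_that("aortic pressure stays in the physiological envelope", {
  h <- rf_baseline()$history
  s <- h$series[h$series$cycle == 3, ]
  ## systolic peak and diastolic trough of the Windkessel pressure (Pa):
  ## the 0.121 / 9.37 parameters with a 73.5 mL stroke should give an
  ## arterial-like 60-130 mmHg envelope
  expect_gt(max(s$P_wk), 90 * 133.322 / 10)   # > ~90 mmHg peak (in Pa)
  expect_lt(max(s$P_wk), 180 * 133.322)
  expect_gt(min(s$P_wk), 40 * 133.322)
})

test_that("step_flow advances a single consistent step", {
  m <- build_root_mesh(root_parameters(), 3, "2d")
  wf <- make_waveform()
  bcs <- cardiac_bc_suite(wf, valve_spec(23))
  cfg <- solver_config(dt = 2e-3, nonlinear_tolerance = 1e-3,
                       max_nonlinear_iters = 6)
  st0 <- flow_state(matrix(0, nrow(m$vertices), 2),
                    numeric(nrow(m$vertices)), 0)
  out <- step_flow(st0, m, bcs, fluid_properties(), cfg)
  expect_s3_class(out$state, "flow_state")
  expect_equal(out$state$time, cfg$dt)
  expect_true(all(is.finite(out$state$velocity)))
  ## wall velocities are Dirichlet-exact zeros
  wall <- boundary_nodes(m, "WALL")
  expect_equal(max(abs(out$state$velocity[wall, ])), 0)
  ## the Windkessel state advanced with the step
  expect_equal(out$bcs$wk_state$time, cfg$dt)
})
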