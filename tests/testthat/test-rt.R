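test_that("the source-only update adds dt exactly away from the Dirichlet set", {
  m <- build_fixture_mesh("CHANNEL", c(6, 2), 0.5)
  n <- nrow(m$vertices)
  phi <- rep(0.3, n)
  vel <- matrix(0, n, 2)
  dt <- 0.05
  out <- step_rt(phi, vel, dt, m)
  dir <- sort(unique(c(boundary_nodes(m, "INLET"), boundary_nodes(m, "OUTLET"))))
  free <- setdiff(seq_len(n), dir)
  expect_equal(out[free], phi[free] + dt, tolerance = 1e-12)
  expect_equal(out[dir], rep(0, length(dir)))
})

test_that("a closed cavity accumulates relative residence time 1 everywhere", {
  m <- build_fixture_mesh("CAVITY", c(5, 5), 1)
  n <- nrow(m$vertices)
  hist <- steady_flow_history(matrix(0, n, 2))
  rt <- run_rt(hist, m, rt_config(rt_cycles = 14))
  expect_equal(max(abs(rt$field$relative_rt - 1)), 0, tolerance = 1e-9)
  expect_equal(rt$field$clipped_fraction, 0)
  st <- rt_stats(rt, m)
  expect_equal(st$rt_mean, 1, tolerance = 1e-9)
  expect_equal(st$rt_max, 1, tolerance = 1e-9)
  expect_equal(st$pct_vol_rt_gt_02, 100)
})

test_that("steady plug flow reproduces the characteristics solution x/U", {
  fx <- rf_plug_rt()
  m <- fx$mesh; U <- fx$U
  phi <- fx$rt$field$phi
  x <- axial_coord(m)
  ## away from the outflow boundary, phi(x) = x / U within 5%
  sel <- x > 0.5 & x < 8.5
  err <- abs(phi[sel] - x[sel] / U) / (x[sel] / U)
  expect_lt(max(err), 0.05)
  ## inflow/outflow Dirichlet faces stay at zero through the whole run
  dir <- c(boundary_nodes(m, "INLET"), boundary_nodes(m, "OUTLET"))
  expect_equal(max(abs(phi[dir])), 0)
})

test_that("strong through-flow keeps the relative residence time small", {
  fx <- rf_plug_rt()
  st <- rt_stats(fx$rt, fx$mesh)
  ## washout time L/U = 0.25 s vs 12 s total: mean relative RT far below 0.2
  expect_lt(st$rt_mean, 0.05)
})

test_that("increasing through-flow does not increase the steady mean RT", {
  m <- build_fixture_mesh("PIPE", c(1.5, 8), 0.8)
  n <- nrow(m$vertices)
  means <- vapply(c(20, 40, 80), function(U) {
    vel <- matrix(0, n, 3); vel[, 3] <- U
    rt <- run_rt(steady_flow_history(vel), m, rt_config(rt_cycles = 6))
    rt_stats(rt, m)$rt_mean
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("the mean-RT convergence flag trips well before 14 cycles", {
  fx <- rf_plug_rt()
  expect_true(fx$rt$converged)
  expect_lte(fx$rt$converged_at_cycle, 8)
})

test_that("relative residence time is bounded in [0, 1] with clipping logged", {
  res <- rf_tavr()
  rel <- res$rt$field$relative_rt
  expect_true(all(rel >= 0 & rel <= 1))
  expect_true(is.finite(res$rt$field$clipped_fraction))
})

test_that("a non-periodic velocity record is rejected", {
  m <- build_fixture_mesh("CHANNEL", c(6, 2), 0.5)
  n <- nrow(m$vertices)
  v1 <- matrix(0, n, 2); v1[, 2] <- 10
  v2 <- matrix(0, n, 2); v2[, 2] <- 40
  hist <- structure(list(snapshots = list(v1, v2),
                         snapshot_times = c(0, 0.857),
                         period = 0.857, dt = 0.01),
                    class = "flow_history")
  expect_error(run_rt(hist, m), "not periodic")
})

test_that("large advective CFL triggers the step-size warning", {
  m <- build_fixture_mesh("CHANNEL", c(6, 2), 0.5)
  n <- nrow(m$vertices)
  vel <- matrix(0, n, 2); vel[, 2] <- 5000
  expect_warning(step_rt(numeric(n), vel, 0.05, m), "CFL")
})
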