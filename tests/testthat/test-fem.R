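test_that("zero forcing yields the exact rest state", {
  m <- build_fixture_mesh("CHANNEL", c(6, 2), 0.5)
  fs <- steady_flow(m, 0)
  expect_equal(max(abs(fs$velocity)), 0, tolerance = 1e-12)
})

test_that("plane Poiseuille flow matches the parabolic closed form", {
  m <- build_fixture_mesh("CHANNEL", c(10, 2), 0.2)
  W <- 2; q <- 50; mu <- fluid_properties()$viscosity
  fs <- steady_flow(m, q)
  Ubar <- q / W
  ## pressure drop between interior planes: dp = 12 mu Ubar L / W^2
  dp <- section_average(m, 2, fs$pressure) - section_average(m, 8, fs$pressure)
  dp_exact <- 12 * mu * Ubar * 6 / W^2
  expect_lt(abs(dp - dp_exact) / dp_exact, 0.1)
  ## mid-channel velocity: 1.5 x mean within 5%
  mid <- which(abs(m$vertices[, 1]) < 1e-9 & abs(m$vertices[, 2] - 5) < 1e-6)
  expect_lt(abs(fs$velocity[mid, 2] - 1.5 * Ubar) / (1.5 * Ubar), 0.05)
  ## no-slip is Dirichlet-exact on walls
  wall <- boundary_nodes(m, "WALL")
  expect_equal(max(abs(fs$velocity[wall, ])), 0, tolerance = 1e-12)
  ## discrete global mass closure
  expect_lt(abs(boundary_flux(m, fs$velocity, "OUTLET") - q) / q, 1e-8)
})

test_that("an impulsively started channel approaches the steady profile", {
  m <- build_fixture_mesh("CHANNEL", c(8, 2), 0.5)
  setup <- rootflow:::fem_setup(m)
  ctx <- rootflow:::bc_context(setup)
  props <- fluid_properties()
  cfg <- solver_config(dt = 5e-3, nonlinear_tolerance = 1e-6,
                       max_nonlinear_iters = 8)
  q <- 50; W <- 2; Ubar <- q / W
  d <- 2; nn <- nrow(m$vertices)
  scale <- q / ctx$F_in_raw
  dir_idx <- rootflow:::vel_dofs(setup$wall_nodes, nn, d)
  dir_val <- numeric(length(dir_idx))
  for (k in 1:2) {
    dir_idx <- c(dir_idx, (k - 1L) * nn + setup$inlet_nodes)
    dir_val <- c(dir_val, scale * ctx$inlet_profile * m$axis[k])
  }
  bc_fun <- function(a) list(dirichlet_idx = dir_idx, dirichlet_val = dir_val,
                             tractions = list(OUTLET = 0),
                             backflow_tags = character(0))
  u <- matrix(0, nn, d)
  mids <- numeric(40)
  mid <- which(abs(m$vertices[, 1]) < 1e-9 & abs(m$vertices[, 2] - 4) < 1e-6)
  for (s in seq_len(40)) {
    res <- rootflow:::ns_solve_step(setup, u, u, cfg$dt, props, cfg, bc_fun)
    u <- res$u
    mids[s] <- u[mid, 2]
  }
  ## viscous time scale rho W^2 / mu ~ 1 s; after 0.2 s the centreline is
  ## within 5% of the analytic 1.5 Ubar and still rising monotonically
  expect_lt(abs(mids[40] - 1.5 * Ubar) / (1.5 * Ubar), 0.05)
  expect_true(all(diff(mids[1:20]) > 0))
})

test_that("Poiseuille pressure drop error shrinks under refinement", {
  errs <- vapply(c(1.0, 0.7, 0.5), function(h) abs(rf_pipe_dp(h)$rel_err),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.10)
})

test_that("orifice narrowing raises peak velocity and gradient monotonically", {
  ## same geometry and BCs, GOA 17 vs 14 mm: steady systolic-peak inflow
  p <- root_parameters()
  wfpeak <- pi / 2 * 73500 / (0.35 * 60 / 70)
  cfg <- solver_config(nonlinear_tolerance = 1e-5, max_nonlinear_iters = 15)
  out <- lapply(c(17, 14), function(goa) {
    m <- build_root_mesh(p, 2, "2d", valve = valve_spec(goa + 6))
    setup <- rootflow:::fem_setup(m)
    ctx <- rootflow:::bc_context(setup)
    q <- wfpeak / ctx$f_conv
    vc <- valve_constraints(m, m$valve$spec, "OPEN")
    nn <- nrow(m$vertices)
    dir_idx <- rootflow:::vel_dofs(setup$wall_nodes, nn, 2)
    dir_idx <- c(dir_idx, rootflow:::vel_dofs(vc$nodes, nn, 2))
    dir_val <- numeric(length(dir_idx))
    scale <- q / ctx$F_in_raw
    for (k in 1:2) {
      dir_idx <- c(dir_idx, (k - 1L) * nn + setup$inlet_nodes)
      dir_val <- c(dir_val, scale * ctx$inlet_profile * m$axis[k])
    }
    bc_fun <- function(a) list(dirichlet_idx = dir_idx,
                               dirichlet_val = dir_val,
                               tractions = list(OUTLET = 0),
                               backflow_tags = "OUTLET")
    res <- rootflow:::ns_solve_step(setup, NULL, matrix(0, nn, 2), Inf,
                                    fluid_properties(), cfg, bc_fun)
    sax <- axial_coord(m)
    down <- sax > m$valve$station & sax <= m$valve$station + 30
    list(peak = max(sqrt(rowSums(res$u^2))[down]),
         dp = section_average(m, 0, res$p) -
           section_average(m, m$valve$station + 30, res$p))
  })
  expect_gt(out[[2]]$peak, out[[1]]$peak)
  expect_gt(out[[2]]$dp, out[[1]]$dp)
})
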