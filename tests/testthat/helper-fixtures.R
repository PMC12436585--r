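## Shared fixtures. Scenario runs are expensive, so they are computed once
## per test session and cached for every file that needs them.

.rf_cache <- new.env(parent = emptyenv())

rf_cached <- function(key, expr) {
  if (!exists(key, envir = .rf_cache)) {
    assign(key, force(expr), envir = .rf_cache)
  }
  get(key, envir = .rf_cache)
}

## The three study scenarios at the CI (2-D planar, coarse) fidelity.
rf_scenario <- function(scenario, label = tolower(scenario),
                        with_rt = FALSE) {
  key <- paste0("scenario_", label, if (with_rt) "_rt" else "")
  rf_cached(key, {
    cfg <- scenario_config(scenario, profile = "ci", label = label, seed = 1L)
    base_key <- paste0("scenario_", label)
    prior <- if (exists(base_key, envir = .rf_cache))
      get(base_key, envir = .rf_cache) else NULL
    run_scenario(cfg, run_rt_stage = with_rt,
                 flow_history = if (!is.null(prior)) prior$history else NULL)
  })
}

rf_baseline <- function() rf_scenario("BASELINE", "baseline", with_rt = TRUE)
rf_yaae <- function() rf_scenario("YAAE", "yaae", with_rt = FALSE)
rf_tavr <- function() rf_scenario("TAVR_IN_SAVR", "tavr", with_rt = TRUE)

## Steady Hagen-Poiseuille pipe solutions over a refinement ladder.
rf_pipe_dp <- function(h, radius = 2, length = 12, Q = 200) {
  key <- sprintf("pipe_%g", h)
  rf_cached(key, {
    mesh <- build_fixture_mesh("PIPE", c(radius, length), h)
    fs <- steady_flow(mesh, Q,
                      config = solver_config(nonlinear_tolerance = 1e-7,
                                             max_nonlinear_iters = 15))
    mu <- fluid_properties()$viscosity
    L <- 8                     # planes at 2 and 10 mm
    dp_num <- section_average(mesh, 2, fs$pressure) -
      section_average(mesh, 10, fs$pressure)
    dp_exact <- 8 * mu * L * Q / (pi * radius^4)
    list(mesh = mesh, state = fs, dp_num = dp_num, dp_exact = dp_exact,
         rel_err = (dp_num - dp_exact) / dp_exact)
  })
}

## Plug-flow channel residence-time run.
rf_plug_rt <- function() {
  rf_cached("plug_rt", {
    mesh <- build_fixture_mesh("CHANNEL", c(10, 2), 0.4)
    U <- 40
    vel <- matrix(0, nrow(mesh$vertices), 2)
    vel[, 2] <- U
    hist <- steady_flow_history(vel)
    rt <- run_rt(hist, mesh, rt_config(rt_cycles = 14))
    list(mesh = mesh, U = U, rt = rt)
  })
}
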