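## Config-driven orchestration: geometry -> flow -> residence time ->
## metrics -> comparison, with provenance, JSONL logging and deterministic
## reruns.

## Fidelity profiles: problem-size presets. "ci" runs the planar 2-D root at
## coarse resolution, "desk" a coarse 3-D root, "paper" the full-resolution
## settings (1 mm edges, dt = 0.0008 s) that reproduce the reference
## operating point and are intended for workstation runs.
profile_defaults <- function(profile = c("ci", "desk", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
    ci = list(mode = "2d", edge_length = 2,
              solver = list(dt = 2e-3, cycles = 3, nonlinear_tolerance = 1e-3,
                            max_nonlinear_iters = 6, snapshot_stride = 4),
              rt = list(rt_cycles = 14, dt_factor = 4)),
    desk = list(mode = "3d", edge_length = 2.5,
                solver = list(dt = 2e-3, cycles = 3,
                              nonlinear_tolerance = 1e-3,
                              max_nonlinear_iters = 8, snapshot_stride = 4),
                rt = list(rt_cycles = 14, dt_factor = 4)),
    paper = list(mode = "3d", edge_length = 1,
                 solver = list(dt = 8e-4, cycles = 3,
                               nonlinear_tolerance = 1e-6,
                               max_nonlinear_iters = 10, snapshot_stride = 5),
                 rt = list(rt_cycles = 14, dt_factor = 4)))
}

#' Build a validated scenario configuration
#'
#' Merges a fidelity profile with explicit overrides and validates every
#' component by constructing it (fail-fast: an inconsistent configuration
#' errors before any compute starts).
#'
#' @param scenario `"BASELINE"`, `"YAAE"` or `"TAVR_IN_SAVR"`.
#' @param profile fidelity profile: `"ci"`, `"desk"` or `"paper"`.
#' @param geometry named list of [root_parameters()] overrides.
#' @param valve named list of [valve_spec()] arguments; default implanted
#'   size is the native annulus diameter for BASELINE/TAVR_IN_SAVR and 29 mm
#'   for YAAE.
#' @param waveform named list of [make_waveform()] overrides.
#' @param windkessel named list of [wk2_params()] overrides.
#' @param solver named list of [solver_config()] overrides.
#' @param rt named list of [rt_config()] overrides.
#' @param goa_area_reduction valve-in-valve GOA area reduction fraction.
#' @param mode mesh mode override (`"2d"`/`"3d"`).
#' @param edge_length mesh edge length override, mm.
#' @param label scenario label; defaults to the scenario name.
#' @param seed integer seed recorded in all provenance metadata.
#' @param outdir output directory for artifacts, or `NULL` for none.
#' @return list of class `scenario_config` with all resolved components.
#' @export
scenario_config <- function(scenario = "BASELINE", profile = "ci",
                            geometry = list(), valve = list(),
                            waveform = list(), windkessel = list(),
                            solver = list(), rt = list(),
                            goa_area_reduction = 0.20,
                            mode = NULL, edge_length = NULL,
                            label = NULL, seed = 1L, outdir = NULL) {
  scenario <- match.arg(scenario, c("BASELINE", "YAAE", "TAVR_IN_SAVR"))
  prof <- profile_defaults(profile)
  mode <- if (is.null(mode)) prof$mode else mode
  edge_length <- if (is.null(edge_length)) prof$edge_length else edge_length
  params <- do.call(root_parameters, geometry)
  if (is.null(valve$implanted_internal_diameter))
    valve$implanted_internal_diameter <-
      if (scenario == "YAAE") 29 else params$annulus_diameter
  vs <- do.call(valve_spec, valve)
  params <- apply_scenario(params, scenario, vs,
                           goa_area_reduction = goa_area_reduction)
  wf <- do.call(make_waveform, waveform)
  wk <- do.call(wk2_params, windkessel)
  sc <- do.call(solver_config, utils::modifyList(prof$solver, solver))
  rc <- do.call(rt_config, utils::modifyList(prof$rt, rt))
  cfg <- structure(list(scenario = scenario, profile = profile,
                        label = if (is.null(label)) scenario else label,
                        params = params, valve = vs, waveform = wf,
                        windkessel = wk, solver = sc, rt = rc,
                        goa_area_reduction = goa_area_reduction,
                        mode = mode, edge_length = edge_length,
                        seed = as.integer(seed), outdir = outdir),
                   class = "scenario_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Load a scenario configuration from YAML
#'
#' The YAML file holds the same named blocks as [scenario_config()]'s
#' arguments (`scenario`, `profile`, `geometry`, `valve`, `waveform`,
#' `windkessel`, `solver`, `rt`, `mode`, `edge_length`, `label`, `seed`).
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file contents.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) y[[nm]] <- over[[nm]]
  do.call(scenario_config, y)
}

## FNV-1a over the canonical JSON of the configuration (provenance hash).
config_hash <- function(cfg) {
  drop <- c("hash", "outdir")
  x <- cfg[setdiff(names(cfg), drop)]
  ## functions inside waveform are not serializable; hash their parameters
  x$waveform <- x$waveform[c("heart_rate", "stroke_volume",
                             "systolic_fraction", "shape",
                             "coronary_fraction")]
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  ## polynomial rolling hash modulo a Mersenne prime (exact in doubles)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run one scenario end to end
#'
#' Executes the full pipeline: build the scenario geometry, run the flow
#' cycles, replay the final cycle through the residence-time solver, and
#' compute the metrics report. With `outdir` set, writes the mesh (MSH +
#' VTU), the final velocity/pressure/relative-RT fields (VTU), the per-step
#' series and per-cycle summaries (CSV), the metrics (JSON), the resolved
#' configuration (YAML) and a JSONL stage log. Reruns with an identical
#' configuration and seed are deterministic.
#'
#' @param config a [scenario_config()].
#' @param run_rt_stage logical; skip the residence-time stage when `FALSE`.
#' @param flow_history optional precomputed [run_cycles()] result, allowing
#'   the residence-time stage to be rerun without recomputing the flow.
#' @return list of class `scenario_result` with `report`, `history`, `rt`,
#'   `mesh` and `config`.
#' @export
run_scenario <- function(config, run_rt_stage = TRUE, flow_history = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  stage <- function(name, expr) {
    s0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log[[length(log) + 1L]] <<- list(stage = name,
                                     seconds = proc.time()[["elapsed"]] - s0)
    out
  }
  set.seed(config$seed)
  mesh <- stage("mesh", build_root_mesh(config$params, config$edge_length,
                                        mode = config$mode,
                                        valve = config$valve,
                                        seed = config$seed))
  history <- if (is.null(flow_history)) {
    stage("flow", run_cycles(mesh, config$waveform, config$valve,
                             props = fluid_properties(),
                             config = config$solver,
                             wk_params = config$windkessel))
  } else flow_history
  rt <- if (run_rt_stage)
    stage("rt", run_rt(history, mesh, config$rt)) else NULL
  report <- stage("metrics",
                  metrics_report(history, rt, mesh, config$valve,
                                 scenario = config$label,
                                 config_hash = config$hash))
  if (!is.null(config$outdir)) {
    stage("artifacts", write_scenario_artifacts(config, mesh, history, rt,
                                                report, log))
  }
  structure(list(report = report, history = history, rt = rt, mesh = mesh,
                 config = config,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "scenario_result")
}

write_scenario_artifacts <- function(config, mesh, history, rt, report, log) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$outdir, f)
  write_mesh(mesh, pth("mesh.msh"))
  fields <- list(velocity = history$u_last, pressure = history$p_last)
  if (!is.null(rt)) {
    fields$phi <- rt$field$phi
    fields$relative_rt <- rt$field$relative_rt
  }
  write_vtu(mesh, pth("fields.vtu"), point_data = fields)
  utils::write.csv(history$series, pth("series.csv"), row.names = FALSE)
  utils::write.csv(history$cycle_summary, pth("cycle_summary.csv"),
                   row.names = FALSE)
  if (!is.null(rt))
    utils::write.csv(data.frame(cycle = seq_along(rt$mean_rt_trace),
                                mean_rt = rt$mean_rt_trace),
                     pth("rt_trace.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report), pth("metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(as.data.frame(unclass(report)[!vapply(report, is.null,
                                                         logical(1))]),
                   pth("metrics.csv"), row.names = FALSE)
  resolved <- list(scenario = config$scenario, profile = config$profile,
                   label = config$label, mode = config$mode,
                   edge_length = config$edge_length, seed = config$seed,
                   hash = config$hash,
                   goa_area_reduction = config$goa_area_reduction)
  yaml::write_yaml(resolved, pth("resolved_config.yaml"))
  writeLines(vapply(log, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE)), character(1)),
    pth("log.jsonl"))
  invisible(config$outdir)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (profile %s, %s, h = %g mm), %.1f s\n",
              x$config$label, x$config$profile, x$config$mode,
              x$config$edge_length, x$elapsed))
  print(x$report)
  invisible(x)
}

#' Run and compare a set of scenarios
#'
#' @param configs list of [scenario_config()] objects.
#' @param control label of the control scenario for percent changes.
#' @param ... passed to [run_scenario()].
#' @return list with `results` (scenario results) and `comparison`
#'   (a [compare_scenarios()] report).
#' @export
run_comparison <- function(configs, control, ...) {
  results <- lapply(configs, run_scenario, ...)
  reports <- lapply(results, function(r) r$report)
  list(results = results,
       comparison = compare_scenarios(reports, control))
}
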