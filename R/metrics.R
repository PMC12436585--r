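## Quantitative hemodynamic metrics: peak transvalvular velocity, mean
## transvalvular pressure gradient (TPG), residence-time statistics, and the
## reporting conventions used for multi-scenario comparison.

PA_PER_MMHG <- 133.322

#' Peak velocity downstream of the valve
#'
#' Maximum velocity magnitude over the cardiac cycle in the region downstream
#' of the valve plane, capped at the plane 30 mm further downstream (the jet
#' region interrogated by echo-style measurements). The region is selected
#' along the stored mesh axis, so the metric is invariant under rigid
#' rotation of mesh and field together.
#'
#' @param history a [run_cycles()] result (final-cycle series).
#' @param mesh the mesh the history was computed on.
#' @param valve the [valve_spec()] used (interface completeness; the valve
#'   plane location is taken from the mesh).
#' @param region `"capped"` (default: up to 30 mm downstream) or `"all"`
#'   (every node beyond the valve plane).
#' @return peak velocity, mm/s.
#' @export
peak_velocity <- function(history, mesh, valve = NULL,
                          region = c("capped", "all")) {
  region <- match.arg(region)
  if (region == "capped") {
    s <- history$series
    last <- s[s$cycle == max(s$cycle), , drop = FALSE]
    return(max(last$vmax_down))
  }
  ## "all": recompute from the stored snapshots over the whole downstream lumen
  sax <- axial_coord(mesh)
  down <- which(sax > history$valve_station + 1e-9)
  if (!length(down)) stop("peak_velocity: empty downstream region")
  max(vapply(history$snapshots, function(u)
    max(sqrt(rowSums(u[down, , drop = FALSE]^2))), numeric(1)))
}

#' Mean transvalvular pressure gradient
#'
#' Time average, over the forward-flow window of the final cycle
#' (transvalvular flux > 0, i.e. valve open), of the positive part of the
#' difference between the area-averaged pressure on the inlet plane and on
#' the plane 30 mm downstream of the valve. Being a difference of plane
#' averages it is invariant to any constant pressure offset.
#'
#' @param history a [run_cycles()] result.
#' @param mesh the mesh the history was computed on.
#' @param valve the [valve_spec()] used (interface completeness).
#' @param in_mmHg report in mmHg instead of Pa (1 mmHg = 133.322 Pa).
#' @return mean TPG in Pa (or mmHg).
#' @export
mean_tpg <- function(history, mesh, valve = NULL, in_mmHg = FALSE) {
  s <- history$series
  last <- s[s$cycle == max(s$cycle), , drop = FALSE]
  fwd <- last$Q_valve > 0
  val <- if (any(fwd)) mean(pmax(last$p_in[fwd] - last$p_30[fwd], 0)) else 0
  if (in_mmHg) val / PA_PER_MMHG else val
}

#' Residence-time statistics
#'
#' Volume-weighted mean, pointwise maximum, and the percentage of the lumen
#' volume whose relative residence time exceeds 0.2.
#'
#' @param rt an [rt_field()] (or the result list from [run_rt()]).
#' @param mesh the [tagged_mesh] the field lives on.
#' @param threshold relative-RT threshold for the volume fraction (default
#'   0.2).
#' @return list with `rt_mean`, `rt_max`, `pct_vol_rt_gt_02`.
#' @export
rt_stats <- function(rt, mesh, threshold = 0.2) {
  if (!inherits(rt, "rt_field") && !is.null(rt$field)) rt <- rt$field
  stopifnot(inherits(rt, "rt_field"))
  rel <- rt$relative_rt
  meas <- cell_measures(mesh)
  cells <- mesh$cells
  nd <- ncol(cells)
  ## lumped nodal volumes: each cell contributes V/(d+1) to its vertices
  w <- acc_vec(as.vector(cells), rep(meas / nd, nd), nrow(mesh$vertices))
  vol <- sum(w)
  rt_mean <- sum(w * rel) / vol
  pct <- 100 * sum(w * (rel > threshold)) / vol
  list(rt_mean = rt_mean, rt_max = max(rel), pct_vol_rt_gt_02 = pct)
}

#' Percent change of a treatment value against a control
#'
#' Reported with the clinical "decrease" convention:
#' `100 (control - treatment) / control`, so a positive value is a reduction
#' relative to control and a negative value an increase.
#'
#' @param treatment treatment value.
#' @param control control (reference) value; must be nonzero.
#' @return percent change (positive = decrease).
#' @export
percent_change <- function(treatment, control) {
  if (any(control == 0)) stop("percent_change: control must be nonzero")
  100 * (control - treatment) / control
}

#' Normalize values by the group maximum
#'
#' @param values numeric vector; the maximum must be positive.
#' @return `values / max(values)`; the maximal element maps to exactly 1.
#' @export
group_normalize <- function(values) {
  if (!length(values)) stop("group_normalize: empty group")
  m <- max(values)
  if (m <= 0) stop("group_normalize: group maximum must be positive")
  values / m
}

#' Assemble a metrics report for one scenario
#'
#' @param history a [run_cycles()] result.
#' @param rt a [run_rt()] result (or `NULL` to skip RT metrics).
#' @param mesh the scenario mesh.
#' @param valve the [valve_spec()] used.
#' @param scenario scenario label.
#' @param config_hash provenance hash of the resolved configuration.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(history, rt, mesh, valve, scenario = "scenario",
                           config_hash = NA_character_) {
  pv <- peak_velocity(history, mesh, valve)
  tpg <- mean_tpg(history, mesh, valve)
  out <- list(scenario = scenario,
              peak_velocity = pv,
              mean_tpg = tpg,
              mean_tpg_mmHg = tpg / PA_PER_MMHG,
              rt_mean = NA_real_, rt_max = NA_real_,
              pct_vol_rt_gt_02 = NA_real_,
              flow_converged = history$converged,
              rt_converged = NA,
              config_hash = config_hash)
  if (!is.null(rt)) {
    st <- rt_stats(rt, mesh)
    out$rt_mean <- st$rt_mean; out$rt_max <- st$rt_max
    out$pct_vol_rt_gt_02 <- st$pct_vol_rt_gt_02
    out$rt_converged <- rt$converged
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n", x$scenario))
  cat(sprintf("  peak velocity: %.1f mm/s\n", x$peak_velocity))
  cat(sprintf("  mean TPG:      %.1f Pa (%.2f mmHg)\n",
              x$mean_tpg, x$mean_tpg_mmHg))
  if (!is.na(x$rt_mean))
    cat(sprintf("  relative RT:   mean %.3f, max %.3f, %%vol > 0.2: %.2f%%\n",
                x$rt_mean, x$rt_max, x$pct_vol_rt_gt_02))
  cat(sprintf("  flow converged: %s; RT converged: %s\n",
              x$flow_converged, x$rt_converged))
  invisible(x)
}

#' Compare scenario metrics against a control
#'
#' Builds the raw, group-normalized and percent-change tables for a set of
#' scenario reports, mirroring bar-chart style comparisons (each metric
#' normalized by its group maximum; percent change positive = decrease vs.
#' the control scenario).
#'
#' @param reports list of [metrics_report()] objects.
#' @param control label of the control scenario.
#' @return list of class `comparison_report` with `raw`, `normalized` and
#'   `percent_change` data frames and `unconverged` labels (if any).
#' @export
compare_scenarios <- function(reports, control) {
  if (length(reports) < 2) stop("compare_scenarios: need at least two reports")
  labs <- vapply(reports, function(r) r$scenario, character(1))
  if (!control %in% labs) stop("compare_scenarios: control scenario not found")
  metrics <- c("peak_velocity", "mean_tpg", "rt_mean", "rt_max",
               "pct_vol_rt_gt_02")
  raw <- data.frame(scenario = labs)
  for (m in metrics)
    raw[[m]] <- vapply(reports, function(r) as.numeric(r[[m]]), numeric(1))
  norm <- raw; pct <- raw
  ctrl <- raw[labs == control, , drop = FALSE]
  for (m in metrics) {
    v <- raw[[m]]
    norm[[m]] <- if (all(is.na(v)) || max(v, na.rm = TRUE) <= 0) v
    else v / max(v, na.rm = TRUE)
    pct[[m]] <- if (is.na(ctrl[[m]]) || ctrl[[m]] == 0) NA_real_
    else percent_change(v, ctrl[[m]])
  }
  unconv <- labs[!vapply(reports, function(r)
    isTRUE(r$flow_converged), logical(1))]
  structure(list(raw = raw, normalized = norm, percent_change = pct,
                 control = control, unconverged = unconv),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> control: %s\n", x$control))
  cat("raw:\n"); print(x$raw)
  cat("percent change vs control (positive = decrease):\n")
  print(x$percent_change)
  if (length(x$unconverged))
    cat("flagged (flow not converged):", paste(x$unconverged, collapse = ", "), "\n")
  invisible(x)
}
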