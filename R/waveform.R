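#' Cardiac cycle waveform
#'
#' Builds the periodic boundary-condition schedule used by the flow solver:
#' a systolic inlet flux whose integral over systole equals the stroke
#' volume, a diastolic inlet pressure trace, and a diastolic coronary flux.
#' Units are mm-g-s: fluxes in mm^3/s, pressures in Pa.
#'
#' Two systolic flux shapes are provided. `HALF_SINE` (default) is
#' `Q(t) = (pi/2) (SV / T_sys) sin(pi t / T_sys)`; `TRAPEZOID` ramps over the
#' first and last fifth of systole with a flat plateau between. The shape is
#' an idealization: only heart rate, stroke volume and the systole/diastole
#' split are physiological inputs.
#'
#' @param heart_rate beats per minute.
#' @param stroke_volume mm^3 ejected per beat (73.5 mL = 73500 mm^3).
#' @param systolic_fraction fraction of the cycle spent in systole, in
#'   (0.2, 0.5).
#' @param shape `"HALF_SINE"` or `"TRAPEZOID"`.
#' @param diastolic_pressure mean diastolic inlet (LV filling) pressure, Pa.
#' @param diastolic_pressure_ramp peak-to-trough amplitude of a linear ramp
#'   added to the diastolic trace, Pa (0 = constant).
#' @param coronary_fraction fraction of mean cardiac output drawn by the two
#'   coronary ostia together; the flux is constant over diastole and zero in
#'   systole, so the per-cycle coronary volume is
#'   `coronary_fraction * stroke_volume`.
#' @return An object of class `cycle_waveform` with fields `period`,
#'   `t_sys`, and functions `inlet_flux(t)`, `diastolic_inlet_pressure(t)`,
#'   `coronary_flux(t)` (all periodic).
#' @export
make_waveform <- function(heart_rate = 70, stroke_volume = 73500,
                          systolic_fraction = 0.35,
                          shape = c("HALF_SINE", "TRAPEZOID"),
                          diastolic_pressure = 1067,
                          diastolic_pressure_ramp = 0,
                          coronary_fraction = 0.04) {
  shape <- match.arg(shape)
  if (heart_rate <= 0) stop("make_waveform: heart_rate must be positive")
  if (stroke_volume <= 0) stop("make_waveform: stroke_volume must be positive")
  if (systolic_fraction <= 0.2 || systolic_fraction >= 0.5)
    stop("make_waveform: systolic_fraction must lie in (0.2, 0.5)")
  period <- 60 / heart_rate
  t_sys <- systolic_fraction * period
  inlet_flux <- if (shape == "HALF_SINE") {
    peak <- pi / 2 * stroke_volume / t_sys
    function(t) {
      tm <- t %% period
      ifelse(tm < t_sys, peak * sin(pi * tm / t_sys), 0)
    }
  } else {
    ramp <- 0.2 * t_sys
    plateau <- stroke_volume / (t_sys - ramp)   # trapezoid area = SV
    function(t) {
      tm <- t %% period
      ifelse(tm >= t_sys, 0,
             plateau * pmin(1, pmin(tm / ramp, (t_sys - tm) / ramp)))
    }
  }
  diastolic_inlet_pressure <- function(t) {
    tm <- t %% period
    frac <- pmax(0, (tm - t_sys)) / (period - t_sys)
    diastolic_pressure + diastolic_pressure_ramp * (frac - 0.5)
  }
  q_cor <- coronary_fraction * stroke_volume / (period - t_sys)
  coronary_flux <- function(t) {
    tm <- t %% period
    ifelse(tm >= t_sys, q_cor, 0)
  }
  structure(list(period = period, heart_rate = heart_rate,
                 stroke_volume = stroke_volume,
                 systolic_fraction = systolic_fraction, t_sys = t_sys,
                 shape = shape,
                 inlet_flux = inlet_flux,
                 diastolic_inlet_pressure = diastolic_inlet_pressure,
                 coronary_flux = coronary_flux,
                 coronary_fraction = coronary_fraction),
            class = "cycle_waveform")
}

#' @export
print.cycle_waveform <- function(x, ...) {
  cat(sprintf("<cycle_waveform> %g bpm, SV %g mm^3, systolic fraction %g (%s)\n",
              x$heart_rate, x$stroke_volume, x$systolic_fraction, x$shape))
  invisible(x)
}

#' Geometric orifice diameter from the implanted valve size
#'
#' The internal geometric orifice of a stented surgical bioprosthesis is
#' modeled as a disc whose diameter is 6.0 mm less than the labelled internal
#' diameter of the implanted valve.
#'
#' @param implanted_internal_diameter labelled internal valve diameter, mm.
#' @return GOA diameter, mm.
#' @export
goa_from_valve <- function(implanted_internal_diameter) {
  if (!is.numeric(implanted_internal_diameter) ||
      any(implanted_internal_diameter <= 6.0))
    stop("goa_from_valve: implanted internal diameter must exceed 6.0 mm")
  implanted_internal_diameter - 6.0
}

#' Valve specification
#'
#' @param implanted_internal_diameter labelled internal diameter, mm.
#' @param valve_plane_offset axial offset of the orifice plane from the
#'   annulus, mm.
#' @return An object of class `valve_spec` with the derived `goa_diameter`.
#' @export
valve_spec <- function(implanted_internal_diameter, valve_plane_offset = 0) {
  goa <- goa_from_valve(implanted_internal_diameter)
  structure(list(implanted_internal_diameter = implanted_internal_diameter,
                 goa_diameter = goa,
                 valve_plane_offset = valve_plane_offset),
            class = "valve_spec")
}

#' Valve open/close schedule
#'
#' The orifice plane opens at the start and closes at the end of systole,
#' instantaneously. The open interval is `[0, t_sys)`: at `t = t_sys`
#' exactly the valve is CLOSED (closed-interval convention at the closing
#' boundary, matching the diastolic pressure condition taking over).
#'
#' @param waveform a [make_waveform()] object.
#' @return An object of class `valve_schedule` with `state(t)` returning
#'   `"OPEN"` or `"CLOSED"`.
#' @export
valve_schedule <- function(waveform) {
  period <- waveform$period; t_sys <- waveform$t_sys
  state <- function(t) {
    tm <- t %% period
    ifelse(tm < t_sys, "OPEN", "CLOSED")
  }
  structure(list(open_interval = c(0, t_sys), period = period, state = state),
            class = "valve_schedule")
}

#' Inlet boundary condition at a time
#'
#' During systole (valve OPEN) the inlet carries a prescribed volumetric
#' flux; during diastole (valve CLOSED) a prescribed pressure mimicking LV
#' filling. The returned kind flips exactly at the valve transitions.
#'
#' @param t time, s.
#' @param waveform a [make_waveform()] object.
#' @param schedule a [valve_schedule()] object.
#' @return A list `list(kind = "FLUX", value = mm^3/s)` or
#'   `list(kind = "PRESSURE", value = Pa)`.
#' @export
inlet_condition_at <- function(t, waveform, schedule) {
  if (any(t < 0)) stop("inlet_condition_at: t must be >= 0")
  if (schedule$state(t) == "OPEN") {
    list(kind = "FLUX", value = waveform$inlet_flux(t))
  } else {
    list(kind = "PRESSURE", value = waveform$diastolic_inlet_pressure(t))
  }
}

## ---- two-element Windkessel ---------------------------------------------

#' Two-element Windkessel parameters
#'
#' Lumped resistance-compliance model of the circulation downstream of the
#' ascending aorta, governed by `C dP/dt = Q - P/R`. Defaults are the
#' systemic values used with the mm-g-s unit system: R = 0.121 Pa s/mm^3,
#' C = 9.37 mm^3/Pa.
#'
#' @param R peripheral resistance, Pa s/mm^3.
#' @param C compliance, mm^3/Pa.
#' @return An object of class `wk2_params`.
#' @export
wk2_params <- function(R = 0.121, C = 9.37) {
  if (R <= 0 || C <= 0) stop("wk2_params: R and C must be positive")
  structure(list(R = R, C = C), class = "wk2_params")
}

#' Two-element Windkessel state
#' @param pressure lumped pressure, Pa.
#' @param time current time, s.
#' @return An object of class `wk2_state`.
#' @export
wk2_state <- function(pressure, time = 0) {
  if (!is.finite(pressure)) stop("wk2_state: pressure must be finite")
  structure(list(pressure = pressure, time = time), class = "wk2_state")
}

#' Advance the two-element Windkessel one time step
#'
#' Exponential integrator for `C dP/dt = Q - P/R` holding the inflow `Q`
#' constant over the step:
#' `P(t+dt) = Q R + (P(t) - Q R) exp(-dt / (R C))`.
#' This is the exact solution for constant `Q`, hence unconditionally stable,
#' and first-order accurate overall when `Q` varies between steps.
#'
#' @param state a [wk2_state()].
#' @param Q inflow over the step, mm^3/s.
#' @param dt time step, s.
#' @param params a [wk2_params()].
#' @return The advanced `wk2_state`.
#' @export
wk2_advance <- function(state, Q, dt, params) {
  stopifnot(inherits(state, "wk2_state"), inherits(params, "wk2_params"))
  if (dt <= 0) stop("wk2_advance: dt must be positive")
  pinf <- Q * params$R
  p <- pinf + (state$pressure - pinf) * exp(-dt / (params$R * params$C))
  wk2_state(p, state$time + dt)
}

#' Export waveform traces to a data frame / CSV
#'
#' Samples the cycle waveform, valve state and (optionally) a Windkessel
#' pressure trace over one period.
#'
#' @param waveform a [make_waveform()] object.
#' @param n number of samples over one period.
#' @param file optional CSV path; when given the table is also written.
#' @return A data frame with columns `t`, `Q_in`, `P_inlet`, `Q_cor`,
#'   `valve`.
#' @export
waveform_table <- function(waveform, n = 200, file = NULL) {
  t <- seq(0, waveform$period, length.out = n + 1L)[-(n + 1L)]
  sched <- valve_schedule(waveform)
  df <- data.frame(t = t,
                   Q_in = waveform$inlet_flux(t),
                   P_inlet = waveform$diastolic_inlet_pressure(t),
                   Q_cor = waveform$coronary_flux(t),
                   valve = sched$state(t))
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
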