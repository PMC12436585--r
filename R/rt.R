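## Blood residence time: the source-driven advection(-diffusion) scalar
##   d(phi)/dt + v . grad(phi) - div(D grad(phi)) = 1
## with phi = 0 on the inflow and outflow faces. phi measures the time fluid
## at a point has spent inside the domain; scaled by the total simulated time
## T it gives the relative residence-time field in [0, 1], a stasis and
## thrombosis surrogate.

#' Residence-time solver configuration
#'
#' @param diffusivity scalar diffusivity D, mm^2/s (0 for the pure-advection
#'   residence-time model).
#' @param rt_cycles number of cardiac cycles to integrate (>= 2).
#' @param convergence_threshold relative cycle-to-cycle change in the mean
#'   residence time below which the run is declared converged.
#' @param dt_factor residence-time step as a multiple of the stored flow step
#'   (velocity snapshots are interpolated linearly in time).
#' @param dirichlet_coronary also hold phi = 0 at the coronary ostia
#'   (default `FALSE`: ostia take the natural zero-flux condition).
#' @param cfl_warn warn when the advective CFL number exceeds this value.
#' @return An object of class `rt_config`.
#' @export
rt_config <- function(diffusivity = 0, rt_cycles = 14L,
                      convergence_threshold = 0.05, dt_factor = 4,
                      dirichlet_coronary = FALSE, cfl_warn = 20) {
  if (diffusivity < 0) stop("rt_config: diffusivity must be >= 0")
  if (rt_cycles < 2) stop("rt_config: rt_cycles must be >= 2")
  structure(list(diffusivity = diffusivity, rt_cycles = as.integer(rt_cycles),
                 convergence_threshold = convergence_threshold,
                 dt_factor = dt_factor,
                 dirichlet_coronary = dirichlet_coronary,
                 cfl_warn = cfl_warn), class = "rt_config")
}

## Dirichlet node set for the residence-time problem.
rt_dirichlet_nodes <- function(setup, config) {
  nodes <- c(setup$inlet_nodes, setup$outlet_nodes)
  if (isTRUE(config$dirichlet_coronary))
    nodes <- c(nodes, boundary_nodes(setup$mesh, c("CORONARY_L", "CORONARY_R")))
  sort(unique(nodes))
}

#' One residence-time transport step
#'
#' Implicit-Euler step of the streamline-upwind (SUPG) stabilized advection(
#' -diffusion) equation with unit source. With zero velocity and zero
#' diffusivity the consistent-mass update is exact: phi grows by `dt`
#' everywhere away from the Dirichlet boundary.
#'
#' @param phi nodal field at time t, s.
#' @param velocity nodal velocity matrix (n x d), mm/s.
#' @param dt time step, s.
#' @param mesh a [tagged_mesh].
#' @param config an [rt_config()].
#' @param setup optional cached [fem_setup()].
#' @return The advanced nodal field.
#' @export
step_rt <- function(phi, velocity, dt, mesh, config = rt_config(),
                    setup = NULL) {
  if (is.null(setup)) setup <- fem_setup(mesh)
  sys <- rt_system(setup, velocity, dt, config)
  drop(advance_rt(sys, phi, dt))
}

## Assemble the (matrix, source, mass) triple for a given advective field.
rt_system <- function(setup, velocity, dt, config) {
  d <- setup$d; nd <- setup$nd; ne <- setup$ne; nn <- setup$nn
  cells <- setup$cells; meas <- setup$meas; grad <- setup$grad
  abar <- matrix(0, ne, d)
  for (k in seq_len(d)) abar[, k] <- rowMeans(matrix(velocity[cells, k], ne, nd))
  amag <- sqrt(rowSums(abar^2))
  cfl <- max(amag * dt / setup$h)
  if (cfl > config$cfl_warn)
    warning(sprintf(
      "residence-time CFL %.1f is large; consider dt <= %.2e s", cfl,
      config$cfl_warn * min(setup$h) / max(max(amag), 1e-12)))
  Dd <- config$diffusivity
  tau <- 1 / sqrt((2 / dt)^2 + (2 * amag / setup$h)^2 +
                  (12 * max(Dd, 1e-30) / setup$h^2)^2)
  adg <- matrix(0, ne, nd)
  for (i in seq_len(nd))
    adg[, i] <- rowSums(abar * matrix(grad[, i, ], ne, d))
  P <- nd * nd
  Ax <- matrix(0, ne, P)
  Mxs <- matrix(0, ne, P)       # lumped mass + SUPG time coupling
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    p <- (i - 1L) * nd + j
    Ax[, p] <- meas * adg[, j] / nd +           # advection
      Dd * setup$Kx[, p] +                      # diffusion
      tau * meas * adg[, i] * adg[, j]          # SUPG advection
    ## row-sum (lumped) mass decouples the pure-source update, making
    ## phi -> phi + dt exact at every free node when v = 0, D = 0
    Mxs[, p] <- (i == j) * meas / nd + tau * meas * adg[, i] / nd
  }
  iv <- as.vector(setup$II); jv <- as.vector(setup$JJ)
  A <- Matrix::sparseMatrix(i = iv, j = jv, x = as.vector(Ax),
                            dims = c(nn, nn))
  Ms <- Matrix::sparseMatrix(i = iv, j = jv, x = as.vector(Mxs),
                             dims = c(nn, nn))
  ## unit source tested against (q + tau a.grad q)
  src <- acc_vec(as.vector(cells),
                 as.vector(meas / nd + tau * meas * adg), nn)
  dir <- rt_dirichlet_nodes(setup, config)
  list(A = A, Ms = Ms, src = src, dir = dir, nn = nn)
}

## phi_new solves (Ms/dt + A) phi = Ms/dt phi_old + src, with phi = 0 on the
## Dirichlet set.
advance_rt <- function(sys, phi, dt) {
  A <- sys$Ms / dt + sys$A
  b <- as.vector(sys$Ms %*% phi) / dt + sys$src
  fixed <- apply_dirichlet(A, b, sys$dir, numeric(length(sys$dir)))
  as.vector(Matrix::solve(fixed$A, fixed$b))
}

#' Residence-time field container
#' @param phi nodal residence time, s.
#' @param total_time total simulated time T, s.
#' @return list of class `rt_field` with `relative_rt = phi / T` clipped to
#'   [0, 1] and the clipped mass fraction recorded.
#' @export
rt_field <- function(phi, total_time) {
  rel_raw <- phi / total_time
  rel <- pmin(pmax(rel_raw, 0), 1)
  structure(list(phi = phi, total_time = total_time,
                 relative_rt = rel,
                 clipped_fraction = mean(rel_raw < -1e-12 | rel_raw > 1 + 1e-12)),
            class = "rt_field")
}

#' @export
print.rt_field <- function(x, ...) {
  cat(sprintf("<rt_field> T = %.3g s, relative RT in [%.3g, %.3g] (clipped fraction %.2g)\n",
              x$total_time, min(x$relative_rt), max(x$relative_rt),
              x$clipped_fraction))
  invisible(x)
}

#' Run the residence-time transport over replayed cardiac cycles
#'
#' Replays the stored final flow cycle periodically (linear interpolation in
#' time between velocity snapshots) for `config$rt_cycles` cycles, solving
#' the source-driven advection equation from phi = 0. Reports the per-cycle
#' volume-weighted mean residence time (relative to elapsed time) and the
#' convergence verdict: relative change in the mean below
#' `config$convergence_threshold` over the final cycle pair.
#'
#' @param flow_history a [run_cycles()] result holding the final cycle at
#'   full snapshot resolution; a synthetic history from
#'   [steady_flow_history()] also works.
#' @param mesh the [tagged_mesh] the flow was computed on.
#' @param config an [rt_config()].
#' @param periodicity_tol maximum allowed relative mismatch between the
#'   first and last stored snapshot (one period apart) before the record is
#'   rejected as non-periodic.
#' @return list with `field` (an [rt_field()]), `mean_rt_trace` (per-cycle
#'   volume-weighted mean residence time, seconds), `converged`, and
#'   `converged_at_cycle`.
#' @export
run_rt <- function(flow_history, mesh, config = rt_config(),
                   periodicity_tol = 0.25) {
  setup <- fem_setup(mesh)
  snaps <- flow_history$snapshots
  stimes <- flow_history$snapshot_times
  if (length(snaps) < 2) stop("run_rt: need at least two velocity snapshots")
  period <- flow_history$period
  vscale <- max(vapply(snaps, function(u) max(abs(u)), numeric(1)))
  mismatch <- max(abs(snaps[[length(snaps)]] - snaps[[1]]))
  if (vscale > 0 && mismatch / vscale > periodicity_tol &&
      !isTRUE(flow_history$steady))
    stop(sprintf(
      "run_rt: velocity record is not periodic (first/last snapshot mismatch %.2f > %.2f)",
      mismatch / vscale, periodicity_tol))
  ## phase of each snapshot within the replayed cycle; histories from
  ## run_cycles record them explicitly (first snapshot at phase 0, last at
  ## phase = period, one full period apart)
  ph <- flow_history$snapshot_phases
  if (is.null(ph)) {
    ph <- (stimes - stimes[1]) %% period
    ph[length(ph)] <- period
  }
  interp_v <- function(tphase) {
    if (tphase <= ph[1]) return(snaps[[1]])
    if (tphase >= ph[length(ph)]) return(snaps[[length(snaps)]])
    k <- findInterval(tphase, ph)
    w <- (tphase - ph[k]) / (ph[k + 1] - ph[k])
    (1 - w) * snaps[[k]] + w * snaps[[k + 1]]
  }
  dt <- flow_history$dt * config$dt_factor
  nsteps <- max(2L, ceiling(period / dt))
  dt <- period / nsteps
  ## node volume weights for the mean
  wvol <- acc_vec(as.vector(setup$cells),
                  rep(setup$meas / setup$nd, setup$nd), setup$nn)
  phi <- numeric(setup$nn)
  ## cache one assembled system per phase point (the replayed field repeats
  ## identically every cycle)
  systems <- vector("list", nsteps)
  mean_trace <- numeric(config$rt_cycles)
  converged_at <- NA_integer_
  for (cyc in seq_len(config$rt_cycles)) {
    for (k in seq_len(nsteps)) {
      tphase <- (k * dt) %% period
      if (is.null(systems[[k]])) {
        v <- interp_v(tphase)
        sys <- rt_system(setup, v, dt, config)
        ## the replayed field repeats every cycle: pre-factor once per phase
        lhs <- sys$Ms / dt + sys$A
        free <- rep(1, sys$nn); free[sys$dir] <- 0
        lhs <- Matrix::Diagonal(x = free) %*% lhs +
          Matrix::Diagonal(sys$nn, x = 1 - free)
        sys$fac <- Matrix::lu(methods::as(lhs, "CsparseMatrix"))
        systems[[k]] <- sys
      }
      sys <- systems[[k]]
      b <- as.vector(sys$Ms %*% phi) / dt + sys$src
      b[sys$dir] <- 0
      phi <- as.vector(Matrix::solve(sys$fac, b))
    }
    ## the convergence criterion tracks the volume-weighted mean residence
    ## time itself (seconds): in a washed-out domain it plateaus once the
    ## transport balances the source, while stagnant regions keep the
    ## per-cycle increment shrinking relative to the accumulated mean
    mean_trace[cyc] <- sum(wvol * phi) / sum(wvol)
    if (cyc >= 2 && is.na(converged_at)) {
      rel <- abs(mean_trace[cyc] - mean_trace[cyc - 1]) /
        max(mean_trace[cyc - 1], 1e-12)
      if (rel < config$convergence_threshold) converged_at <- cyc
    }
  }
  last_change <- abs(diff(mean_trace[(config$rt_cycles - 1):config$rt_cycles])) /
    max(mean_trace[config$rt_cycles - 1], 1e-12)
  list(field = rt_field(phi, config$rt_cycles * period),
       mean_rt_trace = mean_trace,
       converged = last_change < config$convergence_threshold,
       converged_at_cycle = converged_at,
       dt = dt)
}

#' Synthetic steady flow history
#'
#' Wraps a single steady velocity field as a periodic flow record, for
#' residence-time runs on analytic fields (plug flow, closed cavities) and
#' for replaying steady solver solutions.
#'
#' @param velocity nodal velocity matrix.
#' @param period nominal cycle period, s.
#' @param dt nominal flow step used to derive the residence-time step, s.
#' @return A minimal `flow_history` list.
#' @export
steady_flow_history <- function(velocity, period = 60 / 70, dt = period / 100) {
  structure(list(snapshots = list(velocity, velocity),
                 snapshot_times = c(0, period),
                 snapshot_phases = c(0, period),
                 period = period, dt = dt, steady = TRUE),
            class = "flow_history")
}
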