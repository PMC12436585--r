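## Linear (P1) finite-element machinery on simplicial meshes, and the
## stabilized equal-order Navier-Stokes assembly. Everything is vectorized
## over elements; sparse systems are handled by Matrix.

#' Fluid properties
#'
#' Blood is treated as an incompressible Newtonian fluid in the mm-g-s unit
#' system: density in g/mm^3 (1.026 g/ml = 1.026e-3 g/mm^3) and dynamic
#' viscosity in Pa s. With these units pressures land natively in Pa.
#'
#' @param density fluid density, g/mm^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1.026e-3, viscosity = 0.004) {
  if (density <= 0 || viscosity <= 0)
    stop("fluid_properties: density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Flow solver configuration
#'
#' @param dt time step, s.
#' @param cycles number of cardiac cycles to integrate.
#' @param nonlinear_tolerance relative Picard update tolerance per step.
#' @param max_nonlinear_iters Picard iteration cap per step.
#' @param convergence_threshold cycle-to-cycle relative change in peak
#'   velocity and mean TPG below which the run is declared converged.
#' @param snapshot_stride store every `snapshot_stride`-th velocity field of
#'   the final cycle for the residence-time stage.
#' @param backflow_beta backflow-penalty coefficient on Neumann boundaries.
#' @param lsic logical, include the grad-div (least-squares incompressibility)
#'   term.
#' @param verbose print per-cycle summaries while running.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 8e-4, cycles = 3L, nonlinear_tolerance = 1e-4,
                          max_nonlinear_iters = 10L,
                          convergence_threshold = 0.05,
                          snapshot_stride = 5L, backflow_beta = 1,
                          lsic = TRUE, verbose = FALSE) {
  if (dt <= 0) stop("solver_config: dt must be positive")
  if (cycles < 1) stop("solver_config: cycles must be >= 1")
  if (convergence_threshold <= 0 || convergence_threshold >= 1)
    stop("solver_config: convergence_threshold must lie in (0, 1)")
  structure(list(dt = dt, cycles = as.integer(cycles),
                 nonlinear_tolerance = nonlinear_tolerance,
                 max_nonlinear_iters = as.integer(max_nonlinear_iters),
                 convergence_threshold = convergence_threshold,
                 snapshot_stride = as.integer(snapshot_stride),
                 backflow_beta = backflow_beta, lsic = lsic,
                 verbose = verbose), class = "solver_config")
}

#' Instantaneous flow state
#' @param velocity nodal velocity matrix (n x d), mm/s.
#' @param pressure nodal pressure vector, Pa.
#' @param time time, s.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(velocity, pressure, time = 0) {
  if (any(!is.finite(velocity)) || any(!is.finite(pressure)))
    stop("flow_state: fields must be finite")
  structure(list(velocity = velocity, pressure = pressure, time = time),
            class = "flow_state")
}

## ---- element precomputation ---------------------------------------------

#' Precompute P1 element data for a mesh
#'
#' Computes, once per mesh, the constant basis gradients, cell measures,
#' element sizes, triplet index maps, the global mass matrix, and the tagged
#' boundary facet tables used for tractions and flux bookkeeping.
#'
#' @param mesh a [tagged_mesh].
#' @return A `fem_setup` list; cached on repeated use by the solvers.
#' @export
fem_setup <- function(mesh) {
  V <- mesh$vertices; cells <- mesh$cells
  d <- mesh$dim; nd <- d + 1L
  ne <- nrow(cells); nn <- nrow(V)
  meas <- cell_measures(mesh)
  ## constant P1 gradients: rows of the inverse edge matrix
  grad <- array(0, c(ne, nd, d))
  if (d == 2L) {
    x <- matrix(V[cells, 1], ne, nd); y <- matrix(V[cells, 2], ne, nd)
    det2 <- 2 * cell_measures_signed(V, cells)   # positive after orientation
    grad[, 1, 1] <- (y[, 2] - y[, 3]) / det2
    grad[, 2, 1] <- (y[, 3] - y[, 1]) / det2
    grad[, 3, 1] <- (y[, 1] - y[, 2]) / det2
    grad[, 1, 2] <- (x[, 3] - x[, 2]) / det2
    grad[, 2, 2] <- (x[, 1] - x[, 3]) / det2
    grad[, 3, 2] <- (x[, 2] - x[, 1]) / det2
  } else {
    p1 <- V[cells[, 1], , drop = FALSE]
    e1 <- V[cells[, 2], , drop = FALSE] - p1
    e2 <- V[cells[, 3], , drop = FALSE] - p1
    e3 <- V[cells[, 4], , drop = FALSE] - p1
    det6 <- 6 * cell_measures_signed(V, cells)
    cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
    g2 <- cross(e2, e3) / det6
    g3 <- cross(e3, e1) / det6
    g4 <- cross(e1, e2) / det6
    grad[, 2, ] <- g2; grad[, 3, ] <- g3; grad[, 4, ] <- g4
    grad[, 1, ] <- -(g2 + g3 + g4)
  }
  ## element size: longest edge
  h <- rep(0, ne)
  for (i in 1:(nd - 1L)) for (j in (i + 1L):nd) {
    e <- V[cells[, j], , drop = FALSE] - V[cells[, i], , drop = FALSE]
    h <- pmax(h, sqrt(rowSums(e^2)))
  }
  ## triplet index maps for (nd x nd) local blocks
  P <- nd * nd
  II <- matrix(0L, ne, P); JJ <- matrix(0L, ne, P)
  Kx <- matrix(0, ne, P); Mx <- matrix(0, ne, P)
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    p <- (i - 1L) * nd + j
    II[, p] <- cells[, i]; JJ[, p] <- cells[, j]
    Kx[, p] <- meas * rowSums(grad[, i, , drop = FALSE] * grad[, j, , drop = FALSE])
    Mx[, p] <- meas * (1 + (i == j)) / (nd * (nd + 1L))
  }
  Mglobal <- Matrix::sparseMatrix(i = as.vector(II), j = as.vector(JJ),
                                  x = as.vector(Mx), dims = c(nn, nn))
  ## tagged boundary facet tables
  normals <- facet_normals(mesh)
  areas <- facet_measures(V, mesh$facets)
  tg <- mesh_tags()
  ftab <- lapply(tg, function(code) {
    sel <- mesh$facet_tags == code
    list(facets = mesh$facets[sel, , drop = FALSE],
         normals = normals[sel, , drop = FALSE],
         areas = areas[sel])
  })
  names(ftab) <- names(tg)
  ## permanent stabilization mask: cells fully inside an immersed insert
  ## wall are at rest and must carry no PSPG path between jet and pocket
  insert_mask <- NULL
  iw <- if (!is.null(mesh$valve)) mesh$valve$insert_wall_nodes else NULL
  if (length(iw)) {
    allin <- rowSums(matrix(cells %in% iw, ne, nd)) == nd
    if (any(allin)) insert_mask <- as.numeric(!allin)
  }
  structure(list(mesh = mesh, d = d, nd = nd, ne = ne, nn = nn,
                 cells = cells, meas = meas, grad = grad, h = h,
                 insert_mask = insert_mask,
                 II = II, JJ = JJ, Kx = Kx, Mx = Mx, Mglobal = Mglobal,
                 ftab = ftab,
                 ## immersed internal walls (valve-in-valve skirt) join the
                 ## no-slip set
                 wall_nodes = sort(unique(c(
                   boundary_nodes(mesh, "WALL"),
                   if (!is.null(mesh$valve)) mesh$valve$insert_wall_nodes))),
                 inlet_nodes = boundary_nodes(mesh, "INLET"),
                 outlet_nodes = boundary_nodes(mesh, "OUTLET")),
            class = "fem_setup")
}

## Fast boundary flux using the facet tables cached in fem_setup.
tag_flux <- function(setup, U, tags) {
  out <- 0
  d <- setup$d
  for (tag in tags) {
    ft <- setup$ftab[[tag]]
    if (!nrow(ft$facets)) next
    un <- 0
    for (k in seq_len(d))
      un <- un + rowMeans(matrix(U[ft$facets, k], nrow(ft$facets), d)) *
        ft$normals[, k]
    out <- out + sum(ft$areas * un)
  }
  out
}

acc_vec <- function(idx, vals, n) {
  r <- rowsum(vals, idx)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r
  out
}

## Stabilization parameter per element (tau), mm-g-s units.
stab_tau <- function(setup, abar, dt, props) {
  amag <- sqrt(rowSums(abar^2))
  nu <- props$viscosity / props$density
  tinv <- if (is.finite(dt)) (2 / dt)^2 else 0
  1 / sqrt(tinv + (2 * amag / setup$h)^2 + (12 * nu / setup$h^2)^2)
}

## ---- stabilized Navier-Stokes assembly ----------------------------------

## Assemble the monolithic (velocity, pressure) system for one Picard
## iteration of the implicit-Euler, equal-order stabilized scheme.
##   momentum:  rho u_t + rho (a . grad) u + grad p - mu lap u = 0
##   continuity: div u = 0
## with SUPG/PSPG residual stabilization and optional grad-div term.
## `a` is the advective iterate, `u_old` the previous time level (NULL for a
## steady solve, equivalent to dt = Inf).
ns_assemble <- function(setup, a, u_old, dt, props, config, tau_mask = NULL) {
  d <- setup$d; nd <- setup$nd; ne <- setup$ne; nn <- setup$nn
  rho <- props$density; mu <- props$viscosity
  meas <- setup$meas; grad <- setup$grad; cells <- setup$cells
  transient <- is.finite(dt) && !is.null(u_old)
  idt <- if (transient) 1 / dt else 0

  abar <- matrix(0, ne, d)
  for (k in seq_len(d)) abar[, k] <- rowMeans(matrix(a[cells, k], ne, nd))
  tau <- stab_tau(setup, abar, if (transient) dt else Inf, props)
  ## the residual stabilization acts as a pressure-driven porosity; masking
  ## it in elements touching a fully constrained (closed-valve) plane stops
  ## the spurious transvalvular leak the PSPG term would otherwise admit
  if (!is.null(tau_mask)) tau <- tau * tau_mask
  ## a . grad(phi_i), per element and local node
  adg <- matrix(0, ne, nd)
  for (i in seq_len(nd))
    adg[, i] <- rowSums(abar * matrix(grad[, i, ], ne, d))

  P <- nd * nd
  uu <- matrix(0, ne, P)
  pp <- matrix(0, ne, P)
  up <- vector("list", d); pu <- vector("list", d)
  for (k in seq_len(d)) { up[[k]] <- matrix(0, ne, P); pu[[k]] <- matrix(0, ne, P) }
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    p <- (i - 1L) * nd + j
    uu[, p] <- rho * idt * setup$Mx[, p] +
      rho * meas * adg[, j] / nd +
      mu * setup$Kx[, p] +
      rho * tau * meas * adg[, i] * adg[, j] +
      rho * tau * idt * meas * adg[, i] / nd
    pp[, p] <- (tau / rho) * setup$Kx[, p]
    for (k in seq_len(d)) {
      up[[k]][, p] <- -meas * grad[, i, k] / nd +
        tau * meas * adg[, i] * grad[, j, k]
      pu[[k]][, p] <- meas * grad[, j, k] / nd +
        tau * meas * grad[, i, k] * adg[, j] +
        tau * idt * meas * grad[, i, k] / nd
    }
  }

  iv <- as.vector(setup$II); jv <- as.vector(setup$JJ)
  off <- function(k) (k - 1L) * nn            # component offsets
  poff <- d * nn
  ti <- list(); tj <- list(); tx <- list(); n0 <- 0L
  add <- function(ii, jj, xx) {
    n0 <<- n0 + 1L
    ti[[n0]] <<- ii; tj[[n0]] <<- jj; tx[[n0]] <<- xx
  }
  for (k in seq_len(d)) {
    add(iv + off(k), jv + off(k), as.vector(uu))
    add(iv + off(k), jv + poff, as.vector(up[[k]]))
    add(iv + poff, jv + off(k), as.vector(pu[[k]]))
  }
  add(iv + poff, jv + poff, as.vector(pp))
  if (isTRUE(config$lsic)) {
    amag <- sqrt(rowSums(abar^2))
    nul <- 0.5 * setup$h * amag
    for (k in seq_len(d)) for (l in seq_len(d)) {
      x <- matrix(0, ne, P)
      for (i in seq_len(nd)) for (j in seq_len(nd)) {
        p <- (i - 1L) * nd + j
        x[, p] <- rho * nul * meas * grad[, i, k] * grad[, j, l]
      }
      add(iv + off(k), jv + off(l), as.vector(x))
    }
  }
  ndof <- (d + 1L) * nn
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ndof, ndof))
  b <- numeric(ndof)
  if (transient) {
    aold <- matrix(0, ne, d)
    for (k in seq_len(d)) aold[, k] <- rowMeans(matrix(u_old[cells, k], ne, nd))
    for (k in seq_len(d)) {
      b[off(k) + seq_len(nn)] <- rho * idt * as.vector(setup$Mglobal %*% u_old[, k])
      supg_t <- rho * tau * idt * meas * adg * aold[, k]   # ne x nd
      b[off(k) + seq_len(nn)] <- b[off(k) + seq_len(nn)] +
        acc_vec(as.vector(cells), as.vector(supg_t), nn)
    }
    pspg_t <- matrix(0, ne, nd)
    for (k in seq_len(d))
      pspg_t <- pspg_t + tau * idt * meas * grad[, , k] * aold[, k]
    b[poff + seq_len(nn)] <- acc_vec(as.vector(cells), as.vector(pspg_t), nn)
  }
  list(A = A, b = b, abar = abar)
}

## Add a prescribed-pressure traction  t = -P n  on a tagged boundary.
apply_traction <- function(b, setup, tag, pressure) {
  ft <- setup$ftab[[tag]]
  if (!nrow(ft$facets)) return(b)
  d <- setup$d; nn <- setup$nn
  w <- ft$areas / d                           # lumped facet quadrature
  for (k in seq_len(d)) {
    contrib <- -pressure * ft$normals[, k] * w
    b[(k - 1L) * nn + seq_len(nn)] <- b[(k - 1L) * nn + seq_len(nn)] +
      acc_vec(as.vector(ft$facets), rep(contrib, d), nn)
  }
  b
}

## Backflow penalty on a Neumann boundary: adds rho*beta/2 (a.n)_- lumped to
## the velocity diagonal, preventing divergence during flow deceleration.
backflow_diagonal <- function(setup, tag, a, beta, rho) {
  ft <- setup$ftab[[tag]]
  out <- numeric(setup$nn)
  if (!nrow(ft$facets) || beta <= 0) return(out)
  d <- setup$d
  an <- 0
  for (k in seq_len(d))
    an <- an + rowMeans(matrix(a[ft$facets, k], nrow(ft$facets), d)) * ft$normals[, k]
  coef <- rho * beta / 2 * pmax(0, -an) * ft$areas / d
  acc_vec(as.vector(ft$facets), rep(coef, d), setup$nn)
}

## Replace rows of A by identity for Dirichlet dofs and set rhs values.
apply_dirichlet <- function(A, b, idx, val) {
  ndof <- length(b)
  free <- rep(1, ndof); free[idx] <- 0
  A <- Matrix::Diagonal(x = free) %*% A + Matrix::Diagonal(ndof, x = 1 - free)
  b[idx] <- val
  list(A = A, b = b)
}

## One Picard-iterated implicit step (or steady solve when dt = Inf).
## `bc_fun(a, assembled)` returns list(dirichlet_idx, dirichlet_val,
## tractions = list(tag = pressure), backflow_tags).
ns_solve_step <- function(setup, u_old, a0, dt, props, config, bc_fun,
                          tau_mask = NULL) {
  d <- setup$d; nn <- setup$nn
  a <- a0
  ## pressure dofs of nodes buried inside fully masked (rigid) cell patches
  ## are structurally free: pin them (their value is immaterial — every row
  ## referencing them belongs to a Dirichlet velocity dof)
  orphan_p <- integer(0)
  if (!is.null(tau_mask) && any(tau_mask == 0)) {
    act <- setup$cells[tau_mask > 0, , drop = FALSE]
    has_free <- logical(nn); has_free[unique(as.vector(act))] <- TRUE
    orphan_p <- which(!has_free)
  }
  deltas <- numeric(0)
  for (iter in seq_len(config$max_nonlinear_iters)) {
    asm <- ns_assemble(setup, a, u_old, dt, props, config, tau_mask)
    A <- asm$A; b <- asm$b
    bc <- bc_fun(a)
    for (tag in names(bc$tractions))
      b <- apply_traction(b, setup, tag, bc$tractions[[tag]])
    if (length(bc$backflow_tags)) {
      diagadd <- numeric(nn)
      for (tag in bc$backflow_tags)
        diagadd <- diagadd + backflow_diagonal(setup, tag, a,
                                               config$backflow_beta,
                                               props$density)
      if (any(diagadd > 0)) {
        dfull <- c(rep(diagadd, d), numeric(nn))
        A <- A + Matrix::Diagonal(x = dfull)
      }
    }
    dir_idx <- c(bc$dirichlet_idx, d * nn + orphan_p)
    dir_val <- c(bc$dirichlet_val, numeric(length(orphan_p)))
    sys <- apply_dirichlet(A, b, dir_idx, dir_val)
    sol <- as.vector(Matrix::solve(sys$A, sys$b))
    u_new <- matrix(sol[seq_len(d * nn)], nn, d)
    p_new <- sol[d * nn + seq_len(nn)]
    scale <- max(max(abs(u_new)), 1e-12)
    delta <- max(abs(u_new - a)) / scale
    deltas <- c(deltas, delta)
    a <- u_new
    if (delta < config$nonlinear_tolerance) break
  }
  if (length(deltas) >= 3 &&
      deltas[length(deltas)] > 10 * min(deltas) &&
      deltas[length(deltas)] > 0.5)
    stop(sprintf("nonlinear iteration diverged (residual history: %s)",
                 paste(signif(deltas, 3), collapse = ", ")))
  list(u = a, p = p_new, iters = length(deltas), delta = delta,
       deltas = deltas)
}
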