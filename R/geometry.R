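#' Parametric aortic-root description
#'
#' Defines the idealized aortic-root lumen used as the synthetic stand-in for
#' patient anatomies: an LVOT tube, the annulus (valve plane), three sinus
#' bulges, the sinotubular junction (STJ), and a straight ascending aorta,
#' with two optional coronary ostia on the sinus wall. All lengths in mm.
#'
#' Defaults follow a typical surgical-valve cohort: a 23 mm native annulus,
#' sinus bulges of 4 mm amplitude over a 20 mm sinus height, a 26 mm STJ and a
#' 30 mm ascending aorta. The ascending segment is kept at least 30 mm long so
#' the downstream pressure-gradient plane always exists.
#'
#' @param annulus_diameter annulus (LVOT) diameter, mm.
#' @param sinus_bulge_radius radial bulge amplitude of the sinuses, mm.
#' @param sinus_height axial extent of the sinus region, mm.
#' @param stj_diameter sinotubular junction diameter, mm.
#' @param aorta_diameter ascending aorta diameter, mm.
#' @param lvot_length axial length of the LVOT tube upstream of the annulus, mm.
#' @param aorta_length axial length of the ascending aorta beyond the STJ, mm
#'   (must be at least 30 so the TPG plane exists).
#' @param coronary_diameter diameter of each coronary ostium, mm.
#' @param coronary_angles angular placement (degrees) of the two ostia on the
#'   sinus wall (3-D mode); in 2-D planar mode they map to the left/right wall.
#' @param coronary_axial_frac axial position of the ostia as a fraction of the
#'   sinus height above the annulus.
#' @param include_coronaries logical; tag coronary ostia at all?
#' @param enlargement_factor dimensionless scaling (>= 1) of annulus, sinus and
#'   STJ dimensions, used by the annular-enlargement scenario.
#' @param tavr_insert optional [funnel_insert()] describing a valve-in-valve
#'   funnel that narrows the orifice.
#' @return An object of class `root_parameters`.
#' @export
root_parameters <- function(annulus_diameter = 23, sinus_bulge_radius = 4,
                            sinus_height = 20, stj_diameter = 26,
                            aorta_diameter = 30, lvot_length = 10,
                            aorta_length = 40, coronary_diameter = 3,
                            coronary_angles = c(120, 240),
                            coronary_axial_frac = 0.5,
                            include_coronaries = TRUE,
                            enlargement_factor = 1, tavr_insert = NULL) {
  lens <- c(annulus_diameter, sinus_bulge_radius, sinus_height, stj_diameter,
            aorta_diameter, lvot_length, aorta_length, coronary_diameter)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("root_parameters: all lengths must be positive and finite")
  if (enlargement_factor < 1 || enlargement_factor > 2)
    stop("root_parameters: enlargement_factor must lie in [1, 2]")
  if (aorta_length < 30)
    stop("root_parameters: aorta_length must be >= 30 mm (downstream TPG plane)")
  if (!is.null(tavr_insert) && !inherits(tavr_insert, "funnel_insert"))
    stop("tavr_insert must be created with funnel_insert()")
  p <- structure(list(
    annulus_diameter = annulus_diameter,
    sinus_bulge_radius = sinus_bulge_radius,
    sinus_height = sinus_height, stj_diameter = stj_diameter,
    aorta_diameter = aorta_diameter, lvot_length = lvot_length,
    aorta_length = aorta_length, coronary_diameter = coronary_diameter,
    coronary_angles = coronary_angles,
    coronary_axial_frac = coronary_axial_frac,
    include_coronaries = include_coronaries,
    enlargement_factor = enlargement_factor,
    tavr_insert = tavr_insert), class = "root_parameters")
  ## the STJ must not exceed the maximal sinus bulge diameter, estimated at
  ## mid-sinus where the bulge peaks (base ~ (annulus + STJ)/2 + 2 bulge);
  ## wider junctions make the "sinus" a plain cone and the bulge meaningless
  if (stj_diameter > annulus_diameter + 4 * sinus_bulge_radius)
    stop("root_parameters: stj_diameter exceeds the maximal sinus bulge diameter")
  p
}

#' @export
print.root_parameters <- function(x, ...) {
  cat(sprintf("<root_parameters> annulus %g mm, sinus bulge %g mm, STJ %g mm, aorta %g mm x %g mm\n",
              x$annulus_diameter, x$sinus_bulge_radius, x$stj_diameter,
              x$aorta_diameter, x$aorta_length))
  if (x$enlargement_factor > 1)
    cat(sprintf("  enlargement factor %.4g\n", x$enlargement_factor))
  if (!is.null(x$tavr_insert))
    cat(sprintf("  TAVR funnel insert: throat %g mm, inlet %g mm\n",
                x$tavr_insert$throat_diameter, x$tavr_insert$inlet_diameter))
  invisible(x)
}

#' Valve-in-valve funnel insert
#'
#' Parametric idealization of a transcatheter valve deployed inside the
#' surgical valve: a funnel whose inflow sits `axial_offset` mm below the
#' annulus plane, tapering to a reduced throat at the annulus, with a
#' cylindrical skirt of height `skirt_height` continuing above it. The skirt
#' walls off part of the sinus, leaving a deeper, less-washed sinus recess
#' (the neo-sinus analogue).
#'
#' @param inlet_diameter funnel inflow diameter, mm.
#' @param throat_diameter reduced orifice diameter (post-implant GOA), mm.
#' @param axial_offset distance of the funnel inflow below the annulus plane,
#'   mm (default 4).
#' @param skirt_height height of the constant-diameter skirt above the
#'   annulus, mm.
#' @return An object of class `funnel_insert`.
#' @export
funnel_insert <- function(inlet_diameter, throat_diameter,
                          axial_offset = 4, skirt_height = 8) {
  if (any(c(inlet_diameter, throat_diameter, axial_offset, skirt_height) <= 0))
    stop("funnel_insert: all dimensions must be positive")
  if (throat_diameter >= inlet_diameter)
    stop("funnel_insert: throat_diameter must be smaller than inlet_diameter")
  structure(list(inlet_diameter = inlet_diameter,
                 throat_diameter = throat_diameter,
                 axial_offset = axial_offset,
                 skirt_height = skirt_height), class = "funnel_insert")
}

#' Axial breakpoints of the root profile
#' @keywords internal
root_breakpoints <- function(params) {
  z1 <- params$lvot_length
  z2 <- z1 + params$sinus_height
  tlen <- min(5, params$aorta_length / 4)
  c(inlet = 0, annulus = z1, stj = z2, aorta_start = z2 + tlen,
    outlet = z2 + params$aorta_length)
}

#' Lumen radius of the parametric root profile
#'
#' Radius of the root lumen at axial coordinate `s` (mm from the inlet plane)
#' and, in 3-D, azimuthal angle `theta`. The sinus region carries three
#' bulges modulated as `0.7 + 0.3 cos(3 theta)`; in 2-D planar mode the bulge
#' is applied uniformly (`theta = NULL`). A valve-in-valve funnel insert, when
#' present, truncates the profile from inside.
#'
#' @param params a [root_parameters()] object.
#' @param s axial coordinates (vectorized), mm.
#' @param theta azimuthal angles (radians), recycled against `s`; `NULL` for
#'   the planar profile.
#' @return numeric vector of radii, mm.
#' @export
root_radius <- function(params, s, theta = NULL) {
  ef <- params$enlargement_factor
  r_ann <- ef * params$annulus_diameter / 2
  r_stj <- ef * params$stj_diameter / 2
  bulge <- ef * params$sinus_bulge_radius
  r_ao <- params$aorta_diameter / 2
  zs <- root_breakpoints(params)
  lobe <- if (is.null(theta)) rep(1, length(s)) else 0.7 + 0.3 * cos(3 * theta)
  lobe <- rep_len(lobe, length(s))
  r <- numeric(length(s))
  ## LVOT
  i <- s <= zs["annulus"]
  r[i] <- r_ann
  ## sinus region
  i <- s > zs["annulus"] & s <= zs["stj"]
  z <- (s[i] - zs["annulus"]) / params$sinus_height
  base <- r_ann + (r_stj - r_ann) * (1 - cos(pi * z)) / 2
  r[i] <- base + bulge * sin(pi * z) * lobe[i]
  ## STJ -> aorta blend
  i <- s > zs["stj"] & s <= zs["aorta_start"]
  z <- (s[i] - zs["stj"]) / (zs["aorta_start"] - zs["stj"])
  r[i] <- r_stj + (r_ao - r_stj) * (1 - cos(pi * z)) / 2
  ## ascending aorta
  i <- s > zs["aorta_start"]
  r[i] <- r_ao
  ## The funnel insert truncates the lumen below the valve plane only (the
  ## stent frame and held-open surgical leaflets fill the annulus there).
  ## Above the plane the lumen keeps its full sinus profile: the skirt is an
  ## immersed wall added at mesh level, so the fluid between skirt and sinus
  ## wall remains in the domain as the neo-sinus pocket.
  fi <- params$tavr_insert
  if (!is.null(fi)) {
    zv <- zs["annulus"]
    fr <- rep(Inf, length(s))
    j <- s >= zv - fi$axial_offset & s <= zv
    zz <- (s[j] - (zv - fi$axial_offset)) / fi$axial_offset
    fr[j] <- fi$inlet_diameter / 2 +
      (fi$throat_diameter - fi$inlet_diameter) / 2 * zz
    r <- pmin(r, fr)
  }
  unname(r)
}

## ---- structured builders ------------------------------------------------

## Subdivide [a, b] breakpoint intervals into steps of at most `edge`.
subdivide_stations <- function(breaks, edge) {
  breaks <- sort(unique(round(breaks, 9)))
  out <- breaks[1]
  for (k in seq_len(length(breaks) - 1L)) {
    n <- max(1L, ceiling((breaks[k + 1L] - breaks[k]) / edge))
    out <- c(out, seq(breaks[k], breaks[k + 1L], length.out = n + 1L)[-1L])
  }
  out
}

## Structured 2-D planar mesh: transverse fractions `q` in [-1, 1] scaled by
## the local half-width radius_fun(s) at each axial station. `q` may also be
## an (n_stations x nq) matrix of per-station fractions (used to snap nodes
## onto immersed internal walls).
build_structured_2d <- function(stations, q, radius_fun) {
  nk <- length(stations)
  Q <- if (is.matrix(q)) q else matrix(q, nk, length(q), byrow = TRUE)
  nq <- ncol(Q)
  r <- radius_fun(stations)
  x <- as.vector(sweep(t(Q), 2L, r, `*`))   # node (j, k): j fastest
  y <- rep(stations, each = nq)
  vertices <- cbind(x, y)
  id <- function(k, j) (k - 1L) * nq + j
  ks <- rep(seq_len(nk - 1L), each = nq - 1L)
  js <- rep(seq_len(nq - 1L), times = nk - 1L)
  a <- id(ks, js); b <- id(ks, js + 1L)
  c2 <- id(ks + 1L, js + 1L); d2 <- id(ks + 1L, js)
  cells <- rbind(cbind(a, b, c2), cbind(a, c2, d2))
  list(vertices = vertices, cells = cells, nq = nq, nk = nk)
}

## Reference disk triangulation: rings at radius fractions `fracs` (excluding
## the centre), `m` nodes per ring. Returns unit-disk points and triangles.
disk_reference <- function(fracs, m) {
  nr <- length(fracs)
  theta <- 2 * pi * (seq_len(m) - 1L) / m
  pts <- rbind(c(0, 0),
               do.call(rbind, lapply(fracs, function(f)
                 cbind(f * cos(theta), f * sin(theta)))))
  nid <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L
  tris <- list()
  j <- seq_len(m)
  tris[[1]] <- cbind(1L, nid(1L, j), nid(1L, j + 1L))
  if (nr > 1L) for (i in seq_len(nr - 1L)) {
    tris[[i + 1L]] <- rbind(cbind(nid(i, j), nid(i, j + 1L), nid(i + 1L, j + 1L)),
                            cbind(nid(i, j), nid(i + 1L, j + 1L), nid(i + 1L, j)))
  }
  list(points = pts, tris = do.call(rbind, tris),
       theta = c(0, rep(theta, nr)), frac = c(0, rep(fracs, each = m)))
}

## Extrude a 2-D triangulation through axial stations into tetrahedra.
## `coord_fun(k)` returns the (n x 2) in-plane coordinates of layer k.
## Prisms are split into 3 tets with the min-local-index diagonal rule, which
## is conforming across neighbouring prisms and layers.
extrude_triangulation <- function(base_tris, n_base, stations, coord_fun) {
  nk <- length(stations)
  verts <- vector("list", nk)
  for (k in seq_len(nk))
    verts[[k]] <- cbind(coord_fun(k), stations[k])
  vertices <- do.call(rbind, verts)
  tri <- t(apply(base_tris, 1L, sort.int))       # a < b < c locally
  a <- tri[, 1]; b <- tri[, 2]; c3 <- tri[, 3]
  cells <- vector("list", nk - 1L)
  for (k in seq_len(nk - 1L)) {
    lo <- (k - 1L) * n_base; hi <- k * n_base
    a0 <- lo + a; b0 <- lo + b; c0 <- lo + c3
    a1 <- hi + a; b1 <- hi + b; c1 <- hi + c3
    cells[[k]] <- rbind(cbind(a0, b0, c0, c1),
                        cbind(a0, b0, c1, b1),
                        cbind(a0, b1, c1, a1))
  }
  list(vertices = vertices, cells = do.call(rbind, cells))
}

## Boundary facet extraction + geometric tagging shared by the generators.
## `tag_fun(centroids, normals)` returns an integer tag per boundary facet.
extract_tagged_boundary <- function(vertices, cells, tag_fun) {
  d <- ncol(vertices)
  cen <- face_census(cells, d)
  bsel <- cen$count == 1L
  bfaces <- cen$faces[bsel, , drop = FALSE]
  ## deduplicate (each boundary face appears once in the census rows)
  key <- cen$key[bsel]
  keep <- !duplicated(key)
  bfaces <- bfaces[keep, , drop = FALSE]
  fc <- facet_centroids(vertices, bfaces)
  list(facets = bfaces, centroids = fc, owner = cen$owner[bsel][keep],
       census = cen)
}

## Per-layer lumped cross-section weights.
layer_weight_table_2d <- function(vertices, stations, nq) {
  lapply(seq_along(stations), function(k) {
    ids <- (k - 1L) * nq + seq_len(nq)
    x <- vertices[ids, 1]
    o <- order(x); xo <- x[o]
    w <- numeric(nq)
    w[1] <- (xo[2] - xo[1]) / 2
    w[nq] <- (xo[nq] - xo[nq - 1]) / 2
    if (nq > 2) w[2:(nq - 1)] <- (xo[3:nq] - xo[1:(nq - 2)]) / 2
    list(nodes = ids[o], w = w)
  })
}

layer_weight_table_3d <- function(vertices, stations, n_disk, disk_tris) {
  lapply(seq_along(stations), function(k) {
    ids <- (k - 1L) * n_disk + seq_len(n_disk)
    pts <- vertices[ids, 1:2, drop = FALSE]
    a <- pts[disk_tris[, 1], , drop = FALSE]
    b <- pts[disk_tris[, 2], , drop = FALSE]
    c3 <- pts[disk_tris[, 3], , drop = FALSE]
    ar <- abs((b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
              (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])) / 2
    w <- numeric(n_disk)
    for (j in 1:3) {
      acc <- tapply(ar / 3, disk_tris[, j], sum)
      w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
    }
    list(nodes = ids, w = w)
  })
}

## ---- root mesh ----------------------------------------------------------

#' Build a parametric aortic-root mesh
#'
#' Generates the idealized root lumen mesh (LVOT tube, annulus, sinus bulges,
#' STJ, ascending aorta) as a structured simplicial mesh: triangles on the
#' planar mid-slice in `"2d"` mode, tetrahedra from an extruded disk in
#' `"3d"` mode. Boundary facets are tagged INLET / OUTLET / WALL /
#' CORONARY_L / CORONARY_R, and the valve plane at the annulus is stored with
#' its orifice and annulus-ring node sets for the orifice-plane valve model.
#' A transverse node ring is snapped to the geometric orifice radius so the
#' open orifice area matches the GOA.
#'
#' @param params a [root_parameters()] object.
#' @param edge_length target edge length, mm; must be < annulus_diameter / 4.
#' @param mode `"2d"` (planar, CI scale) or `"3d"`.
#' @param valve optional [valve_spec()]; defaults to a valve whose internal
#'   diameter equals the (enlarged) annulus diameter. With a TAVR insert the
#'   orifice is the funnel throat.
#' @param seed integer recorded in the mesh metadata (the structured
#'   generator itself is deterministic).
#' @return A [tagged_mesh].
#' @export
build_root_mesh <- function(params, edge_length, mode = c("2d", "3d"),
                            valve = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "root_parameters"))
  ef <- params$enlargement_factor
  ann <- ef * params$annulus_diameter
  if (edge_length <= 0 || edge_length >= ann / 4)
    stop("build_root_mesh: edge_length must be positive and < annulus_diameter/4")
  if (is.null(valve))
    valve <- valve_spec(implanted_internal_diameter = ann)
  zs <- root_breakpoints(params)
  z_v <- unname(zs["annulus"]) + valve$valve_plane_offset
  if (zs["outlet"] - z_v < 30)
    stop("build_root_mesh: aorta too short for the 30 mm downstream plane")
  r_goa <- if (!is.null(params$tavr_insert)) {
    params$tavr_insert$throat_diameter / 2
  } else valve$goa_diameter / 2
  if (2 * r_goa > ann + 1e-9)
    stop("build_root_mesh: orifice larger than the annulus lumen")

  breaks <- unname(zs)
  breaks <- c(breaks, z_v, z_v + 30)
  fi <- params$tavr_insert
  if (!is.null(fi))
    breaks <- c(breaks, zs["annulus"] - fi$axial_offset,
                zs["annulus"] + 1, zs["annulus"] + 2,   # pocket floor band
                zs["annulus"] + fi$skirt_height)
  if (params$include_coronaries) {
    z_c <- zs["annulus"] + params$coronary_axial_frac * params$sinus_height
    r_c <- params$coronary_diameter / 2
    breaks <- c(breaks, z_c - r_c, z_c, z_c + r_c)
  }
  stations <- subdivide_stations(breaks[breaks >= 0 & breaks <= zs["outlet"]],
                                 edge_length)
  tg <- mesh_tags()

  skirt_ids <- integer(0)
  skirt_span <- if (!is.null(fi))
    c(zs[["annulus"]], zs[["annulus"]] + fi$skirt_height) else NULL
  if (mode == "2d") {
    rfun <- function(s) root_radius(params, s)
    rmax <- max(rfun(stations))
    nq <- max(6L, ceiling(2 * rmax / edge_length))
    q <- seq(-1, 1, length.out = nq + 1L)
    f_goa <- r_goa / rfun(z_v)
    if (f_goa < 1 - 1e-9) {
      ## drop uniform points crowding the snapped orifice fractions
      dq <- 2 / nq
      q <- q[pmin(abs(q - f_goa), abs(q + f_goa)) > 0.25 * dq]
      q <- c(q, -f_goa, f_goa)
    }
    q <- sort(unique(round(q, 9)))
    Q <- matrix(q, length(stations), length(q), byrow = TRUE)
    if (!is.null(skirt_span)) {
      ## The immersed skirt is a thin solid: two reserved columns per side
      ## (inner surface at the throat radius, outer at + wall thickness)
      ## whose in-between cells are fully constrained, so no stabilization
      ## pathway connects jet and neo-sinus pocket. A two-layer floor band
      ## just above the valve plane seals the pocket from below; the only
      ## opening is the pocket mouth above the skirt top.
      t_wall <- 0.6
      ks <- which(stations > skirt_span[1] + 1e-9 &
                  stations <= skirt_span[2] + 1e-9)
      f_in <- pmin(r_goa / rfun(stations), 1 - 1e-6)
      f_out <- pmin((r_goa + t_wall) / rfun(stations), 1 - 1e-6)
      if (length(ks) && max(f_out[ks]) < 1 - 2e-6) {
        dq <- 2 / nq
        band <- c(min(f_in[ks]) - 0.4 * dq, max(f_out[ks]) + 0.4 * dq)
        q <- q[!(abs(q) >= band[1] & abs(q) <= band[2] &
                 abs(q) > 1e-9 & abs(q) < 1 - 1e-9)]
        a1 <- band[1] + 0.25 * diff(band)   # placeholder fractions outside
        a2 <- band[1] + 0.75 * diff(band)   # the skirt span
        q <- sort(c(q, -a2, -a1, a1, a2))
        jcols <- c(which(abs(q + a2) < 1e-12), which(abs(q + a1) < 1e-12),
                   which(abs(q - a1) < 1e-12), which(abs(q - a2) < 1e-12))
        Q <- matrix(q, length(stations), length(q), byrow = TRUE)
        for (k in ks) {
          Q[k, jcols] <- c(-f_out[k], -f_in[k], f_in[k], f_out[k])
          skirt_ids <- c(skirt_ids, (k - 1L) * length(q) + jcols)
        }
        ## floor band: freeze everything outboard of the throat on the two
        ## stations above the valve plane
        kf <- which(stations > z_v + 1e-9 & stations <= z_v + 2 + 1e-9)
        for (k in kf) {
          floor_j <- which(abs(Q[k, ]) >= f_in[k] - 1e-9)
          skirt_ids <- c(skirt_ids, (k - 1L) * length(q) + floor_j)
        }
      }
    }
    gg <- build_structured_2d(stations, Q, rfun)
    bd <- extract_tagged_boundary(gg$vertices, gg$cells, NULL)
    sc <- bd$centroids[, 2]
    tol <- 1e-6 * max(1, edge_length)
    tags <- rep(tg["WALL"], nrow(bd$facets))
    tags[sc < stations[1] + tol] <- tg["INLET"]
    tags[sc > stations[length(stations)] - tol] <- tg["OUTLET"]
    if (params$include_coronaries) {
      z_c <- unname(zs["annulus"] + params$coronary_axial_frac * params$sinus_height)
      r_c <- params$coronary_diameter / 2
      wall <- tags == tg["WALL"]
      span <- abs(sc - z_c) <= r_c + tol
      tags[wall & span & bd$centroids[, 1] < 0] <- tg["CORONARY_L"]
      tags[wall & span & bd$centroids[, 1] > 0] <- tg["CORONARY_R"]
    }
    vertices <- gg$vertices; cells <- gg$cells
    lw <- layer_weight_table_2d(vertices, stations, length(q))
    n_trans <- abs(vertices[, 1])
  } else {
    rfun <- function(s, th) root_radius(params, s, th)
    rmax <- max(root_radius(params, stations)) * 1.01
    nr <- max(3L, ceiling(rmax / edge_length))
    fracs <- seq_len(nr) / nr
    f_goa <- r_goa / root_radius(params, z_v)
    if (f_goa < 1 - 1e-9) {
      fracs <- fracs[abs(fracs - f_goa) > 0.25 / nr]
      fracs <- sort(unique(round(c(fracs, f_goa), 9)))
    }
    ## Immersed skirt wall, 3-D analogue of the 2-D construction: two
    ## reserved rings (throat radius and + wall thickness) whose strip is
    ## fully constrained, plus a two-layer annular floor band.
    t_wall <- 0.6
    ks <- if (!is.null(skirt_span))
      which(stations > skirt_span[1] + 1e-9 &
            stations <= skirt_span[2] + 1e-9) else integer(0)
    i_in <- i_out <- NA_integer_
    if (length(ks)) {
      thg <- seq(0, 2 * pi, length.out = 181)[-181]
      fr_all <- unlist(lapply(stations[ks], function(s)
        r_goa / root_radius(params, rep(s, length(thg)), thg)))
      fr_hi <- fr_all * (r_goa + t_wall) / r_goa
      if (max(fr_hi) < 1 - 2e-6) {
        band <- c(min(fr_all) - 0.4 / nr, max(fr_hi) + 0.4 / nr)
        fracs <- fracs[!(fracs >= band[1] & fracs <= band[2] &
                         fracs < 1 - 1e-9)]
        a1 <- band[1] + 0.25 * diff(band)
        a2 <- band[1] + 0.75 * diff(band)
        fracs <- sort(unique(c(fracs, a1, a2)))
        i_in <- which(abs(fracs - a1) < 1e-12)
        i_out <- which(abs(fracs - a2) < 1e-12)
      } else ks <- integer(0)
    }
    m <- max(8L, ceiling(2 * pi * rmax / edge_length))
    disk <- disk_reference(fracs, m)
    n_disk <- nrow(disk$points)
    ring_of <- c(0L, ceiling(seq_len(n_disk - 1L) / m))  # 0 = centre
    kf3 <- which(stations > z_v + 1e-9 & stations <= z_v + 2 + 1e-9)
    coord_fun <- function(k) {
      rr <- rfun(rep(stations[k], n_disk), disk$theta)
      rad <- disk$frac * rr
      if (k %in% ks) {
        sin_ <- which(ring_of == i_in); sout <- which(ring_of == i_out)
        rad[sin_] <- r_goa
        rad[sout] <- r_goa + t_wall
        skirt_ids <<- c(skirt_ids, (k - 1L) * n_disk + c(sin_, sout))
        if (k %in% kf3) {
          fl <- which(rad >= r_goa - 1e-9)
          skirt_ids <<- c(skirt_ids, (k - 1L) * n_disk + fl)
        }
      }
      cbind(rad * cos(disk$theta), rad * sin(disk$theta))
    }
    ex <- extrude_triangulation(disk$tris, n_disk, stations, coord_fun)
    vertices <- ex$vertices; cells <- ex$cells
    bd <- extract_tagged_boundary(vertices, cells, NULL)
    sc <- bd$centroids[, 3]
    tol <- 1e-6 * max(1, edge_length)
    tags <- rep(tg["WALL"], nrow(bd$facets))
    tags[sc < stations[1] + tol] <- tg["INLET"]
    tags[sc > stations[length(stations)] - tol] <- tg["OUTLET"]
    if (params$include_coronaries) {
      z_c <- unname(zs["annulus"] + params$coronary_axial_frac * params$sinus_height)
      r_c <- params$coronary_diameter / 2
      for (side in 1:2) {
        th <- params$coronary_angles[side] * pi / 180
        ctr_r <- root_radius(params, z_c, th)
        ctr <- c(ctr_r * cos(th), ctr_r * sin(th), z_c)
        rad <- max(r_c, 0.8 * edge_length)
        repeat {
          dd <- sqrt(rowSums(sweep(bd$centroids, 2L, ctr)^2))
          sel <- tags == tg["WALL"] & dd <= rad
          if (sum(sel) >= 2L || rad > 4 * r_c + 2 * edge_length) break
          rad <- rad * 1.4
        }
        tags[sel] <- tg[c("CORONARY_L", "CORONARY_R")[side]]
      }
    }
    lw <- layer_weight_table_3d(vertices, stations, n_disk, disk$tris)
    n_trans <- sqrt(vertices[, 1]^2 + vertices[, 2]^2)
  }

  ## valve plane node sets and interior facets
  dax <- ncol(vertices)
  tolv <- 1e-6 * max(1, edge_length)
  plane_nodes <- which(abs(vertices[, dax] - z_v) <= tolv)
  ## closed-valve band: the plane layer plus the adjacent upstream layer, so
  ## the cells between them are exactly divergence-free when the valve is
  ## shut and the two compartments decouple discretely
  kv <- which(abs(stations - z_v) <= tolv)[1]
  s_prev <- stations[max(1L, kv - 1L)]
  closed_nodes <- sort(unique(c(plane_nodes,
                                which(abs(vertices[, dax] - s_prev) <= tolv))))
  rho <- n_trans[plane_nodes]
  orifice_nodes <- plane_nodes[rho < r_goa - 1e-6]
  annulus_nodes <- setdiff(plane_nodes, orifice_nodes)
  cenl <- face_census(cells, dax)
  on_plane <- abs(vertices[, dax] - z_v) <= tolv
  int_sel <- cenl$count == 2L &
    rowSums(matrix(on_plane[cenl$faces], nrow(cenl$faces))) == dax
  vfaces <- cenl$faces[int_sel, , drop = FALSE]
  vkey <- cenl$key[int_sel]
  vfaces <- vfaces[!duplicated(vkey), , drop = FALSE]
  vc <- facet_centroids(vertices, vfaces)
  vrho <- if (dax == 2L) abs(vc[, 1]) else sqrt(vc[, 1]^2 + vc[, 2]^2)
  vtags <- ifelse(vrho < r_goa, tg["VALVE_ORIFICE"], tg["VALVE_ANNULUS"])

  valve_info <- list(station = z_v, goa_diameter = 2 * r_goa,
                     plane_nodes = plane_nodes,
                     closed_nodes = closed_nodes,
                     orifice_nodes = orifice_nodes,
                     annulus_nodes = annulus_nodes,
                     insert_wall_nodes = sort(unique(skirt_ids)),
                     facets = vfaces, facet_tags = as.integer(vtags),
                     spec = valve)
  new_tagged_mesh(vertices, cells, bd$facets, tags, edge_length,
                  valve = valve_info, stations = stations,
                  layer_weights = lw,
                  meta = list(kind = "root", mode = mode, params = params,
                              seed = seed))
}

#' Apply a surgical scenario to root parameters
#'
#' Transforms a baseline parameter set into one of the study scenarios:
#' \describe{
#'   \item{BASELINE}{returned unchanged (surgical valve matching the native
#'     annulus).}
#'   \item{YAAE}{annular enlargement: annulus, sinus and STJ dimensions are
#'     scaled by the ratio of the implanted to the native valve size, allowing
#'     the larger prosthesis.}
#'   \item{TAVR_IN_SAVR}{valve-in-valve: a [funnel_insert()] is attached whose
#'     throat reduces the geometric orifice area by `goa_area_reduction`
#'     (default 20\%).}
#' }
#'
#' @param params a [root_parameters()] object (native anatomy).
#' @param scenario one of `"BASELINE"`, `"YAAE"`, `"TAVR_IN_SAVR"`.
#' @param valve a [valve_spec()] for the implanted valve.
#' @param goa_area_reduction fractional GOA area reduction caused by the
#'   valve-in-valve implant.
#' @return Updated `root_parameters`.
#' @export
apply_scenario <- function(params, scenario = c("BASELINE", "YAAE", "TAVR_IN_SAVR"),
                           valve, goa_area_reduction = 0.20) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "root_parameters"), inherits(valve, "valve_spec"))
  if (scenario == "BASELINE") return(params)
  if (scenario == "YAAE") {
    ratio <- valve$implanted_internal_diameter / params$annulus_diameter
    if (ratio < 1)
      stop("apply_scenario: YAAE requires a valve larger than the native annulus")
    if (params$enlargement_factor > 1 && params$enlargement_factor < ratio - 1e-9)
      warning(sprintf(
        "enlargement_factor %.3g is smaller than the valve size ratio %.3g; using the ratio",
        params$enlargement_factor, ratio))
    params$enlargement_factor <- ratio
    return(params)
  }
  ## TAVR_IN_SAVR
  goa <- valve$goa_diameter
  throat <- goa * sqrt(1 - goa_area_reduction)
  params$tavr_insert <- funnel_insert(
    inlet_diameter = min(goa + 4, params$enlargement_factor * params$annulus_diameter - 1),
    throat_diameter = throat)
  params
}

#' Build a verification fixture mesh
#'
#' Small analytic domains used to verify the solvers against closed forms:
#' \describe{
#'   \item{PIPE}{3-D straight cylinder, `dims = c(radius, length)`;
#'     INLET/OUTLET/WALL tags (Hagen-Poiseuille oracle).}
#'   \item{CHANNEL}{2-D rectangle, `dims = c(length, width)` with the axial
#'     direction along the length; INLET/OUTLET/WALL tags (plane-Poiseuille
#'     and plug-flow oracles).}
#'   \item{CAVITY}{closed rectangle (2-D, `dims = c(width, height)`) or box
#'     (3-D, `dims = c(width, depth, height)`); every facet tagged WALL.}
#' }
#'
#' @param kind fixture kind.
#' @param dims numeric dimensions, mm (see above).
#' @param edge_length target edge length, mm.
#' @return A [tagged_mesh].
#' @export
build_fixture_mesh <- function(kind = c("PIPE", "CHANNEL", "CAVITY"),
                               dims, edge_length) {
  kind <- match.arg(kind)
  if (any(dims <= 0) || edge_length <= 0)
    stop("build_fixture_mesh: dims and edge_length must be positive")
  tg <- mesh_tags()
  if (kind == "PIPE") {
    stopifnot(length(dims) == 2L)
    R <- dims[1]; L <- dims[2]
    stations <- seq(0, L, length.out = max(2L, ceiling(L / edge_length)) + 1L)
    nr <- max(2L, ceiling(R / edge_length))
    m <- max(8L, ceiling(2 * pi * R / edge_length))
    disk <- disk_reference(seq_len(nr) / nr, m)
    n_disk <- nrow(disk$points)
    coord_fun <- function(k) disk$points * R
    ex <- extrude_triangulation(disk$tris, n_disk, stations, coord_fun)
    bd <- extract_tagged_boundary(ex$vertices, ex$cells, NULL)
    sc <- bd$centroids[, 3]
    tol <- 1e-9 * L
    tags <- rep(tg["WALL"], nrow(bd$facets))
    tags[sc < tol] <- tg["INLET"]
    tags[sc > L - tol] <- tg["OUTLET"]
    lw <- layer_weight_table_3d(ex$vertices, stations, n_disk, disk$tris)
    return(new_tagged_mesh(ex$vertices, ex$cells, bd$facets, tags, edge_length,
                           stations = stations, layer_weights = lw,
                           meta = list(kind = "pipe", dims = dims)))
  }
  if (kind == "CHANNEL" || (kind == "CAVITY" && length(dims) == 2L)) {
    L <- if (kind == "CHANNEL") dims[1] else dims[2]
    W <- if (kind == "CHANNEL") dims[2] else dims[1]
    stations <- seq(0, L, length.out = max(2L, ceiling(L / edge_length)) + 1L)
    nq <- max(2L, ceiling(W / edge_length))
    q <- seq(-1, 1, length.out = nq + 1L)
    gg <- build_structured_2d(stations, q, function(s) rep(W / 2, length(s)))
    bd <- extract_tagged_boundary(gg$vertices, gg$cells, NULL)
    sc <- bd$centroids[, 2]
    tol <- 1e-9 * L
    tags <- rep(tg["WALL"], nrow(bd$facets))
    if (kind == "CHANNEL") {
      tags[sc < tol] <- tg["INLET"]
      tags[sc > L - tol] <- tg["OUTLET"]
    }
    lw <- layer_weight_table_2d(gg$vertices, stations, length(q))
    return(new_tagged_mesh(gg$vertices, gg$cells, bd$facets, tags, edge_length,
                           stations = stations, layer_weights = lw,
                           meta = list(kind = tolower(kind), dims = dims)))
  }
  ## 3-D cavity box: extruded structured rectangle, all WALL
  stopifnot(length(dims) == 3L)
  W <- dims[1]; D <- dims[2]; H <- dims[3]
  nx <- max(2L, ceiling(W / edge_length)); ny <- max(2L, ceiling(D / edge_length))
  xs <- seq(-W / 2, W / 2, length.out = nx + 1L)
  ys <- seq(-D / 2, D / 2, length.out = ny + 1L)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  is <- rep(seq_len(nx), times = ny); jsq <- rep(seq_len(ny), each = nx)
  a <- nid(is, jsq); b <- nid(is + 1L, jsq)
  c3 <- nid(is + 1L, jsq + 1L); d3 <- nid(is, jsq + 1L)
  tris <- rbind(cbind(a, b, c3), cbind(a, c3, d3))
  stations <- seq(0, H, length.out = max(2L, ceiling(H / edge_length)) + 1L)
  ex <- extrude_triangulation(tris, nrow(pts), stations, function(k) pts)
  bd <- extract_tagged_boundary(ex$vertices, ex$cells, NULL)
  tags <- rep(tg["WALL"], nrow(bd$facets))
  new_tagged_mesh(ex$vertices, ex$cells, bd$facets, tags, edge_length,
                  meta = list(kind = "cavity", dims = dims))
}
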