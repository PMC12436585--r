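#' Boundary tag table
#'
#' Integer codes used for boundary (and valve-plane) facet tags on a
#' [tagged_mesh]. The same codes are persisted in the sidecar JSON written by
#' [write_mesh()].
#'
#' @return Named integer vector mapping tag names to codes.
#' @export
mesh_tags <- function() {
  c(INLET = 1L, OUTLET = 2L, WALL = 3L,
    CORONARY_L = 4L, CORONARY_R = 5L,
    VALVE_ORIFICE = 6L, VALVE_ANNULUS = 7L)
}

#' Construct a tagged mesh object
#'
#' Low-level constructor for the mesh container used throughout the package:
#' an unstructured simplicial mesh (triangles in 2-D planar mode, tetrahedra
#' in 3-D) with labelled boundary facets and, optionally, an interior valve
#' plane. Users normally obtain meshes from [build_root_mesh()] or
#' [build_fixture_mesh()] rather than calling this directly.
#'
#' @param vertices numeric matrix (n x d) of vertex coordinates in mm.
#' @param cells integer matrix (m x (d+1)) of cell vertex indices.
#' @param facets integer matrix of boundary facet vertex indices
#'   (edges in 2-D, triangles in 3-D).
#' @param facet_tags integer vector of tags (see [mesh_tags()]), one per facet.
#' @param h target characteristic edge length (mm).
#' @param axis unit vector giving the axial (streamwise) direction.
#' @param origin point on the inlet plane from which axial coordinates are
#'   measured.
#' @param valve optional list describing the valve plane (station, GOA, node
#'   sets, interior facets).
#' @param stations numeric vector of axial stations at which the structured
#'   generator placed vertex layers.
#' @param layer_weights list of per-station lumped cross-section weights.
#' @param meta free-form provenance list (parameters, seed, scenario).
#' @return An object of class `tagged_mesh`.
#' @keywords internal
new_tagged_mesh <- function(vertices, cells, facets, facet_tags, h,
                            axis = NULL, origin = NULL, valve = NULL,
                            stations = NULL, layer_weights = NULL,
                            meta = list()) {
  d <- ncol(vertices)
  stopifnot(d %in% c(2L, 3L), ncol(cells) == d + 1L, ncol(facets) == d)
  if (is.null(axis)) axis <- c(rep(0, d - 1L), 1)
  if (is.null(origin)) origin <- rep(0, d)
  m <- structure(list(
    vertices = vertices, cells = cells, dim = d,
    facets = facets, facet_tags = as.integer(facet_tags),
    h = h, axis = axis / sqrt(sum(axis^2)), origin = origin,
    valve = valve, stations = stations, layer_weights = layer_weights,
    meta = meta), class = "tagged_mesh")
  m <- orient_cells(m)
  m
}

#' @export
print.tagged_mesh <- function(x, ...) {
  tg <- mesh_tags()
  cnt <- vapply(tg, function(tt) sum(x$facet_tags == tt), integer(1))
  cat(sprintf("<tagged_mesh> %d-D, %d vertices, %d cells, %d boundary facets (h = %g mm)\n",
              x$dim, nrow(x$vertices), nrow(x$cells), nrow(x$facets), x$h))
  cat("  tags:", paste(sprintf("%s=%d", names(cnt)[cnt > 0], cnt[cnt > 0]),
                       collapse = ", "), "\n")
  if (!is.null(x$valve))
    cat(sprintf("  valve plane at s = %g mm, GOA diameter %g mm (%d orifice / %d annulus nodes)\n",
                x$valve$station, x$valve$goa_diameter,
                length(x$valve$orifice_nodes), length(x$valve$annulus_nodes)))
  invisible(x)
}

## ---- measures, normals, census ------------------------------------------

#' Signed cell measures (areas in 2-D, volumes in 3-D)
#' @keywords internal
cell_measures_signed <- function(vertices, cells) {
  d <- ncol(vertices)
  if (d == 2L) {
    a <- vertices[cells[, 1], , drop = FALSE]
    b <- vertices[cells[, 2], , drop = FALSE]
    c3 <- vertices[cells[, 3], , drop = FALSE]
    0.5 * ((b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  } else {
    a <- vertices[cells[, 1], , drop = FALSE]
    u <- vertices[cells[, 2], , drop = FALSE] - a
    v <- vertices[cells[, 3], , drop = FALSE] - a
    w <- vertices[cells[, 4], , drop = FALSE] - a
    (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
}

#' Flip cells so every measure is positive
#' @keywords internal
orient_cells <- function(mesh) {
  s <- cell_measures_signed(mesh$vertices, mesh$cells)
  neg <- which(s < 0)
  if (length(neg)) {
    tmp <- mesh$cells[neg, 1L]
    mesh$cells[neg, 1L] <- mesh$cells[neg, 2L]
    mesh$cells[neg, 2L] <- tmp
  }
  mesh
}

#' Cell measures of a mesh
#' @param mesh a [tagged_mesh].
#' @return numeric vector of cell areas (mm^2) or volumes (mm^3).
#' @export
cell_measures <- function(mesh) {
  abs(cell_measures_signed(mesh$vertices, mesh$cells))
}

#' Total lumen measure of a mesh
#' @param mesh a [tagged_mesh].
#' @return total area (2-D) or volume (3-D).
#' @export
mesh_volume <- function(mesh) sum(cell_measures(mesh))

#' Facet measures (edge lengths in 2-D, triangle areas in 3-D)
#' @keywords internal
facet_measures <- function(vertices, facets) {
  d <- ncol(vertices)
  if (d == 2L) {
    e <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    sqrt(rowSums(e^2))
  } else {
    u <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    v <- vertices[facets[, 3], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
}

## Enumerate the (d-1)-faces of every cell. Returns the face vertex matrix
## (one row per cell-face incidence), the owning cell, and a census of how
## many cells share each distinct face.
face_census <- function(cells, d) {
  nf <- d + 1L                                  # faces per cell
  m <- nrow(cells)
  faces <- vector("list", nf)
  for (k in seq_len(nf)) faces[[k]] <- cells[, -k, drop = FALSE]
  faces <- do.call(rbind, faces)
  owner <- rep(seq_len(m), times = nf)
  base <- max(cells) + 1
  key <- face_keys(faces, base)
  u <- match(key, key)                          # representative index
  cnt <- tabulate(u, nbins = length(key))
  list(faces = faces, key = key, owner = owner, count = cnt[u],
       base = base)
}

## Collision-free numeric key for a (sorted) face: polynomial in `base`
## (one more than the largest vertex index); exact in doubles for meshes up
## to ~1e5 vertices. The same base must be used for keys to be comparable.
face_keys <- function(faces, base = max(faces) + 1) {
  d <- ncol(faces)
  if (d == 2L) {
    a <- pmin(faces[, 1], faces[, 2]); b <- pmax(faces[, 1], faces[, 2])
    a * base + b
  } else {
    a <- pmin(faces[, 1], faces[, 2], faces[, 3])
    c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
    b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c3
    (a * base + b) * base + c3
  }
}

#' Outward unit normals of boundary facets
#'
#' @param mesh a [tagged_mesh].
#' @param facets facet matrix (defaults to the mesh boundary facets).
#' @param owner_cells owning cell per facet; found by census when missing.
#' @return matrix of outward unit normals, one row per facet.
#' @keywords internal
facet_normals <- function(mesh, facets = mesh$facets, owner_cells = NULL) {
  V <- mesh$vertices; d <- mesh$dim
  if (is.null(owner_cells)) {
    cen <- face_census(mesh$cells, d)
    idx <- match(face_keys(facets, cen$base), cen$key)
    owner_cells <- cen$owner[idx]
  }
  if (d == 2L) {
    e <- V[facets[, 2], , drop = FALSE] - V[facets[, 1], , drop = FALSE]
    n <- cbind(e[, 2], -e[, 1])
  } else {
    u <- V[facets[, 2], , drop = FALSE] - V[facets[, 1], , drop = FALSE]
    v <- V[facets[, 3], , drop = FALSE] - V[facets[, 1], , drop = FALSE]
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n <- n / sqrt(rowSums(n^2))
  fc <- facet_centroids(V, facets)
  cc <- cell_centroids(V, mesh$cells)[owner_cells, , drop = FALSE]
  flip <- rowSums(n * (fc - cc)) < 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  n
}

facet_centroids <- function(vertices, facets) {
  d <- ncol(facets)
  out <- vertices[facets[, 1], , drop = FALSE]
  for (k in 2:d) out <- out + vertices[facets[, k], , drop = FALSE]
  out / d
}

cell_centroids <- function(vertices, cells) {
  d1 <- ncol(cells)
  out <- vertices[cells[, 1], , drop = FALSE]
  for (k in 2:d1) out <- out + vertices[cells[, k], , drop = FALSE]
  out / d1
}

## ---- axial geometry helpers ---------------------------------------------

#' Axial coordinate of points (distance along the mesh axis from the origin)
#' @param mesh a [tagged_mesh].
#' @param points coordinate matrix; defaults to the mesh vertices.
#' @return numeric vector of axial coordinates (mm).
#' @export
axial_coord <- function(mesh, points = mesh$vertices) {
  drop((points - matrix(mesh$origin, nrow(points), mesh$dim, byrow = TRUE)) %*% mesh$axis)
}

#' Radial distance of points from the mesh axis
#' @keywords internal
radial_coord <- function(mesh, points = mesh$vertices) {
  s <- axial_coord(mesh, points)
  foot <- matrix(mesh$origin, nrow(points), mesh$dim, byrow = TRUE) +
    outer(s, mesh$axis)
  sqrt(rowSums((points - foot)^2))
}

#' Vertex ids lying on an axial station
#' @param mesh a [tagged_mesh].
#' @param s axial coordinate of the plane (mm).
#' @param tol matching tolerance; defaults to a small fraction of `h`.
#' @return integer vector of vertex ids.
#' @export
section_nodes <- function(mesh, s, tol = 1e-6 * max(1, mesh$h)) {
  which(abs(axial_coord(mesh) - s) <= tol)
}

## Lumped cross-section weights at a station: taken from the generator's
## stored layer table when available, otherwise uniform over matched nodes.
section_weights <- function(mesh, s) {
  if (!is.null(mesh$stations)) {
    k <- which(abs(mesh$stations - s) <= 1e-6 * max(1, mesh$h))
    if (length(k) == 1L && !is.null(mesh$layer_weights))
      return(mesh$layer_weights[[k]])
  }
  ids <- section_nodes(mesh, s)
  if (!length(ids)) stop("no vertex layer at axial station s = ", s)
  list(nodes = ids, w = rep(1 / length(ids), length(ids)))
}

#' Area-averaged value of a nodal field over a cross-section plane
#'
#' @param mesh a [tagged_mesh] built by the structured generator.
#' @param s axial station of the plane (mm).
#' @param values nodal scalar field.
#' @return weighted average of `values` over the plane.
#' @export
section_average <- function(mesh, s, values) {
  lw <- section_weights(mesh, s)
  sum(lw$w * values[lw$nodes]) / sum(lw$w)
}

#' Flux of a vector field through a cross-section plane
#'
#' Integrates the axial velocity component over the plane using the
#' generator's lumped cross-section weights (length in 2-D planar mode, area
#' in 3-D), giving mm^2/s in 2-D and mm^3/s in 3-D.
#'
#' @param mesh a [tagged_mesh].
#' @param s axial station (mm).
#' @param U nodal velocity matrix (n x d), mm/s.
#' @return net flux in the +axis direction.
#' @export
section_flux <- function(mesh, s, U) {
  lw <- section_weights(mesh, s)
  ua <- drop(U[lw$nodes, , drop = FALSE] %*% mesh$axis)
  sum(lw$w * ua)
}

#' Flux of a vector field through tagged boundary facets
#'
#' Exact P1 facet quadrature of `u . n` (outward normal), summed over all
#' facets carrying `tag`.
#'
#' @param mesh a [tagged_mesh].
#' @param U nodal velocity matrix (n x d).
#' @param tag tag name (see [mesh_tags()]) or integer code; may be a vector.
#' @return outward flux (mm^2/s in 2-D, mm^3/s in 3-D).
#' @export
boundary_flux <- function(mesh, U, tag) {
  codes <- tag_codes(tag)
  sel <- mesh$facet_tags %in% codes
  if (!any(sel)) return(0)
  f <- mesh$facets[sel, , drop = FALSE]
  n <- facet_normals(mesh)[sel, , drop = FALSE]
  a <- facet_measures(mesh$vertices, f)
  un <- 0
  for (k in seq_len(mesh$dim))
    un <- un + rowMeans(matrix(U[f, k], nrow(f), mesh$dim)) * n[, k]
  sum(a * un)
}

tag_codes <- function(tag) {
  tg <- mesh_tags()
  if (is.character(tag)) {
    bad <- setdiff(tag, names(tg))
    if (length(bad)) stop("unknown tag(s): ", paste(bad, collapse = ", "))
    unname(tg[tag])
  } else as.integer(tag)
}

#' Vertex ids on facets carrying given tags
#' @param mesh a [tagged_mesh].
#' @param tag tag names or codes.
#' @return sorted integer vector of vertex ids.
#' @export
boundary_nodes <- function(mesh, tag) {
  codes <- tag_codes(tag)
  sort(unique(as.vector(mesh$facets[mesh$facet_tags %in% codes, , drop = FALSE])))
}

#' Rigidly rotate a mesh (and optionally a vector field) about a point
#'
#' Rotates vertices, axis, origin and valve-plane metadata consistently, so
#' that axial selections and plane averages remain meaningful after rotation.
#'
#' @param mesh a [tagged_mesh].
#' @param R orthonormal d x d rotation matrix.
#' @param center point about which to rotate (defaults to the origin).
#' @return the rotated mesh.
#' @export
rotate_mesh <- function(mesh, R, center = rep(0, mesh$dim)) {
  stopifnot(nrow(R) == mesh$dim, max(abs(crossprod(R) - diag(mesh$dim))) < 1e-10)
  rot <- function(X) sweep(sweep(X, 2L, center) %*% t(R), 2L, -center)
  mesh$vertices <- rot(mesh$vertices)
  mesh$origin <- drop(rot(matrix(mesh$origin, 1L)))
  mesh$axis <- drop(mesh$axis %*% t(R))
  mesh
}

## ---- validity -----------------------------------------------------------

#' Validate a tagged mesh
#'
#' Checks the structural invariants every generated mesh must satisfy: all
#' cell measures positive, the mesh is watertight (each interior face shared
#' by exactly two cells, each boundary face by one), every boundary facet
#' carries exactly one tag, and the valve plane (when present) forms a single
#' planar cross-section.
#'
#' @param mesh a [tagged_mesh].
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tagged_mesh"))
  meas <- cell_measures_signed(mesh$vertices, mesh$cells)
  if (any(meas <= 0)) stop("mesh has non-positive cell measures")
  cen <- face_census(mesh$cells, mesh$dim)
  if (any(cen$count > 2L)) stop("mesh is not manifold: a face is shared by > 2 cells")
  bnd <- unique(cen$key[cen$count == 1L])
  fkey <- face_keys(mesh$facets, cen$base)
  if (anyDuplicated(fkey)) stop("a boundary facet carries more than one tag")
  if (!setequal(bnd, fkey))
    stop("boundary facets do not match the cell adjacency census (mesh not watertight)")
  if (length(mesh$facet_tags) != nrow(mesh$facets))
    stop("facet_tags length mismatch")
  if (!is.null(mesh$valve)) {
    s <- axial_coord(mesh)
    vf <- mesh$valve$facets
    if (!is.null(vf) && nrow(vf)) {
      svals <- s[as.vector(vf)]
      if (diff(range(svals)) > 1e-6 * max(1, mesh$h))
        stop("valve-plane facets are not coplanar")
      ikey <- face_keys(vf, cen$base)
      if (any(!ikey %in% cen$key[cen$count == 2L]))
        stop("valve-plane facets must be interior faces")
    }
  }
  invisible(TRUE)
}
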