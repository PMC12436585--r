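## Plain-text mesh and field I/O: Gmsh MSH 4.1 and VTK XML (VTU), with a
## JSON sidecar persisting the tag table and generator metadata.

#' Write a mesh to disk
#'
#' Writes Gmsh MSH 4.1 (`.msh`) or VTK unstructured-grid XML (`.vtu`,
#' ASCII), chosen by file extension. Boundary facets are written as
#' lower-dimensional elements carrying their integer tag; a sidecar
#' `<path>.json` records the tag-name table, axis/origin, stations, valve
#' plane and generator metadata so [read_mesh()] can reconstruct the full
#' object.
#'
#' @param mesh a [tagged_mesh].
#' @param path output path ending in `.msh` or `.vtu`.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, sidecar = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") write_msh(mesh, path)
  else if (ext == "vtu") write_vtu(mesh, path)
  else stop("write_mesh: unsupported extension '", ext, "'")
  if (sidecar) {
    meta <- list(
      format = "rootflow-tagged-mesh", version = 1L,
      dim = mesh$dim, h = mesh$h,
      tag_table = as.list(mesh_tags()),
      axis = mesh$axis, origin = mesh$origin,
      stations = mesh$stations,
      layer_weights = mesh$layer_weights,
      valve = if (is.null(mesh$valve)) NULL else list(
        station = mesh$valve$station,
        goa_diameter = mesh$valve$goa_diameter,
        plane_nodes = mesh$valve$plane_nodes,
        orifice_nodes = mesh$valve$orifice_nodes,
        annulus_nodes = mesh$valve$annulus_nodes,
        closed_nodes = mesh$valve$closed_nodes,
        insert_wall_nodes = mesh$valve$insert_wall_nodes,
        facets = mesh$valve$facets,
        facet_tags = mesh$valve$facet_tags),
      meta = mesh$meta[setdiff(names(mesh$meta), "params")],
      seed = mesh$meta$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

write_msh <- function(mesh, path) {
  d <- mesh$dim
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  tg <- mesh_tags()
  w("$PhysicalNames"); w("%d", length(tg) + 1L)
  for (k in seq_along(tg)) w('%d %d "%s"', d - 1L, tg[[k]], names(tg)[k])
  w('%d %d "%s"', d, 100L, "LUMEN")
  w("$EndPhysicalNames")
  nn <- nrow(mesh$vertices)
  coords <- cbind(mesh$vertices, matrix(0, nn, 3L - d))
  w("$Nodes")
  w("1 %d 1 %d", nn, nn)
  w("%d 1 0 %d", d, nn)
  writeLines(as.character(seq_len(nn)), con)
  writeLines(sprintf("%.17g %.17g %.17g", coords[, 1], coords[, 2], coords[, 3]), con)
  w("$EndNodes")
  ## element blocks: one per boundary tag present, then the cells
  ftype <- if (d == 2L) 1L else 2L    # line / triangle
  ctype <- if (d == 2L) 2L else 4L    # triangle / tetrahedron
  tags_present <- sort(unique(mesh$facet_tags))
  nblocks <- length(tags_present) + 1L
  ntot <- nrow(mesh$facets) + nrow(mesh$cells)
  w("$Elements")
  w("%d %d 1 %d", nblocks, ntot, ntot)
  eid <- 0L
  for (tt in tags_present) {
    f <- mesh$facets[mesh$facet_tags == tt, , drop = FALSE]
    w("%d %d %d %d", d - 1L, tt, ftype, nrow(f))
    lines <- apply(cbind(eid + seq_len(nrow(f)), f), 1L, paste, collapse = " ")
    writeLines(lines, con)
    eid <- eid + nrow(f)
  }
  w("%d %d %d %d", d, 100L, ctype, nrow(mesh$cells))
  lines <- apply(cbind(eid + seq_len(nrow(mesh$cells)), mesh$cells), 1L,
                 paste, collapse = " ")
  writeLines(lines, con)
  w("$EndElements")
}

#' Read a mesh written by [write_mesh()]
#'
#' Parses the MSH 4.1 file and, when the JSON sidecar is present, restores
#' the axis, stations, layer weights and valve-plane metadata.
#'
#' @param path path to a `.msh` file.
#' @return A [tagged_mesh].
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("read_mesh: missing section ", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nd <- sect("Nodes")
  hdr <- as.numeric(strsplit(nd[1], " ")[[1]])
  nn <- hdr[2]
  blk <- as.numeric(strsplit(nd[2], " ")[[1]])
  dim <- blk[1]
  coords <- do.call(rbind, lapply(nd[2 + nn + seq_len(nn)], function(s)
    as.numeric(strsplit(s, " ")[[1]])))
  vertices <- coords[, seq_len(dim), drop = FALSE]
  el <- sect("Elements")
  nblocks <- as.numeric(strsplit(el[1], " ")[[1]])[1]
  pos <- 2L
  facets <- NULL; ftags <- integer(0); cells <- NULL
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(el[pos], " ")[[1]])
    edim <- bh[1]; etag <- bh[2]; nel <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(nel)], function(s)
      as.integer(strsplit(s, " ")[[1]][-1])))
    if (edim == dim) cells <- rbind(cells, rows)
    else { facets <- rbind(facets, rows); ftags <- c(ftags, rep(etag, nel)) }
    pos <- pos + nel + 1L
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else NULL
  valve <- NULL; stations <- NULL; lw <- NULL
  axis <- NULL; origin <- NULL; h <- NA_real_
  if (!is.null(meta)) {
    h <- meta$h; axis <- meta$axis; origin <- meta$origin
    stations <- meta$stations
    if (!is.null(meta$layer_weights))
      lw <- lapply(meta$layer_weights, function(x)
        list(nodes = as.integer(x$nodes), w = as.numeric(x$w)))
    if (!is.null(meta$valve))
      valve <- list(station = meta$valve$station,
                    goa_diameter = meta$valve$goa_diameter,
                    plane_nodes = as.integer(meta$valve$plane_nodes),
                    orifice_nodes = as.integer(meta$valve$orifice_nodes),
                    annulus_nodes = as.integer(meta$valve$annulus_nodes),
                    closed_nodes = as.integer(meta$valve$closed_nodes),
                    insert_wall_nodes = as.integer(meta$valve$insert_wall_nodes),
                    facets = matrix(as.integer(meta$valve$facets),
                                    ncol = dim),
                    facet_tags = as.integer(meta$valve$facet_tags),
                    spec = NULL)
  }
  new_tagged_mesh(vertices, cells, facets, ftags,
                  h = if (is.na(h)) stats::median(facet_measures(vertices, facets)) else h,
                  axis = axis, origin = origin, valve = valve,
                  stations = stations, layer_weights = lw,
                  meta = list(kind = "read", source = path))
}

#' Write a mesh with nodal fields as VTK XML (VTU, ASCII)
#'
#' @param mesh a [tagged_mesh].
#' @param path output `.vtu` path.
#' @param point_data named list of nodal fields: vectors (scalars) or
#'   matrices (vectors, padded to 3 components).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  d <- mesh$dim
  nn <- nrow(mesh$vertices); ncl <- nrow(mesh$cells)
  coords <- cbind(mesh$vertices, matrix(0, nn, 3L - d))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ncl)
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val)) {
        val3 <- cbind(val, matrix(0, nrow(val), 3L - ncol(val)))
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
        writeLines(apply(val3, 1L, num), con)
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(num(val), con)
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(coords, 1L, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$cells - 1L, 1L, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ncl) * (d + 1L), collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(if (d == 2L) 5L else 10L, ncl), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
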