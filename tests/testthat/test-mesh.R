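test_that("generated meshes are watertight with single-tagged boundaries", {
  meshes <- list(
    build_fixture_mesh("CHANNEL", c(8, 2), 0.5),
    build_fixture_mesh("PIPE", c(1.5, 8), 0.7),
    build_fixture_mesh("CAVITY", c(3, 3, 3), 1),
    build_root_mesh(root_parameters(), 2.5, "2d"))
  for (m in meshes) expect_true(check_mesh(m))
  ## corrupting a facet tag table must be caught
  bad <- meshes[[1]]
  bad$facets <- rbind(bad$facets, bad$facets[1, ])
  bad$facet_tags <- c(bad$facet_tags, bad$facet_tags[1])
  expect_error(check_mesh(bad), "more than one tag")
})

test_that("section and boundary integrals reproduce linear closed forms", {
  m <- build_fixture_mesh("CHANNEL", c(10, 2), 0.25)
  n <- nrow(m$vertices)
  ## uniform axial flow U: section flux = U * width, boundary flux closes
  U <- matrix(0, n, 2); U[, 2] <- 3
  expect_equal(section_flux(m, 5, U), 3 * 2, tolerance = 1e-12)
  expect_equal(boundary_flux(m, U, "OUTLET"), 6, tolerance = 1e-12)
  expect_equal(boundary_flux(m, U, "INLET"), -6, tolerance = 1e-12)
  ## linear pressure field: plane average equals midpoint value
  p <- 5 + 2 * m$vertices[, 2] + 0.5 * m$vertices[, 1]
  expect_equal(section_average(m, 4, p), 5 + 8, tolerance = 1e-12)
})

test_that("rigid rotation preserves measures and axial bookkeeping", {
  m <- build_fixture_mesh("CHANNEL", c(10, 2), 0.5)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mr <- rotate_mesh(m, R)
  expect_equal(sum(cell_measures(mr)), sum(cell_measures(m)), tolerance = 1e-12)
  expect_equal(axial_coord(mr), axial_coord(m), tolerance = 1e-9)
})

test_that("MSH round trip preserves geometry, tags and valve metadata", {
  m <- build_root_mesh(root_parameters(), 2.5, "2d")
  f <- file.path(tempdir(), "roundtrip.msh")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(nrow(m2$cells), nrow(m$cells))
  expect_identical(sort(table(m2$facet_tags)), sort(table(m$facet_tags)))
  expect_equal(m2$valve$goa_diameter, m$valve$goa_diameter)
  expect_setequal(m2$valve$plane_nodes, m$valve$plane_nodes)
  expect_true(check_mesh(m2))
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-12)
})

test_that("VTU output is well-formed XML with matching counts", {
  m <- build_fixture_mesh("CHANNEL", c(4, 2), 0.5)
  f <- file.path(tempdir(), "fields.vtu")
  vel <- matrix(1, nrow(m$vertices), 2)
  write_vtu(m, f, point_data = list(velocity = vel,
                                    pressure = rep(2, nrow(m$vertices))))
  doc <- xml2::read_xml(f)
  piece <- xml2::xml_find_first(doc, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(m$vertices))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(m$cells))
  arrays <- xml2::xml_find_all(doc, "//PointData/DataArray")
  expect_setequal(xml2::xml_attr(arrays, "Name"), c("velocity", "pressure"))
})
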