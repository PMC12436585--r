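test_that("root parameter invariants are enforced", {
  expect_error(root_parameters(annulus_diameter = -1), "positive")
  expect_error(root_parameters(aorta_length = 25), "30 mm")
  expect_error(root_parameters(enlargement_factor = 2.5), "\\[1, 2\\]")
  expect_error(root_parameters(stj_diameter = 45), "sinus")
  expect_error(funnel_insert(15, 17), "smaller")
  expect_error(funnel_insert(15, -1), "positive")
})

test_that("degenerate mesh resolution is rejected", {
  p <- root_parameters()
  expect_error(build_root_mesh(p, p$annulus_diameter, "2d"), "edge_length")
  expect_error(build_root_mesh(p, 6, "2d"), "edge_length")
})

test_that("2-D root mesh matches the analytic profile area", {
  p <- root_parameters()
  m <- build_root_mesh(p, 1.5, "2d")
  expect_true(check_mesh(m))
  zs <- rootflow:::root_breakpoints(p)
  a_exact <- stats::integrate(function(s) 2 * root_radius(p, s),
                              0, zs[["outlet"]], subdivisions = 2000)$value
  expect_lt(abs(mesh_volume(m) - a_exact) / a_exact, 0.05)
})

test_that("3-D root mesh matches the analytic revolved volume", {
  p <- root_parameters()
  m <- build_root_mesh(p, 3, "3d")
  expect_true(check_mesh(m))
  zs <- rootflow:::root_breakpoints(p)
  area_fun <- Vectorize(function(s) {
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    pi * mean(root_radius(p, rep(s, length(th)), th)^2)
  })
  v_exact <- stats::integrate(area_fun, 0, zs[["outlet"]],
                              subdivisions = 500)$value
  expect_lt(abs(mesh_volume(m) - v_exact) / v_exact, 0.05)
})

test_that("lumen volume grows with the enlargement factor and shrinks with the insert", {
  vols <- vapply(c(1, 1.1, 1.26), function(ef) {
    p <- root_parameters(enlargement_factor = ef)
    mesh_volume(build_root_mesh(p, 2, "2d"))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
  p0 <- root_parameters()
  pt <- p0
  pt$tavr_insert <- funnel_insert(21, 15.2)
  v0 <- mesh_volume(build_root_mesh(p0, 2, "2d"))
  vt <- mesh_volume(build_root_mesh(pt, 2, "2d"))
  expect_lt(vt, v0)
})

test_that("mesh generation is deterministic for identical parameters", {
  p <- root_parameters()
  m1 <- build_root_mesh(p, 2, "2d", seed = 7L)
  m2 <- build_root_mesh(p, 2, "2d", seed = 7L)
  expect_identical(dim(m1$vertices), dim(m2$vertices))
  expect_identical(dim(m1$cells), dim(m2$cells))
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$cells, m2$cells)
})

test_that("scenarios transform the parameters as specified", {
  p <- root_parameters(annulus_diameter = 23)
  v23 <- valve_spec(23); v29 <- valve_spec(29)
  expect_identical(apply_scenario(p, "BASELINE", v23), p)
  py <- apply_scenario(p, "YAAE", v29)
  expect_equal(py$enlargement_factor, 29 / 23)
  p_low <- p; p_low$enlargement_factor <- 1.05
  expect_warning(apply_scenario(p_low, "YAAE", v29), "ratio")
  pt <- apply_scenario(p, "TAVR_IN_SAVR", v23, goa_area_reduction = 0.20)
  expect_equal(pt$tavr_insert$throat_diameter, 17 * sqrt(0.8))
  ## GOA area reduced by exactly the requested fraction
  a_pre <- pi * 17^2 / 4
  a_post <- pi * pt$tavr_insert$throat_diameter^2 / 4
  expect_equal(a_post / a_pre, 0.8, tolerance = 1e-12)
  expect_error(apply_scenario(p, "YAAE", valve_spec(20)), "larger")
})

test_that("fixture meshes have the advertised tag structure", {
  tg <- mesh_tags()
  pp <- build_fixture_mesh("PIPE", c(2, 20), 0.9)
  expect_true(check_mesh(pp))
  expect_setequal(unique(pp$facet_tags),
                  unname(tg[c("INLET", "OUTLET", "WALL")]))
  cv <- build_fixture_mesh("CAVITY", c(5, 5), 1)
  expect_true(all(cv$facet_tags == tg[["WALL"]]))
  expect_error(build_fixture_mesh("PIPE", c(-1, 5), 0.5), "positive")
})

test_that("channel boundary facet count matches a brute-force edge census", {
  m <- build_fixture_mesh("CHANNEL", c(10, 2), 0.25)
  ## independent recount: enumerate all cell edges, boundary = seen once
  edges <- rbind(m$cells[, c(1, 2)], m$cells[, c(2, 3)], m$cells[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_identical(nrow(m$facets), sum(table(key) == 1L))
})

test_that("the valve orifice is snapped to the GOA", {
  p <- root_parameters()
  m2 <- build_root_mesh(p, 2, "2d")
  tg <- mesh_tags()
  open_w <- sum(rootflow:::facet_measures(m2$vertices, m2$valve$facets)[
    m2$valve$facet_tags == tg[["VALVE_ORIFICE"]]])
  expect_equal(open_w, m2$valve$goa_diameter, tolerance = 1e-9)
  m3 <- build_root_mesh(p, 3, "3d")
  open_a <- sum(rootflow:::facet_measures(m3$vertices, m3$valve$facets)[
    m3$valve$facet_tags == tg[["VALVE_ORIFICE"]]])
  goa_a <- pi * m3$valve$goa_diameter^2 / 4
  one_facet <- max(rootflow:::facet_measures(m3$vertices, m3$valve$facets))
  expect_lt(abs(open_a - goa_a), max(one_facet, 0.05 * goa_a))
})
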