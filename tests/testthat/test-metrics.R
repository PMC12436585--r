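## Fabricate a minimal flow_history around prescribed fields, so metric
## conventions can be tested against hand-computable cases.
fake_history <- function(mesh, U, p_in, p_30, Q_valve = 1) {
  vmag <- sqrt(rowSums(U^2))
  sax <- axial_coord(mesh)
  vs <- if (!is.null(mesh$valve)) mesh$valve$station else 0
  down <- sax > vs & sax <= vs + 30
  structure(list(
    series = data.frame(t = 1, cycle = 1, Q_valve = Q_valve,
                        p_in = p_in, p_30 = p_30,
                        vmax_down = max(vmag[down])),
    snapshots = list(U), snapshot_times = 1,
    valve_station = vs, period = 1, dt = 1), class = "flow_history")
}

test_that("peak velocity conventions: uniform field, zero flow, jet bound", {
  m <- build_fixture_mesh("CHANNEL", c(40, 10), 1)
  n <- nrow(m$vertices)
  U <- matrix(0, n, 2); U[, 2] <- 123
  h <- fake_history(m, U, 0, 0)
  expect_equal(peak_velocity(h, m), 123)
  expect_equal(peak_velocity(fake_history(m, 0 * U, 0, 0), m), 0)
  ## continuity bound on the real run: peak >= max transvalvular flux / GOA
  res <- rf_baseline()
  s <- res$history$series
  bound <- max(s$Q_valve) / res$mesh$valve$goa_diameter
  expect_gte(peak_velocity(res$history, res$mesh), 0.95 * bound)
})

test_that("mean TPG conventions: gauge shift, sign clamp, uniform field", {
  m <- build_fixture_mesh("CHANNEL", c(40, 10), 1)
  n <- nrow(m$vertices)
  U <- matrix(0, n, 2)
  expect_equal(mean_tpg(fake_history(m, U, 500, 500), m), 0)
  ## positive-part convention: adverse (reversed) gradient reports zero
  expect_equal(mean_tpg(fake_history(m, U, 100, 400), m), 0)
  h1 <- fake_history(m, U, 700, 400)
  expect_equal(mean_tpg(h1, m), 300)
  ## invariant under a constant pressure offset
  h2 <- fake_history(m, U, 700 + 12345, 400 + 12345)
  expect_equal(mean_tpg(h2, m), mean_tpg(h1, m))
  ## mmHg conversion
  expect_equal(mean_tpg(h1, m, in_mmHg = TRUE), 300 / 133.322)
})

test_that("peak velocity is invariant under rigid rotation", {
  res <- rf_baseline()
  m <- res$mesh; h <- res$history
  pv0 <- peak_velocity(h, m, region = "all")
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mr <- rotate_mesh(m, R)
  hr <- h
  hr$snapshots <- lapply(h$snapshots, function(u) u %*% t(R))
  expect_equal(peak_velocity(hr, mr, region = "all"), pv0, tolerance = 1e-9)
})

test_that("residence-time statistics match a brute-force per-cell oracle", {
  m <- build_fixture_mesh("CAVITY", c(4, 3), 0.8)
  set.seed(42)
  rel <- runif(nrow(m$vertices))
  rt <- rt_field(rel, 1)
  st <- rt_stats(rt, m)
  ## oracle: loop cells, accumulate V/3 per vertex
  w <- numeric(nrow(m$vertices))
  meas <- cell_measures(m)
  for (e in seq_len(nrow(m$cells)))
    for (j in 1:3) w[m$cells[e, j]] <- w[m$cells[e, j]] + meas[e] / 3
  expect_equal(st$rt_mean, sum(w * rel) / sum(w), tolerance = 1e-12)
  expect_equal(st$rt_max, max(rel))
  expect_equal(st$pct_vol_rt_gt_02, 100 * sum(w[rel > 0.2]) / sum(w),
               tolerance = 1e-12)
  expect_lte(st$rt_mean, st$rt_max)
  ## threshold degenerate case: nothing above 0.2 when the max is below it
  st0 <- rt_stats(rt_field(rep(0.1, nrow(m$vertices)), 1), m)
  expect_equal(st0$pct_vol_rt_gt_02, 0)
})

test_that("percent change follows the clinical decrease convention", {
  expect_equal(percent_change(0.6, 1.0), 40)
  expect_equal(percent_change(1.0, 1.0), 0)
  expect_equal(percent_change(1.2, 1.0), -20)
  expect_error(percent_change(1, 0), "nonzero")
})

test_that("group normalization maps the maximum to exactly one", {
  expect_equal(group_normalize(c(2, 4)), c(0.5, 1.0))
  expect_equal(group_normalize(7), 1.0)
  set.seed(7)
  for (i in 1:5) {
    v <- runif(6, 0.1, 10)
    expect_identical(max(group_normalize(v)), 1)
  }
  expect_error(group_normalize(c(0, 0)), "positive")
  expect_error(group_normalize(numeric(0)), "empty")
})

test_that("scenario comparison tables are consistent", {
  res <- rf_baseline()
  r1 <- res$report
  r2 <- r1; r2$scenario <- "copy"
  cmp <- compare_scenarios(list(r1, r2), control = r1$scenario)
  expect_true(all(cmp$percent_change$peak_velocity == 0))
  expect_true(all(cmp$normalized$peak_velocity == 1))
  expect_error(compare_scenarios(list(r1, r2), control = "nope"), "control")
  expect_error(compare_scenarios(list(r1), control = r1$scenario), "two")
})
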