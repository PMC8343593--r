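# Gyral-net extraction and 3-hinge detection.

test_that("altitude is zero on planes, signed on waves, translation invariant", {
  flat <- make_surface(fixture_spec("flat", resolution = 0.5))$surface
  a0 <- compute_altitude(flat)
  expect_lt(max(abs(a0)), 1e-9)
  ## z = sin sheet: with a midsurface much smoother than the wave, the
  ## altitude sign matches the wave's sign away from the rim, and the mean
  ## is zero by construction
  sheet <- make_surface(fixture_spec("flat", L = 40, resolution = 1))$surface
  wave <- sin(2 * pi * sheet$vertices[, 1] / 10)
  sheet$vertices[, 3] <- wave
  cfgs <- detect_config(smooth_length = 15)
  alt <- compute_altitude(sheet, cfgs)
  expect_lt(abs(mean(alt)), 1e-9)
  interior <- sheet$vertices[, 1] > 6 & sheet$vertices[, 1] < 34 &
    sheet$vertices[, 2] > 6 & sheet$vertices[, 2] < 34 & abs(wave) > 0.3
  expect_true(all(sign(alt[interior]) == sign(wave[interior])))
  ## translating the surface leaves the altitude unchanged
  moved <- transform_surface(sheet, t = c(5, -3, 11))
  expect_equal(as.numeric(compute_altitude(moved, cfgs)), as.numeric(alt),
               tolerance = 1e-9)
})

test_that("watershed crest masks honor the altitude level", {
  sheet <- make_surface(fixture_spec("flat", L = 40, resolution = 0.5))$surface
  sheet$vertices[, 3] <- sin(sheet$vertices[, 1])
  alt <- compute_altitude(sheet)
  ## level above the maximum altitude gives an empty mask
  m_hi <- segment_crests(alt, sheet, level = max(alt) + 1)
  expect_equal(sum(m_hi), 0)
  ## level = 0 keeps exactly the non-negative-altitude vertices
  m0 <- segment_crests(alt, sheet, level = 0)
  expect_identical(as.logical(m0), as.numeric(alt) >= 0)
  ## two Gaussian bumps separated by a valley form two components
  two <- make_surface(fixture_spec("multi_y", k = 2, L = 40))$surface
  alt2 <- compute_altitude(two)
  m2 <- segment_crests(alt2, two, level = 0.2)
  net2 <- skeletonize(m2, two, alt2)
  expect_gte(length(unique(net2$component)), 2)
})

test_that("skeletons of ridges are clean paths and Y junctions", {
  ## single straight ridge: one path, no joints
  fx <- make_surface(fixture_spec("single_ridge"))
  rep1 <- detect_hinges(fx$surface)
  deg <- table(factor(c(rep1$net$edges[, "a"], rep1$net$edges[, "b"])))
  expect_equal(rep1$count, 0)
  expect_true(all(deg <= 2))
  ## empty mask yields an empty net
  flat_alt <- compute_altitude(fx$surface)
  empty_net <- skeletonize(
    segment_crests(flat_alt, fx$surface, level = max(flat_alt) + 1),
    fx$surface, flat_alt)
  expect_equal(length(empty_net$vertices), 0)
  expect_equal(length(find_3hinges(empty_net)), 0)
  ## Y junction: exactly one degree-3 joint near the analytic center
  fy <- make_surface(fixture_spec("y_junction"))
  repy <- detect_hinges(fy$surface)
  expect_equal(repy$count, 1)
  ctr <- repy$hinges[[1]]$center_xyz
  mean_edge <- 1 / 1  # resolution 1 -> ~1 mm grid edges
  expect_lt(sqrt(sum((ctr[1:2] - fy$junctions[1, ])^2)), 2 * sqrt(2) * mean_edge)
  ## three spokes recorded with positive lengths and unit directions
  expect_equal(length(repy$hinges[[1]]$spokes), 3)
  expect_true(all(repy$hinges[[1]]$spoke_lengths > 0))
  expect_equal(rowSums(repy$hinges[[1]]$directions^2), rep(1, 3),
               tolerance = 1e-9)
})

test_that("X crossings are higher joints, not 3-hinges", {
  fx <- make_surface(fixture_spec("x_junction"))
  rep <- detect_hinges(fx$surface)
  expect_equal(rep$count, 0)
  expect_equal(nrow(rep$higher_joints), 1)
  expect_gte(rep$higher_joints$degree[1], 4)
})

test_that("multi-Y fixtures are counted exactly", {
  for (k in c(1L, 2L, 5L)) {
    fx <- make_surface(fixture_spec("multi_y", k = k))
    expect_equal(fx$expected_count, k)
    expect_equal(detect_hinges(fx$surface)$count, k)
  }
})

test_that("detection is invariant to rigid motion, scale and subdivision", {
  fx <- make_surface(fixture_spec("y_junction"))
  s <- fx$surface
  base <- detect_hinges(s)
  ## rigid motion: count unchanged, center mapped rigidly
  th <- 0.37
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  t <- c(4, -7, 2)
  moved <- detect_hinges(transform_surface(s, R = R, t = t))
  expect_equal(moved$count, base$count)
  expect_equal(as.numeric(R %*% base$hinges[[1]]$center_xyz + t),
               as.numeric(moved$hinges[[1]]$center_xyz), tolerance = 1e-6)
  ## uniform scaling by 2 (level 0 needs no rescaling)
  expect_equal(detect_hinges(transform_surface(s, scale = 2))$count,
               base$count)
  ## one level of midpoint subdivision
  expect_equal(detect_hinges(subdivide_surface(s))$count, base$count)
  ## determinism of the full pipeline
  again <- detect_hinges(s)
  expect_identical(hinge_centers(again), hinge_centers(base))
})

test_that("hinge reports serialize to JSON", {
  fx <- make_surface(fixture_spec("y_junction"))
  rep <- detect_hinges(fx$surface)
  path <- tempfile(fileext = ".json")
  write_hinge_report(rep, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$count, 1)
  expect_equal(length(unlist(obj$spoke_lengths)), 3)
})
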