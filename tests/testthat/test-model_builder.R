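# Slab construction, perturbation and fiber templates.

test_that("slab meshes honor the requested geometry and partition", {
  mesh <- build_slab(slab_spec())          # 60 x 60 x 50, t = 1.5
  vol_cortex <- sum(mesh$volumes[mesh$region == "cortex"])
  elem_vol <- max(mesh$volumes)
  expect_lt(abs(vol_cortex - 60 * 60 * 1.5), elem_vol + 1e-9)
  expect_true(all(mesh$region %in% c("cortex", "core", "fiber")))
  expect_equal(length(mesh$region), nrow(mesh$conn))  # exactly one label
  expect_true(all(mesh$g == 1))
  expect_true(all(mesh$kind[mesh$region == "cortex"] == "cortical_isotropic"))
  expect_true(all(mesh$kind[mesh$region == "core"] == "none"))
  ## toy spec: structured-grid node count
  toy <- build_slab(slab_spec(10, 10, 5, 1, dx = 1, core_layers = 4L))
  expect_equal(nrow(toy$coords), 11 * 11 * (4 + 2 + 1))
  expect_error(slab_spec(10, 10, 5, 0), "range|positive")
  expect_error(slab_spec(10, 10, 5, 1, cortex_layers = 1L), "2 element")
})

test_that("checkerboard perturbation has the stated closed form", {
  p <- perturbation_spec(A0 = 0.015, omega = 0.5)
  expect_equal(checkerboard_perturbation(c(0, 1, 7), c(0, 2, 3),
                                         perturbation_spec(A0 = 0, omega = 1)),
               c(0, 0, 0))
  expect_equal(checkerboard_perturbation(0, 0, p), 0)
  wq <- pi / 2 / 0.5
  expect_equal(checkerboard_perturbation(wq, wq, p), 2 * 0.015)
  x <- runif(5, 0, 10); y <- runif(5, 0, 10)
  expect_equal(checkerboard_perturbation(x, y, p),
               0.015 * (sin(0.5 * x) + sin(0.5 * y)))
})

test_that("applied perturbations are small, seeded and deterministic", {
  spec <- slab_spec(20, 20, 8, 1.5, dx = 1.5, core_layers = 4L)
  m1 <- apply_perturbation(build_slab(spec), perturbation_spec(seed = 7))
  m1b <- apply_perturbation(build_slab(spec), perturbation_spec(seed = 7))
  m2 <- apply_perturbation(build_slab(spec), perturbation_spec(seed = 8))
  expect_identical(m1$coords, m1b$coords)          # same seed, same mesh
  expect_false(isTRUE(all.equal(m1$coords, m2$coords)))  # different omega
  expect_false(m1$perturbation$omega == m2$perturbation$omega)
  ## amplitude: default A0 = 1% of thickness, offsets bounded by 2 A0
  A0 <- m1$perturbation$A0
  expect_equal(A0, 0.015)
  dz <- m1$coords[m1$sets$top, 3] - build_slab(spec)$coords[m1$sets$top, 3]
  expect_lte(max(abs(dz)), 2 * A0 + 1e-12)
  ## perturbation energy is small: RMS(eps)/t <= 2%
  expect_lte(sqrt(mean(dz^2)) / 1.5, 0.02)
  ## core untouched, interior blended toward the interface
  core_nodes <- which(build_slab(spec)$coords[, 3] < 8 - 1e-9)
  expect_equal(m1$coords[core_nodes, ], build_slab(spec)$coords[core_nodes, ])
})

test_that("fiber templates relabel tube elements with decaying rates", {
  spec <- slab_spec(20, 20, 10, 1.5, dx = 1, core_layers = 5L)
  mesh <- build_slab(spec)
  expect_identical(lay_fibers(mesh, list()), mesh)   # empty template list
  tpl <- y_fiber_template(c(10, 10), length = 8, radius = 1.2)
  m <- lay_fibers(mesh, list(tpl))
  fib <- which(m$region == "fiber")
  expect_gt(length(fib), 0)
  expect_true(all(m$kind[fib] == "fiber_axial"))
  ## region partition still holds
  expect_true(all(m$region %in% c("cortex", "core", "fiber")))
  ## rate = g_axon_max at the junction column, decaying along the spoke
  cx <- rowMeans(matrix(m$coords[m$conn, 1], ncol = 8))
  cy <- rowMeans(matrix(m$coords[m$conn, 2], ncol = 8))
  d_junction <- sqrt((cx - 10)^2 + (cy - 10)^2)
  at_junction <- fib[d_junction[fib] < 0.8]
  expect_true(all(m$rate_scale[at_junction] > 0.85))
  ## monotone non-increasing with arclength along the vertical spoke
  spoke <- fib[abs(cx[fib] - 10) < 0.6 & cy[fib] >= 10]
  ord <- order(cy[spoke])
  rates <- m$rate_scale[spoke][ord]
  agg <- tapply(rates, round(cy[spoke][ord], 3), max)
  expect_true(all(diff(agg) <= 1e-9))
  expect_lt(min(agg), 0.35)             # near zero toward the tip
  ## template outside the footprint errors
  expect_error(lay_fibers(mesh, list(y_fiber_template(c(19, 19), length = 8))),
               "footprint")
})

test_that("volume export writes a readable VTK unstructured grid", {
  mesh <- tiny_slab()
  path <- tempfile(fileext = ".vtk")
  write_volume_vtk(mesh, path)
  lines <- readLines(path)
  expect_true(any(grepl("UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("POINTS %d", nrow(mesh$coords)), lines)))
  expect_true(any(grepl("growth_ratio", lines)))
})
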