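# Surface container, mesh utilities and PLY/OFF/VTK round trips.

test_that("surface construction validates manifoldness and degeneracy", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  f <- rbind(c(1, 2, 3), c(2, 4, 3))
  s <- surface_mesh(V, f)
  expect_s3_class(s, "surface_mesh")
  expect_error(surface_mesh(V, rbind(c(1, 1, 2))), "degenerate")
  ## an edge shared by three triangles is non-manifold
  V5 <- rbind(V, c(0.5, 0.5, 1))
  bad <- rbind(c(1, 2, 3), c(2, 4, 3), c(2, 3, 5), c(3, 2, 1) + c(0, 0, 1))
  expect_error(surface_mesh(V5, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))),
               "non-manifold")
})

test_that("vertex normals point along +z for an upward height field", {
  fx <- make_surface(fixture_spec("single_ridge", resolution = 0.5))
  n <- vertex_normals(fx$surface)
  expect_equal(dim(n), c(nrow(fx$surface$vertices), 3))
  expect_true(all(abs(rowSums(n^2) - 1) < 1e-9))
  expect_true(all(n[, 3] > 0))
})

test_that("midpoint subdivision preserves geometry and quadruples faces", {
  fx <- make_surface(fixture_spec("y_junction", resolution = 0.5))
  s <- fx$surface
  s2 <- subdivide_surface(s)
  expect_equal(nrow(s2$faces), 4 * nrow(s$faces))
  ## original vertices unchanged
  expect_identical(s2$vertices[seq_len(nrow(s$vertices)), ], s$vertices)
  ## total area preserved exactly (flat refinement)
  area <- function(m) {
    a <- m$vertices[m$faces[, 2], ] - m$vertices[m$faces[, 1], ]
    b <- m$vertices[m$faces[, 3], ] - m$vertices[m$faces[, 1], ]
    sum(sqrt(pmax(0, rowSums(a * a) * rowSums(b * b) -
                    rowSums(a * b)^2))) / 2
  }
  expect_equal(area(s2), area(s), tolerance = 1e-9)
})

test_that("PLY, OFF and VTK round trips preserve the mesh", {
  fx <- make_surface(fixture_spec("y_junction", resolution = 0.5))
  s <- fx$surface
  for (ext in c(".ply", ".off", ".vtk")) {
    path <- tempfile(fileext = ext)
    write_surface(s, path)
    r <- read_surface(path)
    expect_lt(max(abs(r$vertices - s$vertices)), 1e-6)
    expect_identical(r$faces, s$faces)
  }
  ## VTK with a scalar field still reads back
  path <- tempfile(fileext = ".vtk")
  write_surface(s, path, scalars = list(z = s$vertices[, 3]))
  r <- read_surface(path)
  expect_equal(nrow(r$vertices), nrow(s$vertices))
})
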