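# Constitutive core: growth kinematics, neo-Hookean energy, Piola stress.

test_that("growth tensors have the stated closed forms and determinants", {
  expect_equal(growth_tensor(growth_state("cortical_isotropic", g = 1)),
               diag(3))
  G <- growth_tensor(growth_state("cortical_isotropic", g = 1.5))
  expect_equal(G, 1.5 * diag(3))
  expect_equal(det(G), 1.5^3)
  Gf <- growth_tensor(growth_state("fiber_axial", g = 1.2,
                                   axis = c(0, 0, 1)))
  expect_equal(Gf, diag(c(1, 1, 1.2)))
  expect_equal(det(Gf), 1.2)
  ## det identities hold exactly for arbitrary axes too
  set.seed(11)
  for (i in 1:20) {
    st <- random_growth()
    d <- det(growth_tensor(st))
    expect_equal(d, if (st$kind == "fiber_axial") st$g else st$g^3,
                 tolerance = 1e-12)
  }
  expect_error(growth_state("fiber_axial", g = 1.1, axis = c(0, 0, 2)),
               "unit vector")
})

test_that("elastic tensor inverts the multiplicative decomposition", {
  G <- growth_tensor(growth_state("cortical_isotropic", g = 1.5))
  expect_equal(elastic_tensor(G, G), diag(3))
  expect_equal(elastic_tensor(diag(3), G), (2 / 3) * diag(3))
  set.seed(21)
  for (i in 1:20) {
    F <- random_deformation()
    G <- growth_tensor(random_growth())
    A <- elastic_tensor(F, G)
    expect_equal(A %*% G, F, tolerance = 1e-12)
    ## and the round trip: elastic_tensor(A G, G) = A
    expect_equal(elastic_tensor(A %*% G, G), A, tolerance = 1e-12)
  }
  expect_error(elastic_tensor(diag(3), matrix(0, 3, 3)), "determinant")
})

test_that("strain energy vanishes at the ground state and under rotation", {
  p <- material_params(mu = 0.5, lam = 1.0)
  expect_equal(strain_energy(diag(3), p), 0)
  ## hand-evaluated closed form for A = diag(1.2, 1, 1)
  a <- 1.2
  W <- strain_energy(diag(c(a, 1, 1)), p)
  expect_equal(W, 0.5 * 1.0 * log(a)^2 + 0.5 * 0.5 * (a^2 - 1 - 2 * log(a)),
               tolerance = 1e-12)
  ## frame indifference: W(Q A) = W(A) for random rotations
  set.seed(31)
  for (i in 1:20) {
    Q <- random_rotation()
    if (det(Q) < 0) Q <- -Q
    A <- random_deformation()
    expect_equal(strain_energy(Q %*% A, p), strain_energy(A, p),
                 tolerance = 1e-10)
    expect_equal(strain_energy(Q, p), 0, tolerance = 1e-12)
  }
  expect_error(strain_energy(diag(c(-1, 1, 1)), p), "determinant")
})

test_that("Piola stress is the exact gradient of the strain energy", {
  p <- material_params()
  set.seed(41)
  for (i in 1:50) {
    F <- random_deformation()
    G <- growth_tensor(random_growth())
    P <- piola_stress(F, G, p)
    Pfd <- fd_piola(F, G, p)
    expect_lt(max(abs(P - Pfd)) / max(abs(P), 1e-8), 1e-6)
  }
})

test_that("stress-free grown states and the uniaxial closed form", {
  p <- material_params()
  set.seed(51)
  for (i in 1:10) {
    G <- growth_tensor(random_growth())
    expect_equal(piola_stress(G, G, p), matrix(0, 3, 3), tolerance = 1e-12)
  }
  ## G = I, F = diag(a,1,1): standard compressible neo-Hookean form
  ## P = mu F + (lam ln J - mu) F^-T (symbolically differentiated)
  for (a in c(0.8, 1.3)) {
    F <- diag(c(a, 1, 1))
    P <- piola_stress(F, diag(3), p)
    Pref <- p$mu * F + (p$lam * log(a) - p$mu) * solve(t(F))
    expect_equal(P, Pref, tolerance = 1e-12)
  }
})

test_that("growth advances linearly in time", {
  st <- growth_state("cortical_isotropic", g = 1)
  expect_equal(advance_growth(st, 0, 1)$g, 1)
  expect_equal(advance_growth(st, 0.1, 3)$g, 1.3)
  ## n small steps vs one big step of equal total time
  st1 <- st
  for (i in 1:10) st1 <- advance_growth(st1, 0.07, 0.1)
  st2 <- advance_growth(st, 0.07, 1)
  expect_equal(st1$g, st2$g, tolerance = 1e-12)
  ## kind and axis unchanged
  stf <- growth_state("fiber_axial", g = 1, axis = c(0, 1, 0))
  stf2 <- advance_growth(stf, 0.2, 1)
  expect_identical(stf2$kind, "fiber_axial")
  expect_equal(stf2$axis, c(0, 1, 0))
  expect_error(advance_growth(st, 0.1, -1), "non-negative")
})
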