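# Quasi-static solver: assembly, equilibrium, growth stepping, thickness.

test_that("undeformed ungrown meshes carry zero residual", {
  mesh <- tiny_slab()
  a <- fe_assemble(mesh, new_solve_state(mesh))
  expect_equal(max(abs(a$residual)), 0)
  expect_equal(a$min_detA, 1, tolerance = 1e-12)
})

test_that("the assembled tangent is the exact linearization", {
  mesh <- make_toy_volume(one_element = TRUE)
  st <- new_solve_state(mesh)
  st$g <- 1.1
  set.seed(5)
  st$u <- matrix(rnorm(24, 0, 0.02), 8, 3)
  a <- fe_assemble(mesh, st, tangent = TRUE)
  K <- as.matrix(a$tangent)
  expect_equal(K, t(K), tolerance = 1e-10)   # hyperelastic symmetry
  h <- 1e-7
  for (d in sample(24, 8)) {
    up <- t(st$u); up[d] <- up[d] + h
    um <- t(st$u); um[d] <- um[d] - h
    stp <- st; stp$u <- t(up)
    stm <- st; stm$u <- t(um)
    col_fd <- (fe_assemble(mesh, stp, tangent = FALSE)$residual -
                 fe_assemble(mesh, stm, tangent = FALSE)$residual) / (2 * h)
    expect_equal(K[, d], col_fd, tolerance = 1e-5)
  }
})

test_that("uniform free growth is a stress-free similarity map", {
  ## with growth everywhere, x = g X has F = G pointwise and zero stress,
  ## so the residual vanishes on every DOF (no confinement needed)
  mesh <- tiny_slab()
  mesh$kind[] <- "cortical_isotropic"
  g <- 1.25
  st <- similarity_state(mesh, g)
  a <- fe_assemble(mesh, st, tangent = FALSE)
  expect_lt(max(abs(a$residual)), 1e-9)
})

test_that("a single-element patch reproduces the closed-form response", {
  ## confined in-plane (u_x = u_y = 0 on the sides), top free: growth g
  ## drives a homogeneous state F = diag(1, 1, s) G with s minimizing W.
  mesh <- make_toy_volume(one_element = TRUE)
  p <- material_params()
  sched <- growth_schedule(n_steps = 4L, g_final = 1.2)
  st <- new_solve_state(mesh)
  for (i in 1:4) st <- fe_step(mesh, st, sched, p)
  expect_true(st$converged)
  g <- 1.2
  ## independent 1D oracle: minimize W(diag(1/g, 1/g, s/g)) over s
  obj <- function(s) strain_energy(diag(c(1 / g, 1 / g, s / g)), p)
  s_star <- optimize(obj, c(0.5, 8))$minimum
  top_dz <- mean(st$u[mesh$sets$top, 3])
  expect_equal(1 + top_dz, s_star, tolerance = 1e-4)
  ## in-plane displacement stays zero by the symmetric BCs
  expect_lt(max(abs(st$u[, 1:2])), 1e-10)
})

test_that("zero-rate schedules leave the state unchanged", {
  mesh <- tiny_slab()
  st <- new_solve_state(mesh)
  st2 <- fe_step(mesh, st, growth_schedule(n_steps = 1L, g_final = 1,
                                           g_ct = 0, g_af = 0))
  expect_equal(st2$u, st$u)
  expect_equal(st2$g, st$g)
  expect_equal(st2$step, 1L)
})

test_that("growth stepping is path independent before buckling", {
  spec <- slab_spec(10, 10, 5, 1, dx = 1.25, core_layers = 3L)
  mesh <- apply_perturbation(build_slab(spec), perturbation_spec(seed = 3))
  p <- material_params()
  ## one increment to g = 1.06
  st1 <- new_solve_state(mesh)
  st1 <- fe_step(mesh, st1, growth_schedule(n_steps = 1L, g_final = 1.06), p)
  ## two increments of half size
  st2 <- new_solve_state(mesh)
  s2 <- growth_schedule(n_steps = 2L, g_final = 1.06)
  st2 <- fe_step(mesh, st2, s2, p)
  st2 <- fe_step(mesh, st2, s2, p)
  expect_true(st1$converged && st2$converged)
  expect_lt(max(abs(st1$u - st2$u)), 1e-6)
})

test_that("trajectories record surfaces and are deterministic", {
  spec <- slab_spec(10, 10, 5, 1, dx = 1.25, core_layers = 3L)
  mesh <- apply_perturbation(build_slab(spec), perturbation_spec(seed = 3))
  sched <- growth_schedule(n_steps = 3L, g_final = 1.12)
  tr1 <- fe_run(mesh, sched, record_every = 1L)
  tr2 <- fe_run(mesh, sched, record_every = 1L)
  expect_equal(length(tr1$surfaces), 3 + 1)   # initial + each step
  expect_identical(tr1$state$u, tr2$state$u)  # bit-identical rerun
  expect_identical(tr1$surfaces[[4]]$vertices, tr2$surfaces[[4]]$vertices)
  expect_equal(nrow(tr1$log), 3)
  expect_true(all(tr1$log$converged))
  ## residuals reported below tolerance at convergence
  expect_true(all(tr1$log$residual < 1e-3))
})

test_that("cortical thickness measurement matches analytic states", {
  mesh <- tiny_slab(tcortex = 1)
  th0 <- measure_cortical_thickness(mesh, NULL)
  expect_equal(th0$mean, 1, tolerance = 1e-9)
  expect_equal(th0$sd, 0, tolerance = 1e-9)
  ## uniformly grown similarity map: thickness scales by g
  g <- 1.2
  st <- similarity_state(mesh, g)
  th1 <- measure_cortical_thickness(mesh, st)
  expect_equal(th1$mean, g * 1, tolerance = 1e-9)
  ## sampling stability: 50 vs 200 samples agree within 5% on a rough state
  set.seed(9)
  st$u <- st$u + matrix(rnorm(length(st$u), 0, 0.02), ncol = 3)
  a <- measure_cortical_thickness(mesh, st, n_samples = 50, seed = 1)
  b <- measure_cortical_thickness(mesh, st, n_samples = 200, seed = 2)
  expect_lt(abs(a$mean - b$mean) / b$mean, 0.05)
})
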