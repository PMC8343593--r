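# shared helpers: random admissible tensors and small meshes

random_deformation <- function(scale = 0.1) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, scale), 3)
    if (det(F) > 0.2) return(F)
  }
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

random_growth <- function() {
  if (stats::runif(1) < 0.5) {
    growth_state("cortical_isotropic", g = stats::runif(1, 1, 1.6))
  } else {
    ax <- stats::rnorm(3)
    growth_state("fiber_axial", g = stats::runif(1, 1, 1.6),
                 axis = ax / sqrt(sum(ax^2)))
  }
}

# finite-difference gradient of W(F G^-1) wrt F -- the independent oracle
# for the Piola stress
fd_piola <- function(F, G, params, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(elastic_tensor(Fp, G), params) -
                  strain_energy(elastic_tensor(Fm, G), params)) / (2 * h)
  }
  P
}

tiny_slab <- function(Lx = 12, Ly = 12, Hcore = 6, tcortex = 1, dx = 1.5) {
  build_slab(slab_spec(Lx = Lx, Ly = Ly, Hcore = Hcore, tcortex = tcortex,
                       dx = dx, core_layers = 4L, grading = 1.4))
}

# similarity-map state: u = (g - 1) X, uniform growth g everywhere
similarity_state <- function(mesh, g) {
  st <- new_solve_state(mesh)
  st$u <- (g - 1) * mesh$coords
  st$g <- rep(g, nrow(mesh$conn))
  st
}
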