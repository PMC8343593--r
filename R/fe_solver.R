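## Quasi-static nonlinear FE solution of Div P = 0 under incrementally
## advancing growth: load-stepped Newton with line search, adaptive
## substepping and a light node-pair penalty against top-surface
## self-penetration.

#' Growth schedule
#'
#' Growth is linear in time.  One schedule step advances the cortical growth
#' ratio by \code{g_ct} and the fiber growth ratio by \code{g_af} (scaled per
#' element by its template gradient).  The default drives the cortex to a
#' final growth ratio of 1.8 in 100 increments: past the wrinkling
#' instability, before severe self-contact.
#'
#' @param n_steps Number of growth increments.
#' @param g_final Target cortical growth ratio (>= 1).
#' @param g_ct Cortical growth increment per step; derived from
#'   \code{g_final} when missing.
#' @param g_af Fiber growth increment per step; defaults to \code{g_ct}
#'   (fibers at the hinge junction grow at the cortical rate).
#' @return An object of class \code{growth_schedule}.
#' @export
growth_schedule <- function(n_steps = 100L, g_final = 1.8,
                            g_ct = (g_final - 1) / n_steps, g_af = g_ct) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  if (g_final < 1) stop("'g_final' must be >= 1", call. = FALSE)
  structure(list(n_steps = n_steps, g_ct = g_ct, g_af = g_af,
                 g_final = g_final), class = "growth_schedule")
}

#' Solver control parameters
#'
#' @param tol_rel Relative residual tolerance for Newton convergence.
#' @param max_newton Maximum Newton iterations per (sub)step.
#' @param max_substeps Maximum halvings of a growth increment.
#' @param contact Enable the top-surface self-contact penalty.
#' @param contact_gap Activation distance of the penalty (mm); \code{NULL}
#'   means half the in-plane element size.
#' @param contact_stiffness Penalty stiffness in units of shear modulus per
#'   mm (nodal stiffness = \code{contact_stiffness * mu * dx^2}).
#' @param dr_max_iter Iteration budget of the dynamic-relaxation fallback
#'   that carries the solution across post-buckling bifurcations where the
#'   Newton tangent is singular.
#' @param dr_damping Viscous damping factor of the dynamic relaxation.
#' @param verbose Print per-step diagnostics.
#' @return An object of class \code{solve_control}.
#' @export
solve_control <- function(tol_rel = 1e-6, max_newton = 30L, max_substeps = 10L,
                          contact = TRUE, contact_gap = NULL,
                          contact_stiffness = 100, dr_max_iter = 4000L,
                          dr_damping = 0.08, verbose = FALSE) {
  structure(list(tol_rel = tol_rel, max_newton = as.integer(max_newton),
                 max_substeps = as.integer(max_substeps), contact = contact,
                 contact_gap = contact_gap,
                 contact_stiffness = contact_stiffness,
                 dr_max_iter = as.integer(dr_max_iter),
                 dr_damping = dr_damping, verbose = verbose),
            class = "solve_control")
}

#' Initial solve state for a mesh
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @return An object of class \code{solve_state}: nodal displacements,
#'   per-element growth ratios, step counter and diagnostics.
#' @export
new_solve_state <- function(mesh) {
  structure(list(u = matrix(0, nrow(mesh$coords), 3), g = mesh$g,
                 converged = TRUE, step = 0L,
                 diagnostics = list(residual = 0, min_detA = 1,
                                    max_penetration = 0)),
            class = "solve_state")
}

# logical mask of free DOFs (node-major x,y,z) for the symmetric BCs:
# zero normal displacement on the four sides, bottom fully fixed
.free_dofs <- function(mesh) {
  N <- nrow(mesh$coords)
  free <- rep(TRUE, 3L * N)
  fix <- function(nodes, comp) free[3L * (nodes - 1L) + comp] <<- FALSE
  fix(mesh$sets$side_x0, 1L); fix(mesh$sets$side_x1, 1L)
  fix(mesh$sets$side_y0, 2L); fix(mesh$sets$side_y1, 2L)
  for (c in 1:3) fix(mesh$sets$bottom, c)
  free
}

# node-pair penalty against self-penetration of the top surface.
# Returns force vector contribution (3N), tangent triplets and max overlap.
.contact_forces <- function(mesh, u, control) {
  top <- mesh$sets$top
  X <- mesh$coords[top, , drop = FALSE]
  P <- X + u[top, , drop = FALSE]
  dx <- mesh$spec$dx
  gap <- if (is.null(control$contact_gap)) 0.5 * dx else control$contact_gap
  excl <- 3 * dx                       # material neighbours never interact
  n <- nrow(P)
  ## coarse in-plane binning on deformed coordinates
  cell <- gap * 2
  key <- paste(floor(P[, 1] / cell), floor(P[, 2] / cell), floor(P[, 3] / cell))
  buckets <- split(seq_len(n), key)
  cand_i <- integer(0); cand_j <- integer(0)
  keys <- strsplit(names(buckets), " ", fixed = TRUE)
  kx <- vapply(keys, function(k) as.integer(k[1]), 1L)
  ky <- vapply(keys, function(k) as.integer(k[2]), 1L)
  kz <- vapply(keys, function(k) as.integer(k[3]), 1L)
  keymap <- new.env(hash = TRUE)
  for (b in seq_along(buckets))
    assign(paste(kx[b], ky[b], kz[b]), b, envir = keymap)
  for (b in seq_along(buckets)) {
    ids <- buckets[[b]]
    others <- integer(0)
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      if (ox == 0 && oy == 0 && oz == 0) next
      nb <- mget(paste(kx[b] + ox, ky[b] + oy, kz[b] + oz),
                 envir = keymap, ifnotfound = list(NULL))[[1]]
      if (!is.null(nb) && nb > b) others <- c(others, buckets[[nb]])
    }
    if (length(ids) > 1L) {
      pr <- utils::combn(ids, 2L)
      cand_i <- c(cand_i, pr[1, ]); cand_j <- c(cand_j, pr[2, ])
    }
    if (length(others)) {
      cand_i <- c(cand_i, rep(ids, each = length(others)))
      cand_j <- c(cand_j, rep(others, times = length(ids)))
    }
  }
  out <- list(f = NULL, trips = NULL, max_pen = 0)
  if (!length(cand_i)) return(out)
  dref <- sqrt(rowSums((X[cand_i, , drop = FALSE] -
                          X[cand_j, , drop = FALSE])^2))
  keep <- dref > excl
  cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
  if (!length(cand_i)) return(out)
  dvec <- P[cand_i, , drop = FALSE] - P[cand_j, , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  act <- d < gap & d > 1e-9
  if (!any(act)) return(out)
  cand_i <- cand_i[act]; cand_j <- cand_j[act]
  dvec <- dvec[act, , drop = FALSE]; d <- d[act]
  k <- control$contact_stiffness * dx^2          # x mu, applied by caller
  nrm <- dvec / d
  fmag <- k * (gap - d)
  N <- nrow(mesh$coords)
  f <- numeric(3L * N)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  gi <- mesh$sets$top[cand_i]; gj <- mesh$sets$top[cand_j]
  for (c in 1:3) {
    di <- 3L * (gi - 1L) + c; dj <- 3L * (gj - 1L) + c
    fc <- fmag * nrm[, c]
    f[di] <- f[di] + fc
    f[dj] <- f[dj] - fc
  }
  ## tangent: k n n^T blocks (repulsive spring), assembled as triplets
  for (a in 1:3) for (b in 1:3) {
    v <- k * nrm[, a] * nrm[, b]
    dia <- 3L * (gi - 1L) + a; dib <- 3L * (gi - 1L) + b
    dja <- 3L * (gj - 1L) + a; djb <- 3L * (gj - 1L) + b
    ti <- c(ti, dia, dja, dia, dja)
    tj <- c(tj, dib, djb, djb, dib)
    tx <- c(tx, v, v, -v, -v)
  }
  list(f = f, trips = list(i = ti, j = tj, x = tx), max_pen = max(gap - d),
       energy = 0.5 * k * sum((gap - d)^2))
}

#' Assemble residual and tangent of the growth problem
#'
#' Discrete virtual-work residual of the finite-growth neo-Hookean material
#' with the current per-element growth tensors, together with its consistent
#' linearization.  External loads are absent; the residual of an
#' equilibrated state is zero on the free degrees of freedom.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param state A \code{\link{new_solve_state}} state (displacements and
#'   per-element growth ratios).
#' @param params A \code{\link{material_params}}.
#' @param tangent Assemble the sparse tangent operator as well?
#' @return List with \code{residual} (length-3N node-major vector),
#'   \code{tangent} (dgCMatrix or NULL), \code{energy}, \code{min_detA} and
#'   the free-DOF mask.
#' @export
fe_assemble <- function(mesh, state, params = material_params(),
                        tangent = TRUE) {
  Gm <- .growth_matrices(mesh, state$g)
  out <- .hex_assemble(mesh$coords, mesh$conn, state$u, Gm,
                       params$mu, params$lam, tangent)
  list(residual = if (is.null(out$force)) NULL else as.numeric(out$force),
       tangent = out$tangent,
       energy = out$energy, min_detA = out$min_detA,
       free = .free_dofs(mesh))
}

# node-major flattening helpers: v = (x1, y1, z1, x2, ...)
.flatten_u <- function(u) as.numeric(t(u))
.unflatten_u <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Newton solve at fixed growth field. Returns list(u, converged, ...)
.solve_equilibrium <- function(mesh, g, u0, params, control) {
  Gm <- .growth_matrices(mesh, g)
  free <- .free_dofs(mesh)
  u <- .flatten_u(u0)
  kcon <- params$mu                      # contact stiffness scale
  eval_force <- function(v, want_tangent) {
    u <- .unflatten_u(v)
    out <- .hex_assemble(mesh$coords, mesh$conn, u, Gm,
                         params$mu, params$lam, want_tangent)
    if (is.null(out$force)) return(out)   # inverted element
    pen <- 0
    if (isTRUE(control$contact)) {
      cf <- .contact_forces(mesh, u, control)
      if (!is.null(cf$f)) {
        out$force <- out$force + kcon * cf$f
        out$energy <- out$energy + kcon * cf$energy
        pen <- cf$max_pen
        if (want_tangent && !is.null(cf$trips)) {
          N3 <- length(out$force)
          Kc <- Matrix::sparseMatrix(i = cf$trips$i, j = cf$trips$j,
                                     x = kcon * cf$trips$x,
                                     dims = c(N3, N3))
          out$tangent <- out$tangent + Kc
        }
      }
    }
    out$max_pen <- pen
    out
  }
  ev <- eval_force(u, TRUE)
  if (is.null(ev$force))
    return(list(u = .unflatten_u(u), converged = FALSE, residual = Inf,
                min_detA = ev$min_detA, iters = 0L, max_pen = 0))
  fscale <- max(sqrt(sum(ev$force[free]^2)), 1e-12)
  res <- sqrt(sum(ev$force[free]^2))
  iters <- 0L
  stalled <- 0L
  while (iters < control$max_newton) {
    if (res <= control$tol_rel * fscale || res < 1e-12) break
    Kff <- Matrix::forceSymmetric(ev$tangent[free, free])
    ## sparse Cholesky while the tangent is positive definite; on an
    ## indefinite tangent (at/past a bifurcation) fall back to increasingly
    ## shifted factorizations — a modified Newton direction that the line
    ## search keeps honest
    du <- NULL
    dscale <- max(Matrix::diag(Kff))
    for (sh in c(0, 1e-6, 1e-4, 1e-2)) {
      ch <- suppressWarnings(
        tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE,
                                  Imult = sh * dscale),
                 error = function(e) NULL))
      if (!is.null(ch)) {
        du <- as.numeric(Matrix::solve(ch, -ev$force[free]))
        break
      }
    }
    if (is.null(du))
      du <- tryCatch(as.numeric(Matrix::solve(
        Kff + Matrix::Diagonal(sum(free), x = 1e-6 * dscale),
        -ev$force[free])), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du)))
      return(list(u = .unflatten_u(u), converged = FALSE, residual = res,
                  min_detA = ev$min_detA, iters = iters, max_pen = ev$max_pen))
    ## backtracking line search.  With no external loads, quasi-statics is
    ## minimization of the total potential energy, so a step is accepted
    ## when it satisfies an Armijo decrease of the energy (this follows
    ## stable branches through bifurcations, where the residual alone is a
    ## poor merit function) or when it reduces the residual norm.
    gTd <- sum(ev$force[free] * du)     # directional derivative of energy
    E0 <- ev$energy
    alpha <- 1; ok <- FALSE
    for (ls in 1:10) {
      utry <- u
      utry[free] <- u[free] + alpha * du
      evt <- eval_force(utry, FALSE)
      if (!is.null(evt$force)) {
        rtry <- sqrt(sum(evt$force[free]^2))
        armijo <- is.finite(E0) && gTd < 0 &&
          evt$energy <= E0 + 1e-4 * alpha * gTd
        if (rtry < (1 - 1e-4 * alpha) * res || armijo ||
            rtry < control$tol_rel * fscale) {
          u <- utry; res <- rtry; ok <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!ok)
      return(list(u = .unflatten_u(u), converged = FALSE, residual = res,
                  min_detA = ev$min_detA, iters = iters, max_pen = ev$max_pen))
    ev <- eval_force(u, TRUE)
    if (is.null(ev$force))
      return(list(u = .unflatten_u(u), converged = FALSE, residual = res,
                  min_detA = ev$min_detA, iters = iters, max_pen = 0))
    res_new <- sqrt(sum(ev$force[free]^2))
    ## stagnation guard: give up early when the residual barely moves, so
    ## substepping can try a smaller growth increment instead
    stalled <- if (res_new > 0.7 * res) stalled + 1L else 0L
    res <- res_new
    if (stalled >= 4L)
      return(list(u = .unflatten_u(u), converged = FALSE, residual = res,
                  min_detA = ev$min_detA, iters = iters, max_pen = ev$max_pen))
    iters <- iters + 1L
  }
  list(u = .unflatten_u(u), converged = res <= max(control$tol_rel * fscale, 1e-12),
       residual = res, min_detA = ev$min_detA, iters = iters,
       max_pen = ev$max_pen)
}

# Dynamic relaxation: damped explicit pseudo-dynamics at fixed growth.
# Used when Newton stalls at a bifurcation: the damped dynamics leaves the
# unstable (symmetric) branch -- round-off asymmetry is amplified by the
# instability exactly as in the quasi-static dynamic stepping the original
# simulations used -- and settles near a stable post-buckling equilibrium,
# which Newton then polishes.  Returns the relaxed displacement vector.
.dynamic_relaxation <- function(mesh, Gm, u0, params, control, free, kdiag) {
  u <- u0
  v <- numeric(length(u))
  ## Gershgorin-safe nodal pseudo-mass (kdiag = row sums of |tangent|)
  m <- 0.5 * pmax(kdiag, 1e-8 * max(kdiag))
  vmax <- 0.02 * mesh$spec$dx           # per-iteration displacement cap
  damp <- control$dr_damping
  kcon <- params$mu
  force_of <- function(v) {
    out <- .hex_assemble(mesh$coords, mesh$conn, .unflatten_u(v), Gm,
                         params$mu, params$lam, FALSE)
    if (is.null(out$force)) return(NULL)
    if (isTRUE(control$contact)) {
      cf <- .contact_forces(mesh, .unflatten_u(v), control)
      if (!is.null(cf$f)) out$force <- out$force + kcon * cf$f
    }
    out$force
  }
  f0 <- force_of(u)
  if (is.null(f0)) return(u0)
  fscale <- max(sqrt(sum(f0^2)), 1e-12)
  f <- f0
  for (it in seq_len(control$dr_max_iter)) {
    v[free] <- (1 - damp) * v[free] - f[free] / m[free]
    vm <- max(abs(v[free]))
    if (vm > vmax) v[free] <- v[free] * (vmax / vm)
    unew <- u
    unew[free] <- u[free] + v[free]
    fnew <- force_of(unew)
    if (is.null(fnew)) {        # overshoot inverted an element: back off
      v <- 0.25 * v
      next
    }
    u <- unew
    f <- fnew
    if (sqrt(sum(f[free]^2)) < 1e-4 * fscale) break
  }
  u
}

# per-element growth increment of one schedule step (dt = 1)
.growth_increment <- function(mesh, schedule) {
  dg <- numeric(nrow(mesh$conn))
  dg[mesh$kind == "cortical_isotropic"] <- schedule$g_ct
  fib <- mesh$kind == "fiber_axial"
  dg[fib] <- schedule$g_af * mesh$rate_scale[fib]
  dg
}

#' Advance one growth increment and re-equilibrate
#'
#' Advances every growing element's ratio by one schedule step (growth is
#' linear in time) and re-solves mechanical equilibrium with Newton + line
#' search, falling back to adaptive substepping of the growth increment when
#' Newton diverges.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param state Previous converged \code{solve_state}.
#' @param schedule A \code{\link{growth_schedule}}.
#' @param params A \code{\link{material_params}}.
#' @param control A \code{\link{solve_control}}.
#' @return The updated \code{solve_state}.
#' @export
fe_step <- function(mesh, state, schedule, params = material_params(),
                    control = solve_control()) {
  stopifnot(inherits(state, "solve_state"))
  if (!isTRUE(state$converged))
    stop("previous state did not converge; cannot advance", call. = FALSE)
  dg <- .growth_increment(mesh, schedule)
  if (all(dg == 0)) {
    state$step <- state$step + 1L
    return(state)
  }
  g_start <- state$g
  done <- 0; frac <- 1
  u <- state$u
  halvings <- 0L
  last <- NULL
  while (done < 1 - 1e-12) {
    f <- min(frac, 1 - done)
    g_try <- g_start + (done + f) * dg
    sol <- .solve_equilibrium(mesh, g_try, u, params, control)
    if (sol$converged) {
      done <- done + f
      u <- sol$u
      last <- sol
      frac <- min(1, frac * 1.5)
    } else {
      frac <- frac / 2
      halvings <- halvings + 1L
      if (frac < 0.3 || halvings > control$max_substeps) {
        ## Newton cannot pass this point by shrinking the increment (a
        ## bifurcation, not a step-size problem): relax dynamically at the
        ## full step target, then polish with Newton
        g_t <- g_start + dg
        Gm <- .growth_matrices(mesh, g_t)
        asm <- .hex_assemble(mesh$coords, mesh$conn, u, Gm,
                             params$mu, params$lam, TRUE)
        free <- .free_dofs(mesh)
        if (!is.null(asm$tangent)) {
          kdiag <- Matrix::rowSums(abs(asm$tangent))
          uv <- .dynamic_relaxation(mesh, Gm, .flatten_u(u), params,
                                    control, free, kdiag)
          sol <- .solve_equilibrium(mesh, g_t, .unflatten_u(uv), params,
                                    control)
          if (sol$converged) {
            done <- 1
            u <- sol$u
            last <- sol
            next
          }
        }
        state$converged <- FALSE
        state$diagnostics <- list(residual = sol$residual,
                                  min_detA = sol$min_detA,
                                  max_penetration = sol$max_pen,
                                  failed_at_fraction = done)
        warning("growth step failed to converge after max substeps")
        return(state)
      }
    }
  }
  state$u <- u
  state$g <- g_start + dg
  state$step <- state$step + 1L
  state$converged <- TRUE
  state$diagnostics <- list(residual = last$residual, min_detA = last$min_detA,
                            max_penetration = last$max_pen,
                            newton_iters = last$iters)
  state
}

#' Extract the deformed top surface as a triangulated mesh
#'
#' The structured top face (quads) is split into triangles with a fixed
#' diagonal orientation for reproducibility.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param u Nodal displacement matrix (N x 3); zero for the reference state.
#' @return A \code{\link{surface_mesh}}.
#' @export
extract_top_surface <- function(mesh, u = NULL) {
  top <- mesh$sets$top
  V <- mesh$coords[top, , drop = FALSE]
  if (!is.null(u)) V <- V + u[top, , drop = FALSE]
  nnx <- mesh$nx + 1L; nny <- mesh$ny + 1L
  vid <- function(i, j) i + (j - 1L) * nnx
  ii <- rep(seq_len(mesh$nx), times = mesh$ny)
  jj <- rep(seq_len(mesh$ny), each = mesh$nx)
  f1 <- cbind(vid(ii, jj), vid(ii + 1L, jj), vid(ii + 1L, jj + 1L))
  f2 <- cbind(vid(ii, jj), vid(ii + 1L, jj + 1L), vid(ii, jj + 1L))
  surface_mesh(V, rbind(f1, f2))
}

#' Peak-to-trough fold amplitude of a surface
#'
#' Half the range of the vertical coordinate; the uniform rise of a growing
#' flat plate cancels, so this measures the folding deviation seeded by the
#' initial perturbation.
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @return Amplitude (mm).
#' @export
fold_amplitude <- function(surface) {
  z <- surface$vertices[, 3]
  (max(z) - min(z)) / 2
}

#' Run a growth simulation
#'
#' Steps the growth schedule from the initial state to the target growth
#' ratio, recording the deformed top surface along the way.  Deterministic
#' for a fixed mesh, schedule and control.
#'
#' @inheritParams fe_step
#' @param record_every Record the top surface every this many steps (the
#'   final state is always recorded).
#' @return An object of class \code{surface_trajectory}: recorded surfaces,
#'   the final state, the mesh and a per-step diagnostics log.
#' @export
fe_run <- function(mesh, schedule, params = material_params(),
                   control = solve_control(), record_every = 1L) {
  state <- new_solve_state(mesh)
  surfaces <- list(extract_top_surface(mesh, state$u))
  recorded_g <- 1
  log <- vector("list", schedule$n_steps)
  gct <- 1
  for (s in seq_len(schedule$n_steps)) {
    state <- fe_step(mesh, state, schedule, params, control)
    gct <- gct + schedule$g_ct
    if (!state$converged) {
      warning(sprintf("simulation stopped at step %d (g_ct = %.4f)", s, gct))
      log[[s]] <- data.frame(step = s, g = gct, converged = FALSE,
                             residual = state$diagnostics$residual,
                             min_detA = state$diagnostics$min_detA,
                             max_penetration =
                               state$diagnostics$max_penetration)
      ## record the last converged configuration before stopping
      surfaces[[length(surfaces) + 1L]] <- extract_top_surface(mesh, state$u)
      recorded_g <- c(recorded_g, gct - schedule$g_ct)
      break
    }
    log[[s]] <- data.frame(step = s, g = gct, converged = TRUE,
                           residual = state$diagnostics$residual,
                           min_detA = state$diagnostics$min_detA,
                           max_penetration =
                             state$diagnostics$max_penetration)
    if (control$verbose)
      message(sprintf("step %3d  g = %.4f  res = %.3e  minJ = %.3f", s, gct,
                      state$diagnostics$residual,
                      state$diagnostics$min_detA))
    if (s %% record_every == 0L || s == schedule$n_steps) {
      surfaces[[length(surfaces) + 1L]] <- extract_top_surface(mesh, state$u)
      recorded_g <- c(recorded_g, gct)
    }
  }
  structure(list(surfaces = surfaces, g = recorded_g, state = state,
                 mesh = mesh, log = do.call(rbind, log[!vapply(log, is.null,
                                                               TRUE)])),
            class = "surface_trajectory")
}

#' @export
print.surface_trajectory <- function(x, ...) {
  cat(sprintf(
    "Growth trajectory: %d recorded surfaces, final g_ct = %.3f (%s)\n",
    length(x$surfaces), max(x$g),
    if (isTRUE(x$state$converged)) "converged" else "NOT converged"))
  invisible(x)
}

# minimum distance from point p to triangle (a, b, c)
.point_tri_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((ap - v * ab)^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((ap - w * ac)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((ap - v * ab - w * ac)^2))
}

#' Mean cortical thickness of a (deformed) slab
#'
#' Samples random top-surface vertices (seeded) and measures the distance to
#' the deformed gray--white interface surface; after folding the cortical
#' layer is not uniform, so the mean and SD over random locations are
#' reported.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param state A \code{solve_state} (or NULL for the reference state).
#' @param n_samples Number of random sample points.
#' @param seed Sampling seed.
#' @return List with \code{mean}, \code{sd} and the per-sample thicknesses.
#' @export
measure_cortical_thickness <- function(mesh, state = NULL, n_samples = 200L,
                                       seed = 1L) {
  u <- if (is.null(state)) matrix(0, nrow(mesh$coords), 3) else state$u
  def <- mesh$coords + u
  top <- def[mesh$sets$top, , drop = FALSE]
  ifc <- def[mesh$sets$interface, , drop = FALSE]
  ## triangulate the interface grid like the top surface
  nnx <- mesh$nx + 1L
  vid <- function(i, j) i + (j - 1L) * nnx
  ii <- rep(seq_len(mesh$nx), times = mesh$ny)
  jj <- rep(seq_len(mesh$ny), each = mesh$nx)
  tris <- rbind(cbind(vid(ii, jj), vid(ii + 1L, jj), vid(ii + 1L, jj + 1L)),
                cbind(vid(ii, jj), vid(ii + 1L, jj + 1L), vid(ii, jj + 1L)))
  cent <- (ifc[tris[, 1], ] + ifc[tris[, 2], ] + ifc[tris[, 3], ]) / 3
  n_samples <- min(n_samples, nrow(top))
  pick <- .with_seed(seed, sample.int(nrow(top), n_samples))
  th <- vapply(pick, function(k) {
    p <- top[k, ]
    d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 + (cent[, 3] - p[3])^2
    cand <- order(d2)[seq_len(min(24L, nrow(cent)))]
    min(vapply(cand, function(tr)
      .point_tri_dist(p, ifc[tris[tr, 1], ], ifc[tris[tr, 2], ],
                      ifc[tris[tr, 3], ]), 0))
  }, 0)
  list(mean = mean(th), sd = stats::sd(th), samples = th)
}
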