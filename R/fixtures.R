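## Analytic surface fixtures with known hinge structure, and toy volumes
## for solver unit tests.  Ground truth is exact by construction.

#' Fixture specification
#'
#' Height-field surfaces built from superposed Gaussian-profile ridges along
#' polyline centerlines; junction points where three or more ridges meet are
#' the expected 3-hinge locations.
#'
#' @param kind One of \code{"flat"}, \code{"single_ridge"},
#'   \code{"y_junction"}, \code{"x_junction"}, \code{"multi_y"},
#'   \code{"sinusoid_checkerboard"}.
#' @param L Domain side length (mm), square \code{[0,L]^2}.
#' @param height Ridge height (mm).
#' @param width Ridge cross-section SD (mm).
#' @param k Number of disjoint Y-junctions for \code{multi_y}.
#' @param resolution Vertices per mm (grid spacing = 1/resolution).
#' @param omega Spatial frequency for the sinusoid checkerboard (rad/mm).
#' @param seed Seed for randomized junction placement jitter.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(kind = c("flat", "single_ridge", "y_junction",
                                  "x_junction", "multi_y",
                                  "sinusoid_checkerboard"),
                         L = 40, height = 2, width = 3, k = 5L,
                         resolution = 1, omega = 2 * pi / 10, seed = 1L) {
  kind <- match.arg(kind)
  if (L <= 0 || height < 0 || width <= 0 || resolution <= 0 || k < 1)
    stop("fixture parameters must be positive", call. = FALSE)
  structure(list(kind = kind, L = L, height = height, width = width,
                 k = as.integer(k), resolution = resolution, omega = omega,
                 seed = as.integer(seed)), class = "fixture_spec")
}

# ridge centerlines (list of polylines) + junctions for a Y at a center
.y_polylines <- function(center, len, angle0 = pi / 2) {
  ang <- angle0 + c(0, 2, 4) * pi / 3
  lapply(ang, function(a)
    rbind(center, center + len * c(cos(a), sin(a))))
}

#' Generate an analytic fixture surface with known ground truth
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return List with \code{surface} (a \code{\link{surface_mesh}}),
#'   \code{expected_count} (number of 3-hinge junctions) and
#'   \code{junctions} (matrix of their in-plane coordinates, mm).
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- 1 / spec$resolution
  xs <- seq(0, spec$L, by = h)
  ys <- seq(0, spec$L, by = h)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  mid <- c(spec$L / 2, spec$L / 2)
  polylines <- list()
  junctions <- matrix(numeric(0), 0, 2)
  expected <- 0L

  if (spec$kind == "flat") {
    z <- rep(0, length(gx))
  } else if (spec$kind == "sinusoid_checkerboard") {
    z <- spec$height * (sin(spec$omega * gx) + sin(spec$omega * gy))
  } else {
    wid <- spec$width
    if (spec$kind == "single_ridge") {
      polylines <- list(rbind(c(spec$L * 0.1, mid[2]),
                              c(spec$L * 0.9, mid[2])))
    } else if (spec$kind == "y_junction") {
      polylines <- .y_polylines(mid, spec$L * 0.35)
      junctions <- matrix(mid, 1)
      expected <- 1L
    } else if (spec$kind == "x_junction") {
      len <- spec$L * 0.35
      ang <- pi / 4 + c(0, 1, 2, 3) * pi / 2
      polylines <- lapply(ang, function(a)
        rbind(mid, mid + len * c(cos(a), sin(a))))
      junctions <- matrix(mid, 1)   # a 4-hinge joint, not a 3-hinge
      expected <- 0L
    } else if (spec$kind == "multi_y") {
      ## disjoint Y-junctions on a jittered sub-grid; spoke length and
      ## ridge width scale with the sub-grid cell so each Y stays resolved
      ng <- ceiling(sqrt(spec$k))
      cell <- spec$L / ng
      centers <- expand.grid(i = seq_len(ng), j = seq_len(ng))
      centers <- centers[seq_len(spec$k), , drop = FALSE]
      jit <- .with_seed(spec$seed,
                        matrix(stats::runif(2 * spec$k, -0.05, 0.05) * cell,
                               ncol = 2))
      len <- 0.35 * cell
      wid <- min(spec$width, cell / 8)
      for (q in seq_len(spec$k)) {
        ctr <- c((centers$i[q] - 0.5) * cell, (centers$j[q] - 0.5) * cell) +
          jit[q, ]
        polylines <- c(polylines, .y_polylines(ctr, len))
        junctions <- rbind(junctions, ctr)
      }
      expected <- spec$k
    }
    ## superpose Gaussian ridge profiles (max keeps crest height uniform)
    z <- rep(0, length(gx))
    pts <- cbind(gx, gy)
    for (pl in polylines) {
      d <- .polyline_project(pts, pl)$dist
      z <- pmax(z, spec$height * exp(-d^2 / (2 * wid^2)))
    }
  }

  nnx <- length(xs)
  vid <- function(i, j) i + (j - 1L) * nnx
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  faces <- rbind(cbind(vid(ii, jj), vid(ii + 1L, jj), vid(ii + 1L, jj + 1L)),
                 cbind(vid(ii, jj), vid(ii + 1L, jj + 1L), vid(ii, jj + 1L)))
  list(surface = surface_mesh(cbind(gx, gy, z), faces, validate = FALSE),
       expected_count = expected, junctions = junctions)
}

#' Miniature slab volume for solver unit tests
#'
#' A toy \code{\link{build_slab}} wrapper: small dimensions, coarse uniform
#' core, meshed in well under a second.  With \code{one_element = TRUE}
#' a single-hexahedron mesh is returned for constitutive patch tests.
#'
#' @param dims Length-3 numeric, (Lx, Ly, Hcore) in mm; each <= 20.
#' @param tcortex Cortical thickness (mm).
#' @param dx In-plane element size (mm).
#' @param one_element Return a unit-cube single-element mesh.
#' @return A \code{volume_mesh}.
#' @export
make_toy_volume <- function(dims = c(10, 10, 5), tcortex = 1, dx = 1,
                            one_element = FALSE) {
  if (one_element) {
    coords <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1,
                                    KEEP.OUT.ATTRS = FALSE))
    mesh <- structure(list(
      coords = coords,
      conn = matrix(c(1L, 2L, 4L, 3L, 5L, 6L, 8L, 7L), 1),
      region = "cortex", kind = "cortical_isotropic",
      g = 1, rate_scale = 1, axis = c(0, 0, 1),
      sets = list(side_x0 = which(coords[, 1] == 0),
                  side_x1 = which(coords[, 1] == 1),
                  side_y0 = which(coords[, 2] == 0),
                  side_y1 = which(coords[, 2] == 1),
                  bottom = which(coords[, 3] == 0),
                  top = which(coords[, 3] == 1),
                  interface = which(coords[, 3] == 0)),
      spec = list(Lx = 1, Ly = 1, Hcore = 0, tcortex = 1, dx = 1),
      nx = 1L, ny = 1L, nz = 1L, zlevels = c(0, 1)), class = "volume_mesh")
    mesh$volumes <- .hex_volumes(mesh$coords, mesh$conn)
    return(mesh)
  }
  if (any(dims > 20)) stop("toy volumes are limited to 20 mm", call. = FALSE)
  build_slab(slab_spec(Lx = dims[1], Ly = dims[2], Hcore = dims[3],
                       tcortex = tcortex, dx = dx, core_layers = 4L,
                       grading = 1.4))
}
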