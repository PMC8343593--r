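## Bilayer slab construction: structured hexahedral mesh, region labels,
## boundary node sets, checkerboard perturbation and fiber-bundle templates.

#' Specification of the bilayer slab geometry
#'
#' The model is a flat rectangular bilayer: a thin growing cortical plate of
#' thickness \code{tcortex} bonded to a thick non-growing core of depth
#' \code{Hcore}.  The base configuration mirrors a small flat piece of a
#' developing brain: 60 mm x 60 mm in plane with a 50 mm core and a 1.5 mm
#' cortex.  In-plane element size defaults to the cortical thickness; the
#' cortex is discretized with at least two element layers through its
#' thickness, and the core layers are geometrically graded (fine at the
#' cortex--core interface, coarse at depth) so that deep core resolution
#' does not dominate the cost.
#'
#' @param Lx,Ly In-plane dimensions (mm).
#' @param Hcore Core thickness (mm), not counting the cortex.
#' @param tcortex Initial cortical thickness (mm); sanity range [0.5, 5].
#' @param dx Target in-plane element size (mm).
#' @param cortex_layers Element layers through the cortex (>= 2).
#' @param core_layers Element layers through the core.
#' @param grading Geometric ratio between successive core layer thicknesses.
#' @return An object of class \code{slab_spec}.
#' @examples
#' slab_spec()                     # 60 x 60 x 50 mm base model, t = 1.5 mm
#' slab_spec(10, 10, 5, 1, dx = 1)
#' @export
slab_spec <- function(Lx = 60, Ly = 60, Hcore = 50, tcortex = 1.5,
                      dx = tcortex, cortex_layers = 2L, core_layers = 8L,
                      grading = 1.6) {
  if (any(c(Lx, Ly, Hcore, tcortex, dx) <= 0) ||
      !all(is.finite(c(Lx, Ly, Hcore, tcortex, dx))))
    stop("all slab dimensions must be positive and finite", call. = FALSE)
  if (tcortex < 0.5 || tcortex > 5)
    stop("'tcortex' outside the sane cortical range [0.5, 5] mm", call. = FALSE)
  if (cortex_layers < 2)
    stop("the cortex must be resolved by at least 2 element layers",
         call. = FALSE)
  if (core_layers < 1 || grading < 1)
    stop("invalid core discretization", call. = FALSE)
  structure(list(Lx = Lx, Ly = Ly, Hcore = Hcore, tcortex = tcortex,
                 dx = dx, cortex_layers = as.integer(cortex_layers),
                 core_layers = as.integer(core_layers), grading = grading),
            class = "slab_spec")
}

# z-levels of the structured grid: graded core then uniform cortex layers
.slab_zlevels <- function(spec) {
  r <- spec$grading
  n <- spec$core_layers
  h0 <- if (r == 1) spec$Hcore / n else spec$Hcore * (r - 1) / (r^n - 1)
  core_h <- h0 * r^(seq_len(n) - 1)
  ## finest core layer sits at the interface (top of the core)
  z_core <- spec$Hcore - rev(cumsum(core_h))
  z_core[1] <- max(z_core[1], 0)
  z_cortex <- spec$Hcore + spec$tcortex * seq_len(spec$cortex_layers) /
    spec$cortex_layers
  c(0, z_core[-1], spec$Hcore, z_cortex)
}

#' Build the bilayer slab volume mesh
#'
#' Constructs a structured trilinear-hexahedral mesh spanning
#' \code{[0,Lx] x [0,Ly] x [0, Hcore + tcortex]} with the cortex--core
#' interface at \code{z = Hcore}.  Elements above the interface are labelled
#' \code{cortex} and carry isotropic growth; core elements do not grow.
#' Boundary node sets (four side faces, bottom, top surface, interface) are
#' recorded for the solver's symmetric boundary conditions.
#'
#' @param spec A \code{\link{slab_spec}}.
#' @return An object of class \code{volume_mesh}: node coordinates,
#'   connectivity, per-element region/growth bookkeeping and node sets.
#' @export
build_slab <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  ## ny = 1 with the symmetric side BCs realizes a plane-strain slice
  nx <- max(1L, as.integer(round(spec$Lx / spec$dx)))
  ny <- max(1L, as.integer(round(spec$Ly / spec$dx)))
  xs <- seq(0, spec$Lx, length.out = nx + 1L)
  ys <- seq(0, spec$Ly, length.out = ny + 1L)
  zs <- .slab_zlevels(spec)
  nz <- length(zs) - 1L

  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  coords <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                  KEEP.OUT.ATTRS = FALSE))
  ## node index helper: x fastest, then y, then z (matches expand.grid)
  nid <- function(i, j, k) i + (j - 1L) * nnx + (k - 1L) * nnx * nny

  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  conn <- cbind(nid(ii,      jj,      kk),
                nid(ii + 1L, jj,      kk),
                nid(ii + 1L, jj + 1L, kk),
                nid(ii,      jj + 1L, kk),
                nid(ii,      jj,      kk + 1L),
                nid(ii + 1L, jj,      kk + 1L),
                nid(ii + 1L, jj + 1L, kk + 1L),
                nid(ii,      jj + 1L, kk + 1L))
  storage.mode(conn) <- "integer"

  zc <- (zs[kk] + zs[kk + 1L]) / 2          # element centroid height
  region <- ifelse(zc > spec$Hcore, "cortex", "core")
  kind <- ifelse(region == "cortex", "cortical_isotropic", "none")
  rate_scale <- as.numeric(region == "cortex")

  iz_interface <- which.min(abs(zs - spec$Hcore))
  sets <- list(
    side_x0 = which(coords[, 1] == 0),
    side_x1 = which(coords[, 1] == spec$Lx),
    side_y0 = which(coords[, 2] == 0),
    side_y1 = which(coords[, 2] == spec$Ly),
    bottom  = which(coords[, 3] == zs[1]),
    top     = which(coords[, 3] == zs[nnz]),
    interface = which(coords[, 3] == zs[iz_interface]))

  mesh <- structure(list(
    coords = coords, conn = conn,
    region = region, kind = kind,
    g = rep(1, nrow(conn)), rate_scale = rate_scale,
    axis = c(0, 0, 1),
    sets = sets, spec = spec,
    nx = nx, ny = ny, nz = nz, zlevels = zs), class = "volume_mesh")
  vols <- .hex_volumes(mesh$coords, mesh$conn)
  if (any(vols <= 0)) stop("mesh construction produced inverted elements",
                           call. = FALSE)
  mesh$volumes <- vols
  mesh
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("Bilayer slab mesh: %d nodes, %d hexahedra (%d x %d x %d)\n",
              nrow(x$coords), nrow(x$conn), x$nx, x$ny, x$nz))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s=%d", names(table(x$region)),
                            table(x$region)), collapse = ", ")))
  invisible(x)
}

#' Checkerboard perturbation specification
#'
#' The instability trigger is a small checkerboard offset of the top surface,
#' \eqn{\epsilon_z = A_0[\sin(\omega x) + \sin(\omega y)]}, with amplitude
#' defaulting to 1\% of the cortical thickness.  When \code{omega} is not
#' given it is drawn (reproducibly from \code{seed}) from wavelengths of
#' 5--20 mm, bracketing observed fold wavelengths, so that ensemble members
#' with different seeds carry different initial perturbations.
#'
#' @param A0 Amplitude (mm); \code{NULL} means 1\% of the mesh's cortical
#'   thickness, resolved when the perturbation is applied.
#' @param omega Spatial frequency (rad/mm); \code{NULL} draws from the seed.
#' @param seed Integer seed for the randomized omega.
#' @return An object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(A0 = NULL, omega = NULL, seed = 1L) {
  if (!is.null(A0) && (!is.numeric(A0) || A0 < 0))
    stop("'A0' must be non-negative", call. = FALSE)
  if (is.null(omega)) {
    omega <- .with_seed(seed, stats::runif(1, 2 * pi / 20, 2 * pi / 5))
  }
  structure(list(A0 = A0, omega = omega, seed = as.integer(seed)),
            class = "perturbation_spec")
}

# evaluate f with a temporary RNG state; restores the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Checkerboard surface offset
#'
#' Closed form of the seeded perturbation,
#' \eqn{\epsilon_z(x, y) = A_0[\sin(\omega x) + \sin(\omega y)]} (mm), applied
#' in the direction normal to the undeformed cortical surface.
#'
#' @param x,y In-plane coordinates (mm); vectorized.
#' @param p A \code{\link{perturbation_spec}} with a resolved \code{A0}.
#' @return Vertical offsets (mm).
#' @export
checkerboard_perturbation <- function(x, y, p) {
  stopifnot(inherits(p, "perturbation_spec"))
  A0 <- if (is.null(p$A0)) stop("A0 unresolved; supply it or apply to a mesh",
                                call. = FALSE) else p$A0
  A0 * (sin(p$omega * x) + sin(p$omega * y))
}

#' Apply the checkerboard perturbation to a slab mesh
#'
#' Offsets the top-surface nodes by \eqn{\epsilon_z(x,y)} and blends the
#' offset linearly to zero at the cortex--core interface, leaving the core
#' untouched.  The default amplitude is 1\% of the cortical thickness.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param p A \code{\link{perturbation_spec}}.
#' @return The perturbed \code{volume_mesh} (reference coordinates moved).
#' @export
apply_perturbation <- function(mesh, p) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(p, "perturbation_spec"))
  A0 <- if (is.null(p$A0)) 0.01 * mesh$spec$tcortex else p$A0
  t <- mesh$spec$tcortex
  hmin <- min(diff(mesh$zlevels))
  if (2 * A0 >= 0.5 * hmin)
    stop("perturbation amplitude would invert cortical elements", call. = FALSE)
  z <- mesh$coords[, 3]
  above <- z > mesh$spec$Hcore
  blend <- pmax(0, (z - mesh$spec$Hcore) / t)
  pr <- p; pr$A0 <- A0
  eps <- checkerboard_perturbation(mesh$coords[, 1], mesh$coords[, 2], pr)
  mesh$coords[, 3] <- z + blend * eps
  mesh$perturbation <- pr
  vols <- .hex_volumes(mesh$coords, mesh$conn)
  if (any(vols <= 0))
    stop("perturbation inverted mesh elements", call. = FALSE)
  mesh$volumes <- vols
  mesh
}

#' Fiber-bundle template with three spokes
#'
#' Templates mimic concentrated axonal fiber bundles projecting from the base
#' of the white matter up to the cortex--core interface underneath a target
#' 3-hinge pattern: three spoke polylines meet at a junction point.  The
#' axial growth rate is highest in the junction column and decays linearly
#' with arclength along each spoke to zero at the spoke tip, mirroring the
#' fiber-density gradient observed along gyral hinge lines.
#'
#' @param junction Length-2 numeric, in-plane junction point (mm).
#' @param spokes List of exactly 3 polylines (k x 2 matrices, mm); each
#'   spoke's first point must coincide with the junction.
#' @param radius Bundle tube radius (mm).
#' @param g_axon_max Peak axial growth rate at the junction, expressed as a
#'   multiple of the fiber growth-rate constant (1 = same rate as the cortex).
#' @return An object of class \code{fiber_template}.
#' @export
fiber_template <- function(junction, spokes, radius = 1, g_axon_max = 1) {
  junction <- as.numeric(junction)
  if (length(junction) != 2L) stop("'junction' must be (x, y)", call. = FALSE)
  if (!is.list(spokes) || length(spokes) != 3L)
    stop("a 3-hinge template needs exactly 3 spokes", call. = FALSE)
  spokes <- lapply(spokes, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 2L || nrow(s) < 2L)
      stop("each spoke must be a k x 2 polyline with k >= 2", call. = FALSE)
    if (sqrt(sum((s[1, ] - junction)^2)) > 1e-8)
      stop("every spoke must start at the junction point", call. = FALSE)
    s
  })
  if (radius <= 0 || g_axon_max < 0) stop("invalid template parameters",
                                          call. = FALSE)
  structure(list(junction = junction, spokes = spokes, radius = radius,
                 g_axon_max = g_axon_max), class = "fiber_template")
}

#' Standard Y-shaped fiber template
#'
#' Convenience constructor: three straight spokes of equal length leaving the
#' junction at 120 degrees.
#'
#' @param junction In-plane junction point (mm).
#' @param length Spoke length (mm).
#' @param angle0 Orientation of the first spoke (rad).
#' @param radius,g_axon_max Passed to \code{\link{fiber_template}}.
#' @export
y_fiber_template <- function(junction, length = 10, angle0 = pi / 2,
                             radius = 1, g_axon_max = 1) {
  ang <- angle0 + c(0, 2, 4) * pi / 3
  spokes <- lapply(ang, function(a)
    rbind(junction, junction + length * c(cos(a), sin(a))))
  fiber_template(junction, spokes, radius = radius, g_axon_max = g_axon_max)
}

# distance to a 2-column polyline + normalized arclength of the projection
.polyline_project <- function(pts, poly) {
  segl <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                          poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(segl))
  total <- cum[length(cum)]
  best_d <- rep(Inf, nrow(pts)); best_s <- rep(0, nrow(pts))
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                         (pts[, 2] - a[2]) * ab[2]) / L2))
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_s[upd] <- (cum[s] + t[upd] * segl[s]) / max(total, 1e-12)
  }
  list(dist = best_d, s = best_s)
}

#' Embed fiber-bundle templates in a slab mesh
#'
#' Core elements whose centroids fall inside a vertical tube of the template
#' radius swept along a spoke (from the slab base up to the cortex--core
#' interface) are relabelled \code{fiber} and grow axially along the slab
#' normal.  The per-element growth-rate scale equals \code{g_axon_max} at
#' the junction and decays linearly with spoke arclength to zero at the tip.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param templates List of \code{\link{fiber_template}} objects (possibly
#'   empty, in which case the mesh is returned unchanged).
#' @return The modified \code{volume_mesh}.
#' @export
lay_fibers <- function(mesh, templates) {
  stopifnot(inherits(mesh, "volume_mesh"))
  if (length(templates) == 0L) return(mesh)
  spec <- mesh$spec
  cx <- rowMeans(matrix(mesh$coords[mesh$conn, 1], ncol = 8))
  cy <- rowMeans(matrix(mesh$coords[mesh$conn, 2], ncol = 8))
  cz <- rowMeans(matrix(mesh$coords[mesh$conn, 3], ncol = 8))
  core <- cz <= spec$Hcore
  pts <- cbind(cx, cy)
  for (tm in templates) {
    if (!inherits(tm, "fiber_template"))
      stop("templates must be 'fiber_template' objects", call. = FALSE)
    allp <- do.call(rbind, tm$spokes)
    if (any(allp[, 1] < 0 | allp[, 1] > spec$Lx |
            allp[, 2] < 0 | allp[, 2] > spec$Ly))
      stop("fiber template lies outside the slab footprint", call. = FALSE)
    for (sp in tm$spokes) {
      pr <- .polyline_project(pts, sp)
      idx <- which(core & pr$dist <= tm$radius)
      if (!length(idx)) next
      rate <- tm$g_axon_max * pmax(0, 1 - pr$s[idx])
      ## an element caught by several spokes keeps its highest growth rate
      cur <- ifelse(mesh$kind[idx] == "fiber_axial", mesh$rate_scale[idx], -Inf)
      take <- rate > cur
      mesh$region[idx[take]] <- "fiber"
      mesh$kind[idx[take]] <- "fiber_axial"
      mesh$rate_scale[idx[take]] <- rate[take]
    }
  }
  mesh
}

# per-element growth tensors as an M x 9 row-major matrix
.growth_matrices <- function(mesh, g = mesh$g) {
  M <- nrow(mesh$conn)
  Gm <- matrix(rep(as.numeric(diag(3)), each = M), nrow = M)
  iso <- mesh$kind == "cortical_isotropic"
  if (any(iso)) Gm[iso, c(1, 5, 9)] <- g[iso]
  fib <- mesh$kind == "fiber_axial"
  if (any(fib)) {
    ## G = I + (g - 1) z x z ; both I and z x z are symmetric, so the
    ## row-major flattening equals the column-major one
    zz <- as.numeric(tcrossprod(mesh$axis))
    iv <- as.numeric(diag(3))
    for (c in 1:9) Gm[fib, c] <- iv[c] + (g[fib] - 1) * zz[c]
  }
  Gm
}
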