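## Constitutive core: multiplicative growth kinematics and the
## compressible neo-Hookean energy shared by cortex, core and fibers.

#' Material parameters for the neo-Hookean energy
#'
#' Both the cortical plate and the core are modelled with the same
#' compressible neo-Hookean solid; reported brain-tissue stiffness gives a
#' shear modulus of about 0.5 kPa for gray matter, white matter and axonal
#' fiber bundles alike.  The first Lame constant is not constrained by the
#' available tissue data, so the default corresponds to a Poisson ratio of
#' 0.45 (near-incompressible soft tissue): \eqn{\lambda = 2\mu\nu/(1-2\nu)}.
#'
#' @param mu Shear modulus (kPa). Must be positive.
#' @param lam First Lame constant (kPa). Must be non-negative.
#' @return An object of class \code{material_params}.
#' @examples
#' material_params()            # mu = 0.5 kPa, lambda = 4.5 kPa (nu = 0.45)
#' material_params(mu = 1, lam = 0)
#' @export
material_params <- function(mu = 0.5, lam = 2 * mu * 0.45 / (1 - 2 * 0.45)) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number (kPa)", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("'lam' must be a single non-negative number (kPa)", call. = FALSE)
  structure(list(mu = mu, lam = lam), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  nu <- x$lam / (2 * (x$lam + x$mu))
  cat(sprintf("Neo-Hookean material: mu = %g kPa, lambda = %g kPa (nu = %.3f)\n",
              x$mu, x$lam, nu))
  invisible(x)
}

#' Growth state of a material region
#'
#' A region either grows isotropically (the cortical plate), grows along a
#' fixed axis (axonal fiber bundles, axis normal to the cortical surface),
#' or does not grow at all (the core).  The scalar growth ratio \code{g}
#' starts at 1 and advances linearly in time.
#'
#' @param kind One of \code{"cortical_isotropic"}, \code{"fiber_axial"},
#'   \code{"none"}.
#' @param g Scalar growth ratio (dimensionless, \eqn{\ge 1} initially 1).
#' @param axis Unit 3-vector, required for \code{kind = "fiber_axial"}.
#' @return An object of class \code{growth_state}.
#' @examples
#' growth_state("cortical_isotropic", g = 1.2)
#' growth_state("fiber_axial", g = 1.1, axis = c(0, 0, 1))
#' @export
growth_state <- function(kind = c("cortical_isotropic", "fiber_axial", "none"),
                         g = 1, axis = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("'g' must be a single positive number", call. = FALSE)
  if (kind == "fiber_axial") {
    if (is.null(axis) || length(axis) != 3L || !all(is.finite(axis)))
      stop("fiber_axial growth requires a finite 3-vector 'axis'", call. = FALSE)
    n <- sqrt(sum(axis^2))
    if (abs(n - 1) > 1e-8)
      stop("fiber growth axis must be a unit vector (|axis| = 1)", call. = FALSE)
    axis <- as.numeric(axis)
  } else {
    axis <- NULL
  }
  structure(list(kind = kind, g = g, axis = axis), class = "growth_state")
}

#' Growth tensor G of a growth state
#'
#' Isotropic cortical growth maps to \eqn{G = gI} (with \eqn{\det G = g^3});
#' axial fiber growth to \eqn{G = (g-1)\, z \otimes z + I} (with
#' \eqn{\det G = g}); a non-growing region to the identity.
#'
#' @param state A \code{\link{growth_state}}.
#' @return A 3x3 matrix.
#' @examples
#' growth_tensor(growth_state("cortical_isotropic", g = 1.5))  # 1.5 * I
#' growth_tensor(growth_state("fiber_axial", g = 1.2, axis = c(0, 0, 1)))
#' @export
growth_tensor <- function(state) {
  stopifnot(inherits(state, "growth_state"))
  switch(state$kind,
    cortical_isotropic = diag(3) * state$g,
    none = diag(3),
    fiber_axial = {
      z <- state$axis
      (state$g - 1) * tcrossprod(z) + diag(3)
    })
}

#' Elastic part of the deformation gradient
#'
#' Multiplicative decomposition \eqn{F = A G}: the growth tensor G adds
#' material, the elastic tensor A carries the stress-producing deformation.
#'
#' @param F Deformation gradient, 3x3 matrix with positive determinant.
#' @param G Growth tensor, 3x3 matrix with positive determinant.
#' @return The elastic tensor \eqn{A = F G^{-1}}.
#' @export
elastic_tensor <- function(F, G) {
  .check_tensor(F, "F")
  .check_tensor(G, "G")
  dG <- det(G)
  if (!is.finite(dG) || dG <= 0)
    stop("growth tensor G must have positive determinant", call. = FALSE)
  F %*% solve(G)
}

.check_tensor <- function(x, name) {
  if (!is.matrix(x) || !identical(dim(x), c(3L, 3L)) || !all(is.finite(x)))
    stop(sprintf("'%s' must be a finite 3x3 matrix", name), call. = FALSE)
  invisible(x)
}

#' Neo-Hookean strain energy density
#'
#' \deqn{W(A) = \tfrac12 \lambda \ln^2 J + \tfrac12 \mu (A\!:\!A - 3 - 2\ln J),
#'   \quad J = \det A,}
#' parameterized exclusively in the elastic tensor and its Jacobian, so a
#' stress-free grown state (\eqn{A = I}) has zero energy regardless of how
#' much material has been added.
#'
#' @param A Elastic tensor, 3x3 with positive determinant.
#' @param params A \code{\link{material_params}}.
#' @return Energy density (kPa, i.e. per unit reference volume).
#' @export
strain_energy <- function(A, params = material_params()) {
  .check_tensor(A, "A")
  J <- det(A)
  if (!is.finite(J) || J <= 0)
    stop("elastic tensor must have positive determinant", call. = FALSE)
  lnJ <- log(J)
  0.5 * params$lam * lnJ^2 + 0.5 * params$mu * (sum(A * A) - 3 - 2 * lnJ)
}

#' First Piola-Kirchhoff stress of the grown neo-Hookean solid
#'
#' The stress work-conjugate to the total deformation gradient, i.e. the
#' exact gradient of \code{strain_energy(elastic_tensor(F, G))} with respect
#' to F:
#' \deqn{P = \left[\mu A + (\lambda \ln J - \mu) A^{-T}\right] G^{-T},
#'   \quad A = F G^{-1},\; J = \det A.}
#' A grown but unstressed configuration (\eqn{F = G}) carries zero stress.
#'
#' @inheritParams elastic_tensor
#' @param params A \code{\link{material_params}}.
#' @return 3x3 first Piola-Kirchhoff stress (kPa).
#' @export
piola_stress <- function(F, G, params = material_params()) {
  .check_tensor(F, "F")
  if (!is.finite(det(F)) || det(F) <= 0)
    stop("deformation gradient must have positive determinant", call. = FALSE)
  Ginv <- tryCatch(solve(G), error = function(e)
    stop("growth tensor G is singular", call. = FALSE))
  A <- F %*% Ginv
  J <- det(A)
  if (J <= 0) stop("elastic tensor must have positive determinant", call. = FALSE)
  Ainv <- solve(A)
  dWdA <- params$mu * A + (params$lam * log(J) - params$mu) * t(Ainv)
  dWdA %*% t(Ginv)
}

#' Advance a growth state in time
#'
#' Growth is linear in time, \eqn{\dot g = \mathrm{rate}}, for both the
#' cortical plate and axonal fibers; the kind and fiber axis are untouched.
#'
#' @param state A \code{\link{growth_state}}.
#' @param rate Growth rate per unit time (\eqn{\dot g}).
#' @param dt Time increment, must be \eqn{\ge 0}.
#' @return The advanced \code{growth_state}.
#' @export
advance_growth <- function(state, rate, dt) {
  stopifnot(inherits(state, "growth_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("'dt' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate))
    stop("'rate' must be a single finite number", call. = FALSE)
  state$g <- state$g + rate * dt
  state
}
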