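# Axisymmetric midsurface geometry and through-thickness closed forms.
#
# All lengths are measured in units of the undeformed radius R; the shell
# is described on a uniform grid in undeformed arclength s in [0, pi*R].
# Conventions: outward normal, sphere curvatures positive
# (kappa_phi = sin(psi)/r > 0 for the sphere); s = 0 is the posterior pole.

# uniform-grid first-derivative matrix action: central differences in the
# interior, second-order one-sided at the ends
.deriv_uniform <- function(y, h) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  d
}

# cumulative quadrature on a uniform grid, 4th order: composite Simpson on
# even prefixes, with the trailing odd interval integrated from the local
# quadratic through the last three nodes
.cumquad_uniform <- function(y, h) {
  n <- length(y)
  out <- numeric(n)
  if (n < 3) {
    if (n == 2) out[2] <- h * (y[1] + y[2]) / 2
    return(out)
  }
  # first interval from the quadratic through nodes 1..3; thereafter
  # Simpson increments over interval pairs along both parities
  out[2] <- h * (5 * y[1] + 8 * y[2] - y[3]) / 12
  for (j in 3:n)
    out[j] <- out[j - 2] + h * (y[j - 2] + 4 * y[j - 1] + y[j]) / 3
  out
}

# Simpson weights on a uniform grid (n odd preferred; even n falls back to
# Simpson on n-1 nodes plus a quadratic-end correction)
.simpson_weights <- function(n, h) {
  if (n < 3) stop("need at least 3 grid points")
  if (n %% 2 == 1) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- w[n] <- 1
    w * h / 3
  } else {
    w <- .simpson_weights(n - 1, h)
    w <- c(w, 0)
    # last interval by quadratic through final three nodes
    w[n - 2] <- w[n - 2] - h / 12
    w[n - 1] <- w[n - 1] + 8 * h / 12
    w[n] <- w[n] + 5 * h / 12
    w
  }
}

.new_midsurface <- function(s, r, z, psi, stretch_s, kappa_s, kappa_phi,
                            closure = NA_real_) {
  out <- data.frame(s = s, r = r, z = z, psi = psi, stretch_s = stretch_s,
                    kappa_s = kappa_s, kappa_phi = kappa_phi)
  attr(out, "closure") <- closure
  class(out) <- c("midsurface_shape", class(out))
  out
}

#' Undeformed spherical midsurface
#'
#' Builds the unit-sphere reference shape of the cell sheet on a uniform
#' grid in arclength: \eqn{s \in [0, \pi R]}, \eqn{r = R\sin(s/R)},
#' \eqn{z = -R\cos(s/R)}, tangent angle \eqn{\psi = s/R}, both curvatures
#' \eqn{1/R}, meridional stretch 1.  \eqn{s = 0} is the posterior pole.
#'
#' @param radius sphere radius (units of R; default 1, the nondimensional
#'   convention).
#' @param n_grid number of arclength samples (at least 50).
#' @return a \code{midsurface_shape} data frame with columns \code{s, r, z,
#'   psi, stretch_s, kappa_s, kappa_phi}.
#' @export
undeformed_sphere <- function(radius = 1, n_grid = 401) {
  if (radius <= 0) stop("radius must be positive")
  if (n_grid < 50) stop("n_grid must be at least 50")
  s <- seq(0, pi * radius, length.out = n_grid)
  psi <- s / radius
  .new_midsurface(s, r = radius * sin(psi), z = -radius * cos(psi),
                  psi = psi, stretch_s = rep(1, n_grid),
                  kappa_s = rep(1 / radius, n_grid),
                  kappa_phi = rep(1 / radius, n_grid),
                  closure = 0)
}

#' Reconstruct a deformed midsurface from tangent fields
#'
#' Given the deformed tangent angle \eqn{\tilde\psi(s)} and meridional
#' stretch \eqn{\tilde f_s(s)} sampled on the arclength grid of a reference
#' shape, integrates \eqn{\tilde r' = \tilde f_s\cos\tilde\psi},
#' \eqn{\tilde z' = \tilde f_s \sin\tilde\psi} (4th-order cumulative
#' quadrature) and extracts the curvatures
#' \eqn{\tilde\kappa_s = \tilde\psi'/\tilde f_s},
#' \eqn{\tilde\kappa_\phi = \sin\tilde\psi/\tilde r} with the removable
#' pole singularity handled by the limit
#' \eqn{\tilde\kappa_\phi \to \tilde\kappa_s}.
#'
#' The axial gauge fixes \eqn{\tilde z} at the anterior pole
#' (\eqn{s = \pi R}) to its reference value, so posterior-pole displacement
#' can be read at \eqn{s = 0}.  The closure residual
#' \eqn{\int \tilde f_s \cos\tilde\psi\, ds} (which must vanish for a
#' closed shell) is stored in the \code{"closure"} attribute; a warning is
#' emitted when it exceeds \code{closure_tol} — closure is the equilibrium
#' solver's constraint, this function only reports it.
#'
#' @param psi numeric vector, deformed tangent angle at the reference
#'   arclength samples (radians).
#' @param stretch_s numeric vector of positive meridional stretches.
#' @param reference a \code{midsurface_shape} providing the grid and gauge.
#' @param closure_tol tolerance for the closure diagnostic.
#' @return a \code{midsurface_shape}.
#' @export
shape_from_tangent_fields <- function(psi, stretch_s, reference,
                                      closure_tol = 1e-6) {
  s <- reference$s
  n <- length(s)
  if (length(psi) != n || length(stretch_s) != n)
    stop("psi and stretch_s must be sampled on the reference s grid")
  if (any(stretch_s <= 0)) stop("stretch_s must be positive")
  h <- s[2] - s[1]
  r <- .cumquad_uniform(stretch_s * cos(psi), h)
  z <- .cumquad_uniform(stretch_s * sin(psi), h)
  z <- z - z[n] + reference$z[n]          # anterior-pole gauge
  closure <- r[n]
  if (abs(closure) > closure_tol)
    warning("shell not closed: closure residual ", format(closure))
  kappa_s <- .deriv_uniform(psi, h) / stretch_s
  kappa_phi <- numeric(n)
  kappa_phi[2:(n - 1)] <- sin(psi[2:(n - 1)]) / r[2:(n - 1)]
  kappa_phi[c(1, n)] <- kappa_s[c(1, n)]  # regularity limit at the poles
  .new_midsurface(s, r, z, psi, stretch_s, kappa_s, kappa_phi,
                  closure = closure)
}

#' @export
print.midsurface_shape <- function(x, ...) {
  cat("Axisymmetric midsurface:", nrow(x), "arclength samples on [0, ",
      format(max(x$s)), "]\n", sep = "")
  cat("  pole radii: ", format(x$r[1]), ", ", format(x$r[nrow(x)]),
      "; closure residual: ", format(attr(x, "closure")), "\n", sep = "")
  invisible(x)
}

#' @export
plot.midsurface_shape <- function(x, ..., reference = NULL) {
  plot(x$r, x$z, type = "l", asp = 1, xlab = "r / R", ylab = "z / R", ...)
  if (!is.null(reference)) lines(reference$r, reference$z, lty = 3)
  invisible(x)
}

#' Leading-order transverse profile of the intrinsic volume map
#'
#' Closed-form solution \eqn{Z^0(\zeta) = (1 - \sqrt{1 - 2\lambda_s^0
#' \zeta})/\lambda_s^0} of the leading-order intrinsic volume-conservation
#' equation \eqn{(1 - \lambda_s^0 Z^0)\, dZ^0/d\zeta = 1} with
#' \eqn{Z^0(0) = 0}.  For \eqn{|\lambda_s^0|} below \eqn{10^{-8}} the
#' analytic limit \eqn{\zeta(1 + \lambda_s^0 \zeta / 2)} is used.
#'
#' @param zeta transverse coordinate (units of R).
#' @param lambda_s0 scaled intrinsic meridional curvature (1/R).
#' @return numeric vector of \eqn{Z^0} values.
#' @export
z0_profile <- function(zeta, lambda_s0) {
  arg <- 1 - 2 * lambda_s0 * zeta
  if (any(arg <= 0))
    stop("transverse coordinate beyond the geometric singularity ",
         "(1 - 2*lambda_s0*zeta <= 0)")
  if (abs(lambda_s0) < 1e-8)
    zeta * (1 + lambda_s0 * zeta / 2)
  else
    (1 - sqrt(arg)) / lambda_s0
}

#' Through-thickness surface offsets
#'
#' The shell surfaces sit at \eqn{\zeta = \pm h^\pm} with
#' \eqn{h^\pm = (H^0/2)(1 \mp \lambda_s^0 H^0/4)}; their sum equals the
#' undeformed thickness \eqn{H^0} exactly, and
#' \eqn{Z^0(\pm h^\pm) = \pm H^0/2}.
#'
#' @param H0 intrinsic thickness parameter (units of R).
#' @param lambda_s0 scaled intrinsic meridional curvature (1/R).
#' @return list with components \code{h_plus} and \code{h_minus}.
#' @export
surface_offsets <- function(H0, lambda_s0) {
  if (abs(lambda_s0) * H0 / 4 >= 1)
    stop("constriction limit: |lambda_s0| * H0 / 4 must be below 1")
  list(h_plus = (H0 / 2) * (1 - lambda_s0 * H0 / 4),
       h_minus = (H0 / 2) * (1 + lambda_s0 * H0 / 4))
}

#' First-order incompressibility correction to the transverse map
#'
#' Closed-form solution
#' \deqn{Z_{(1)} = -\frac{Z^0\{6(E_s+E_\phi) - 3Z^0[L_s+L_\phi+
#'   \lambda_s^0(E_s+E_\phi)] + 2\lambda_s^0 L_\phi (Z^0)^2\}}
#'   {6(1-\lambda_s^0 Z^0)}}
#' of the order-\eqn{\epsilon} incompressibility condition, in the scaled
#' strain variables of the through-thickness expansion.
#'
#' @param Z0 leading transverse profile values.
#' @param Es,Ephi shell strains (scalars or vectors conformable with
#'   \code{Z0}).
#' @param Ls,Lphi curvature strains.
#' @param lambda_s0 scaled intrinsic meridional curvature (1/R).
#' @return numeric vector \eqn{Z_{(1)}}.
#' @export
z1_correction <- function(Z0, Es, Ephi, Ls, Lphi, lambda_s0) {
  den <- 1 - lambda_s0 * Z0
  if (any(den <= 0))
    stop("constriction limit: 1 - lambda_s0 * Z0 must be positive")
  A <- Es + Ephi
  -Z0 * (6 * A - 3 * Z0 * (Ls + Lphi + lambda_s0 * A) +
           2 * lambda_s0 * Lphi * Z0^2) / (6 * den)
}
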