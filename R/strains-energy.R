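# Strain measures and energy densities.
#
# The implementation works in physical strains with the thickness
# parameter t = eps*h: e_s = eps*E_s = (fs_tilde - fs0)/fs0, and the
# curvature strains K, L evaluated literally from their defining formulas
# (which contain no eps).  Under this absorption the large-bending density
#   e = (C/2) { t [ab_ss e_s^2 + (ab_sph + ab_phs) e_s e_ph + a_phph e_ph^2]
#        + 2 t^2 [bb_ss e_s K_s + bb_sph e_s K_ph + b_phs e_ph K_s
#                 + b_phph e_ph K_ph]
#        + t^3 [g_ss K_s^2 + (g_sph + g_phs) K_s K_ph + g_phph K_ph^2] }
# is term-by-term identical to the eps-bookkeeping form (each eps^3 h^m E^j
# K^l monomial maps to t^m e^j K^l); a unit test verifies the mapping.
# The material constant is C = 1: energies are reported in units of C R^3.

#' Shell strains of a deformed midsurface
#'
#' Computes, pointwise on the shared arclength grid, the physical shell
#' strains \eqn{e_s = (\tilde f_s - f_s^0)/f_s^0},
#' \eqn{e_\phi = (\tilde f_\phi - f_\phi^0)/f_\phi^0} (with
#' \eqn{\tilde f_\phi = \tilde r / r}, pole limit by continuity), the
#' alternative curvature strains
#' \eqn{K_s = (\tilde f_s \tilde\kappa_s - f_s^0
#' \kappa_s^0)/((f_s^0)^2 f_\phi^0)},
#' \eqn{K_\phi = (\tilde f_\phi\tilde\kappa_\phi - f_\phi^0
#' \kappa_\phi^0)/(f_s^0 (f_\phi^0)^2)}, and the raw curvature strains
#' \eqn{L_s = (\tilde\kappa_s - \kappa_s^0)/(f_s^0 f_\phi^0)},
#' \eqn{L_\phi = (\tilde\kappa_\phi - \kappa_\phi^0)/(f_s^0 f_\phi^0)}.
#' The K strains vanish for pure stretching (a sphere inflated to radius
#' \eqn{fR} has \eqn{K_s = K_\phi = 0} but nonzero L); the exact pointwise
#' identity \eqn{L_s - K_s = -\tilde\kappa_s e_s / g^0} links the two
#' families.
#'
#' @param deformed a \code{midsurface_shape} (the current embedding).
#' @param intrinsic an \code{intrinsic_config} on the same grid.
#' @param reference the undeformed shape; defaults to the unit sphere on
#'   the shared grid.
#' @return a \code{strain_field} data frame with columns \code{s, es, ephi,
#'   Ks, Kphi, Ls, Lphi, eta}.
#' @export
shell_strains <- function(deformed, intrinsic, reference = NULL) {
  n <- nrow(deformed)
  if (nrow(intrinsic) != n ||
      max(abs(deformed$s - intrinsic$s)) > 1e-10)
    stop("deformed shape and intrinsic config must share the s grid")
  if (is.null(reference)) reference <- undeformed_sphere(n_grid = n)
  fphi <- numeric(n)
  inner <- 2:(n - 1)
  fphi[inner] <- deformed$r[inner] / reference$r[inner]
  # pole limit of r_tilde / r by l'Hopital
  fphi[1] <- deformed$stretch_s[1] * cos(deformed$psi[1]) /
    cos(reference$psi[1])
  fphi[n] <- deformed$stretch_s[n] * cos(deformed$psi[n]) /
    cos(reference$psi[n])
  fs0 <- intrinsic$fs0; fphi0 <- intrinsic$fphi0
  g0 <- intrinsic$g0
  es <- (deformed$stretch_s - fs0) / fs0
  ephi <- (fphi - fphi0) / fphi0
  Ks <- (deformed$stretch_s * deformed$kappa_s - fs0 * intrinsic$kappa_s0) /
    (fs0^2 * fphi0)
  Kphi <- (fphi * deformed$kappa_phi - fphi0 * intrinsic$kappa_phi0) /
    (fs0 * fphi0^2)
  Ls <- (deformed$kappa_s - intrinsic$kappa_s0) / g0
  Lphi <- (deformed$kappa_phi - intrinsic$kappa_phi0) / g0
  out <- data.frame(s = deformed$s, es = es, ephi = ephi,
                    Ks = Ks, Kphi = Kphi, Ls = Ls, Lphi = Lphi,
                    eta = intrinsic$eta)
  attr(out, "t") <- attr(intrinsic, "t")
  class(out) <- c("strain_field", class(out))
  out
}

# raw strain container for direct density evaluation (tests, excess checks)
#' Assemble a strain field from explicit values
#'
#' Convenience constructor used to evaluate the energy density on
#' prescribed strains (e.g. random sampling of the quadratic form).
#'
#' @param es,ephi,Ks,Kphi strain components (recycled to a common length).
#' @param eta large-bending parameter values.
#' @param t thickness parameter stored with the field.
#' @return a \code{strain_field}.
#' @export
strain_field <- function(es, ephi, Ks, Kphi, eta, t = 0.15) {
  n <- max(length(es), length(ephi), length(Ks), length(Kphi), length(eta))
  out <- data.frame(s = rep(NA_real_, n), es = rep_len(es, n),
                    ephi = rep_len(ephi, n), Ks = rep_len(Ks, n),
                    Kphi = rep_len(Kphi, n), Ls = NA_real_, Lphi = NA_real_,
                    eta = rep_len(eta, n))
  attr(out, "t") <- t
  class(out) <- c("strain_field", class(out))
  out
}

# coefficient columns for the density quadratic form; classical model uses
# the eta = 0 moduli
.density_coefs <- function(eta, model) {
  if (model == "classical") eta <- rep(0, length(eta))
  shell_coefficients(eta)
}

#' Energy densities of the shell
#'
#' Evaluates, per grid point, the stretching, coupling and bending parts of
#' the effective two-dimensional energy density (energy per undeformed
#' midsurface area, units \eqn{C R}).  Under \code{model =
#' "large_bending"} the moduli are the \eqn{\eta}-dependent coefficient
#' functions; under \code{"classical"} they are frozen at their
#' \eqn{\eta = 0} values, which reproduces the thin Hookean shell density
#' \eqn{\hat e_0 = 2C[t(e_s^2 + e_s e_\phi + e_\phi^2) +
#' (t^3/12)(K_s^2 + K_s K_\phi + K_\phi^2)]}
#' (Poisson ratio 1/2, modulus \eqn{E = 3C}) with no stretch-bend
#' coupling.
#'
#' @param strains a \code{strain_field}.
#' @param t thickness parameter; defaults to the value stored in
#'   \code{strains}.
#' @param model \code{"large_bending"} or \code{"classical"}.
#' @return data frame with per-point columns \code{stretch, couple, bend,
#'   total}.
#' @export
energy_density <- function(strains, t = attr(strains, "t"),
                           model = c("large_bending", "classical")) {
  model <- match.arg(model)
  if (model == "large_bending") .check_eta_domain(strains$eta)
  cf <- .density_coefs(strains$eta, model)
  es <- strains$es; ephi <- strains$ephi
  Ks <- strains$Ks; Kphi <- strains$Kphi
  stretch <- 0.5 * t * (cf$alpha_bar_ss * es^2 +
                          (cf$alpha_bar_sphi + cf$alpha_bar_phis) * es * ephi +
                          cf$alpha_phiphi * ephi^2)
  couple <- t^2 * (cf$beta_bar_ss * es * Ks + cf$beta_bar_sphi * es * Kphi +
                     cf$beta_phis * ephi * Ks + cf$beta_phiphi * ephi * Kphi)
  bend <- 0.5 * t^3 * (cf$gamma_ss * Ks^2 +
                         (cf$gamma_sphi + cf$gamma_phis) * Ks * Kphi +
                         cf$gamma_phiphi * Kphi^2)
  data.frame(stretch = stretch, couple = couple, bend = bend,
             total = stretch + couple + bend)
}

#' Total elastic energy of a deformed midsurface
#'
#' \eqn{\mathcal{E} = 2\pi \int \hat e(s)\, r(s)\, ds} over the undeformed
#' generator (undeformed measure), by Simpson quadrature.  Units
#' \eqn{C R^3}.
#'
#' @inheritParams shell_strains
#' @param model energy model.
#' @param breakdown if \code{TRUE}, return the integrated stretch, couple,
#'   bend and total energies; otherwise the total only.
#' @return scalar energy, or a named numeric vector when
#'   \code{breakdown = TRUE}.
#' @export
total_energy <- function(deformed, intrinsic,
                         model = c("large_bending", "classical"),
                         reference = NULL, breakdown = FALSE) {
  model <- match.arg(model)
  if (is.null(reference)) reference <- undeformed_sphere(n_grid = nrow(deformed))
  st <- shell_strains(deformed, intrinsic, reference)
  dens <- energy_density(st, model = model)
  h <- deformed$s[2] - deformed$s[1]
  w <- .simpson_weights(nrow(deformed), h) * reference$r * 2 * pi
  tot <- c(stretch = sum(w * dens$stretch), couple = sum(w * dens$couple),
           bend = sum(w * dens$bend), total = sum(w * dens$total))
  if (breakdown) tot else unname(tot["total"])
}

#' Excess of the large-bending over the classical energy density
#'
#' Closed-form densities
#' \deqn{\hat e_{stretch} - \hat e_{0,stretch} = \frac{C t}{2}\,
#'   \frac{\eta^2(2-\eta^2)}{(1-\eta^2)^2}\,(2e_s + e_\phi)^2 \ge 0,}
#' \deqn{\hat e_{bend} - \hat e_{0,bend} = \frac{C t^3}{2}\,
#'   \frac{\eta^2(3-2\eta^2)}{36(1-\eta^2)^2}\,(3K_s + K_\phi)
#'   (k(\eta)K_s + K_\phi),}
#' which must agree with direct differencing of the corresponding
#' large-bending and classical breakdown terms.  The stretch excess
#' vanishes iff \eqn{e_\phi = -2e_s}; the bend excess is negative iff
#' \eqn{K_s K_\phi < 0} and \eqn{k(\eta)|K_s| < |K_\phi| < 3|K_s|}.
#'
#' @param strains a \code{strain_field}.
#' @param t thickness parameter.
#' @return data frame with columns \code{stretch_excess, bend_excess}.
#' @export
energy_excess <- function(strains, t = attr(strains, "t")) {
  eta <- strains$eta
  .check_eta_domain(eta)
  om <- (1 - eta^2)^2
  stretch_excess <- 0.5 * t * eta^2 * (2 - eta^2) / om *
    (2 * strains$es + strains$ephi)^2
  bend_excess <- 0.5 * t^3 * eta^2 * (3 - 2 * eta^2) / (36 * om) *
    (3 * strains$Ks + strains$Kphi) * (k_eta(eta) * strains$Ks + strains$Kphi)
  data.frame(stretch_excess = stretch_excess, bend_excess = bend_excess)
}

#' Write a per-point strain/energy table
#'
#' CSV with columns \code{s,es,ephi,Ks,Kphi,eta,e_stretch,e_couple,e_bend,
#' e_total}.
#'
#' @param strains a \code{strain_field} with a valid \code{s} column.
#' @param path output path.
#' @param model energy model used for the density columns.
#' @export
write_strain_table <- function(strains, path,
                               model = c("large_bending", "classical")) {
  model <- match.arg(model)
  dens <- energy_density(strains, model = model)
  d <- data.frame(s = strains$s, es = strains$es, ephi = strains$ephi,
                  Ks = strains$Ks, Kphi = strains$Kphi, eta = strains$eta,
                  e_stretch = dens$stretch, e_couple = dens$couple,
                  e_bend = dens$bend, e_total = dens$total)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
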