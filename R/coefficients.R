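# Coefficient functions of the large-bending shell energy density.
#
# All moduli of the quadratic energy form are functions of the large-bending
# parameter eta = kappa_s0 * t / (2 * fs0 * fphi0) alone.  Each raw
# coefficient is a rational function of eta plus a multiple of
# atanh(eta)/eta^n; the atanh terms cancel the 1/eta^n singularities at
# eta = 0, so direct evaluation loses precision there and a frozen Taylor
# series (exact rational constants, order 12) is used for small |eta|.

# Taylor coefficients about eta = 0, powers 0..12 (exact rationals).
.series_table <- list(
  alpha_ss     = c(4, 0, 8/3, 0, 17/5, 0, 30/7, 0, 47/9, 0, 68/11, 0, 93/13),
  alpha_sphi   = c(2, 0, 7/3, 0, 16/5, 0, 29/7, 0, 46/9, 0, 67/11, 0, 92/13),
  alpha_phiphi = c(4, 0, 2, 0, 3, 0, 4, 0, 5, 0, 6, 0, 7),
  beta_ss      = c(0, -1, 0, -3/2, 0, -2, 0, -5/2, 0, -3, 0, -7/2, 0),
  beta_sphi    = c(0, -1/3, 0, -8/15, 0, -29/42, 0, -23/27, 0, -67/66, 0, -46/39, 0),
  beta_phis    = c(0, -5/6, 0, -7/5, 0, -27/14, 0, -22/9, 0, -65/22, 0, -45/13, 0),
  beta_phiphi  = c(0, 1/6, 0, -1/2, 0, -2/3, 0, -5/6, 0, -1, 0, -7/6, 0),
  gamma_ss     = c(1/3, 0, 13/20, 0, 13/14, 0, 43/36, 0, 16/11, 0, 89/52, 0, 59/30),
  gamma_sphi   = c(1/6, 0, 7/30, 0, 9/28, 0, 11/27, 0, 65/132, 0, 15/26, 0, 119/180),
  gamma_phiphi = c(1/3, 0, 1/12, 0, 1/9, 0, 5/36, 0, 1/6, 0, 7/36, 0, 2/9),
  alpha_bar_ss   = c(4, 0, 8, 0, 12, 0, 16, 0, 20, 0, 24, 0, 28),
  alpha_bar_sphi = c(2, 0, 4, 0, 6, 0, 8, 0, 10, 0, 12, 0, 14),
  beta_bar_ss    = c(0, -5/3, 0, -14/5, 0, -27/7, 0, -44/9, 0, -65/11, 0, -90/13, 0),
  beta_bar_sphi  = c(0, -2/3, 0, -1, 0, -4/3, 0, -5/3, 0, -2, 0, -7/3, 0),
  k_eta = c(13/5, 0, 26/105, 0, 4/35, 0, 184/3465, 0, 3104/135135, 0,
            3184/405405, 0, 8464/20675655)
)

# switch to the series branch below this |eta|
.eta_series_switch <- 1e-2
# k(eta) cancels through eta^5, so its series branch extends further
.k_series_switch <- 8e-2
# guard band before the constriction singularity at |eta| = 1
.eta_guard <- 1 - 1e-6

.eval_series <- function(name, eta) {
  cs <- .series_table[[name]]
  # Horner in eta (series in eta, alternating coefficients carry parity)
  out <- rep(cs[length(cs)], length(eta))
  for (i in (length(cs) - 1):1) out <- out * eta + cs[i]
  out
}

.check_eta_domain <- function(eta, guard = .eta_guard) {
  if (any(!is.finite(eta)))
    stop("eta must be finite", call. = FALSE)
  if (any(abs(eta) > guard))
    stop("|eta| >= ", format(guard),
         ": intrinsic configuration is at the constriction limit ",
         "(wedge-shaped cells, coefficient functions diverge)", call. = FALSE)
  invisible(eta)
}

# atanh via logs; callers guarantee |eta| < 1
.atanh <- function(eta) 0.5 * log((1 + eta) / (1 - eta))

.closed_forms <- function(eta) {
  at <- .atanh(eta)
  om <- (1 - eta^2)^2
  e2 <- eta^2
  list(
    alpha_ss     = (e2^2 - 2 * e2 + 2) / om + 2 * at / eta,
    alpha_sphi   = 1 / om + at / eta,
    alpha_phiphi = (3 * e2^2 - 6 * e2 + 4) / om,
    beta_ss      = -eta * (2 - e2) / (2 * om),
    beta_sphi    = (e2^3 + 4 * e2^2 - 11 * e2 + 3) / (18 * eta * om) -
                   at / (6 * e2),
    beta_phis    = -1 / (2 * eta * om) + at / (2 * e2),
    beta_phiphi  = eta * (3 * e2^2 - 5 * e2 + 1) / (6 * om),
    gamma_ss     = (e2^2 - 2 * e2 + 2) / (4 * e2 * om) - at / (2 * eta^3),
    gamma_sphi   = (e2^3 - 2 * e2^2 + e2 + 3) / (36 * e2 * om) -
                   at / (12 * eta^3),
    gamma_phiphi = (10 * e2^2 - 21 * e2 + 12) / (36 * om),
    alpha_bar_ss   = 4 / om,
    alpha_bar_sphi = 2 / om,
    beta_bar_ss    = -1 / (eta * om) + at / e2,
    beta_bar_sphi  = -eta * (2 - e2) / (3 * om)
  )
}

.coef_names <- c("alpha_ss", "alpha_sphi", "alpha_phis", "alpha_phiphi",
                 "beta_ss", "beta_sphi", "beta_phis", "beta_phiphi",
                 "gamma_ss", "gamma_sphi", "gamma_phis", "gamma_phiphi",
                 "alpha_bar_ss", "alpha_bar_sphi", "alpha_bar_phis",
                 "beta_bar_ss", "beta_bar_sphi")

#' Coefficient functions of the large-bending energy density
#'
#' Evaluates, for each value of the large-bending parameter \eqn{\eta}, the
#' raw moduli \eqn{\alpha}, \eqn{\beta}, \eqn{\gamma} of the quadratic
#' energy form in the shell strains and curvature strains, together with the
#' combined moduli \eqn{\bar\alpha}, \eqn{\bar\beta} that arise when the
#' energy is written in the alternative curvature strains
#' \eqn{K_s, K_\phi}.  By symmetry \code{alpha_sphi == alpha_phis},
#' \code{gamma_sphi == gamma_phis} and
#' \code{alpha_bar_sphi == alpha_bar_phis}.
#'
#' All coefficients diverge like \eqn{(1-|\eta|)^{-2}} in the constriction
#' limit \eqn{|\eta| \to 1} (fully wedge-shaped cells).  Near \eqn{\eta = 0}
#' the closed forms suffer catastrophic cancellation between rational and
#' \eqn{\mathrm{artanh}} terms, so evaluation switches to a frozen Taylor
#' series there; both branches agree to better than \eqn{10^{-10}} relative
#' in the overlap window.
#'
#' @param eta numeric vector, \eqn{|\eta| < 1}. The large-bending parameter
#'   \eqn{\eta = \kappa_s^0 t / (2 f_s^0 f_\phi^0)} (dimensionless).
#' @param scaled logical; if \code{TRUE}, every coefficient is multiplied by
#'   \eqn{(1-|\eta|)^2}, removing the constriction-limit divergence (useful
#'   for studying the \eqn{|\eta|\to 1} behaviour).
#' @return a \code{data.frame} with one row per \code{eta} and columns
#'   \code{eta} plus the seventeen coefficient fields.
#' @examples
#' shell_coefficients(0)$alpha_bar_ss   # 4, the classical stretching value
#' shell_coefficients(0.5)$alpha_bar_ss # 4 / (1 - 0.25)^2
#' @seealso [k_eta()], [coefficient_series()]
#' @export
shell_coefficients <- function(eta, scaled = FALSE) {
  .check_eta_domain(eta)
  n <- length(eta)
  small <- abs(eta) < .eta_series_switch
  vals <- lapply(setdiff(.coef_names, c("alpha_phis", "gamma_phis",
                                        "alpha_bar_phis")),
                 function(nm) numeric(n))
  names(vals) <- setdiff(.coef_names, c("alpha_phis", "gamma_phis",
                                        "alpha_bar_phis"))
  if (any(!small)) {
    cf <- .closed_forms(eta[!small])
    for (nm in names(vals)) vals[[nm]][!small] <- cf[[nm]]
  }
  if (any(small)) {
    for (nm in names(vals)) vals[[nm]][small] <- .eval_series(nm, eta[small])
  }
  out <- data.frame(eta = eta,
                    alpha_ss = vals$alpha_ss,
                    alpha_sphi = vals$alpha_sphi,
                    alpha_phis = vals$alpha_sphi,
                    alpha_phiphi = vals$alpha_phiphi,
                    beta_ss = vals$beta_ss,
                    beta_sphi = vals$beta_sphi,
                    beta_phis = vals$beta_phis,
                    beta_phiphi = vals$beta_phiphi,
                    gamma_ss = vals$gamma_ss,
                    gamma_sphi = vals$gamma_sphi,
                    gamma_phis = vals$gamma_sphi,
                    gamma_phiphi = vals$gamma_phiphi,
                    alpha_bar_ss = vals$alpha_bar_ss,
                    alpha_bar_sphi = vals$alpha_bar_sphi,
                    alpha_bar_phis = vals$alpha_bar_sphi,
                    beta_bar_ss = vals$beta_bar_ss,
                    beta_bar_sphi = vals$beta_bar_sphi)
  if (scaled) {
    fac <- (1 - abs(eta))^2
    for (nm in .coef_names) out[[nm]] <- out[[nm]] * fac
  }
  class(out) <- c("shell_coefficients", class(out))
  out
}

#' Bending-excess multiplier k(eta)
#'
#' The factorized difference between the large-bending and classical bending
#' energies is proportional to \eqn{(3K_s + K_\phi)(k(\eta)K_s + K_\phi)}.
#' \code{k_eta} evaluates \eqn{k(\eta)}, reconstructed from the bending
#' moduli as \eqn{k = (\gamma_{ss} - 1/3) / (3 c_b)} with
#' \eqn{c_b = \eta^2(3-2\eta^2)/36(1-\eta^2)^2}; equivalently
#' \eqn{k(\eta) = [\eta(6 - 10\eta^2 + 11\eta^4 - 4\eta^6) -
#' 6(1-\eta^2)^2 \mathrm{artanh}\,\eta] / [\eta^5 (3 - 2\eta^2)]}.
#' It increases from \eqn{k(0) = 13/5} to \eqn{k(\pm 1) = 3}.
#'
#' @param eta numeric vector with \eqn{|\eta| \le 1}; the endpoints are
#'   evaluated by their limits.
#' @return numeric vector of the same length.
#' @examples
#' k_eta(0)      # 13/5
#' k_eta(c(-1, 1))  # both 3
#' @export
k_eta <- function(eta) {
  if (any(!is.finite(eta)) || any(abs(eta) > 1))
    stop("|eta| > 1: outside the admissible range of the bending parameter",
         call. = FALSE)
  out <- numeric(length(eta))
  ends <- abs(eta) == 1
  out[ends] <- 3
  small <- !ends & abs(eta) < .k_series_switch
  if (any(small)) out[small] <- .eval_series("k_eta", eta[small])
  rest <- !ends & !small
  if (any(rest)) {
    e <- eta[rest]
    out[rest] <- (e * (6 - 10 * e^2 + 11 * e^4 - 4 * e^6) -
                    6 * (1 - e^2)^2 * .atanh(e)) / (e^5 * (3 - 2 * e^2))
  }
  out
}

#' Divergence-scaled coefficient set
#'
#' Returns [shell_coefficients()] multiplied by \eqn{(1-|\eta|)^2}, the rate
#' at which all coefficients diverge in the constriction limit; every scaled
#' field tends to a finite limit as \eqn{|\eta| \to 1} (for instance scaled
#' \eqn{\bar\alpha_{ss} = 4/(1+\eta)^2 \to 1}).
#'
#' @inheritParams shell_coefficients
#' @export
divergence_scaled_set <- function(eta) {
  if (any(eta == 0))
    stop("divergence scaling is defined for 0 < |eta| < 1", call. = FALSE)
  shell_coefficients(eta, scaled = TRUE)
}
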