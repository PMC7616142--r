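# Independent Taylor-series construction for the coefficient functions.
#
# Every raw or combined coefficient has the shape
#     coef(eta) = P(eta) / (d * eta^a * (1-eta^2)^2) + c * atanh(eta)/eta^(a+1)
# with a small integer polynomial P.  Both factors have elementary exact
# series -- 1/(1-eta^2)^2 = sum (n+1) eta^(2n) and
# atanh(eta)/eta = sum eta^(2n)/(2n+1) -- so the expansion about eta = 0 is
# assembled by convolution of small rationals, independently of the frozen
# constants used by shell_coefficients().  The apparent eta^(-a) pole must
# cancel between the two parts; the cancellation is checked and is itself a
# correctness test.

.poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

# series of 1/(1 - eta^2)^2 up to power nmax
.series_inv_om2 <- function(nmax) {
  out <- numeric(nmax + 1)
  n <- 0:(nmax %/% 2)
  out[2 * n + 1] <- n + 1
  out
}

# series of atanh(eta)/eta up to power nmax
.series_atanh_over_eta <- function(nmax) {
  out <- numeric(nmax + 1)
  n <- 0:(nmax %/% 2)
  out[2 * n + 1] <- 1 / (2 * n + 1)
  out
}

# drop the first a coefficients (i.e. multiply by eta^(-a)), verifying that
# the dropped, formally singular coefficients vanish
.series_shift_down <- function(cs, a, tol = 1e-12) {
  if (a == 0) return(cs)
  if (any(abs(cs[seq_len(a)]) > tol))
    stop("singular part did not cancel in series construction")
  cs[-seq_len(a)]
}

# recipe table: eta^a * coef = P/(d*(1-eta^2)^2) + c * atanh(eta)/eta
.series_recipes <- list(
  alpha_ss     = list(p = c(2, 0, -2, 0, 1),        d = 1,  a = 0, c = 2),
  alpha_sphi   = list(p = 1,                        d = 1,  a = 0, c = 1),
  alpha_phiphi = list(p = c(4, 0, -6, 0, 3),        d = 1,  a = 0, c = 0),
  beta_ss      = list(p = c(0, -2, 0, 1),           d = 2,  a = 0, c = 0),
  beta_sphi    = list(p = c(3, 0, -11, 0, 4, 0, 1), d = 18, a = 1, c = -1 / 6),
  beta_phis    = list(p = -1,                       d = 2,  a = 1, c = 1 / 2),
  beta_phiphi  = list(p = c(0, 1, 0, -5, 0, 3),     d = 6,  a = 0, c = 0),
  gamma_ss     = list(p = c(2, 0, -2, 0, 1),        d = 4,  a = 2, c = -1 / 2),
  gamma_sphi   = list(p = c(3, 0, 1, 0, -2, 0, 1),  d = 36, a = 2, c = -1 / 12),
  gamma_phiphi = list(p = c(12, 0, -21, 0, 10),     d = 36, a = 0, c = 0),
  alpha_bar_ss   = list(p = 4,                      d = 1,  a = 0, c = 0),
  alpha_bar_sphi = list(p = 2,                      d = 1,  a = 0, c = 0),
  beta_bar_ss    = list(p = -1,                     d = 1,  a = 1, c = 1),
  beta_bar_sphi  = list(p = c(0, -2, 0, 1),         d = 3,  a = 0, c = 0)
)

#' Taylor expansion of a coefficient function about eta = 0
#'
#' Series oracle: assembles the expansion of a named raw or combined
#' coefficient (or of \code{"k_eta"}) by exact series convolution,
#' independently of the evaluation path used by [shell_coefficients()] and
#' [k_eta()].  Constant terms reproduce the classical-limit moduli
#' (\eqn{\alpha}'s 4, 2, 2, 4; \eqn{\beta}'s 0; \eqn{\gamma}'s 1/3, 1/6,
#' 1/6, 1/3), and the parity of each coefficient in \eqn{\eta} is manifest
#' (\eqn{\alpha, \gamma} even, \eqn{\beta} odd).
#'
#' @param name coefficient name, e.g. \code{"gamma_ss"},
#'   \code{"alpha_bar_ss"}, \code{"k_eta"}.  The symmetric partners
#'   \code{alpha_phis}, \code{gamma_phis}, \code{alpha_bar_phis} resolve to
#'   their twins.
#' @param order highest power of eta retained (at most 12).
#' @return numeric vector of Taylor coefficients for powers \code{0:order}.
#' @examples
#' coefficient_series("gamma_ss", 2)   # 1/3, 0, 13/20
#' @export
coefficient_series <- function(name, order = 8) {
  if (order > 12 || order < 0) stop("order must be between 0 and 12")
  alias <- c(alpha_phis = "alpha_sphi", gamma_phis = "gamma_sphi",
             alpha_bar_phis = "alpha_bar_sphi")
  if (name %in% names(alias)) name <- alias[[name]]
  nmax <- order + 16L
  if (name == "k_eta") return(.k_series(order, nmax))
  rec <- .series_recipes[[name]]
  if (is.null(rec)) stop("unknown coefficient name: ", name)
  cs <- .poly_mul(rec$p, .series_inv_om2(nmax))[seq_len(nmax + 1)] / rec$d
  if (rec$c != 0) cs <- cs + rec$c * .series_atanh_over_eta(nmax)
  cs <- .series_shift_down(cs, rec$a)
  cs[seq_len(order + 1)]
}

# k(eta) = [eta(6 - 10 eta^2 + 11 eta^4 - 4 eta^6)
#           - 6 (1-eta^2)^2 atanh(eta)] / (eta^5 (3 - 2 eta^2))
.k_series <- function(order, nmax) {
  num <- numeric(nmax + 1)
  num[c(2, 4, 6, 8)] <- c(6, -10, 11, -4)
  at <- .poly_mul(c(1, 0, -2, 0, 1),
                  c(0, .series_atanh_over_eta(nmax)))  # atanh(eta) itself
  num <- num - 6 * at[seq_len(nmax + 1)]
  num <- .series_shift_down(num, 5)
  inv <- numeric(length(num))           # 1/(3 - 2 eta^2)
  n <- 0:((length(num) - 1) %/% 2)
  inv[2 * n + 1] <- (1 / 3) * (2 / 3)^n
  .poly_mul(num, inv)[seq_len(order + 1)]
}
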