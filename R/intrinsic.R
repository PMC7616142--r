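# Intrinsic configurations: the locally stress-free stretches and
# curvatures encoding cell shape changes, and the derived large-bending
# parameter field eta(s) = kappa_s0 * t / (2 * fs0 * fphi0).

#' Scenario parameters for the invagination model
#'
#' Collects and validates the parameters of the piecewise intrinsic
#' stretch/curvature profiles driving invagination of a spherical cell
#' sheet: posterior, bend-region and anterior intrinsic curvatures
#' \eqn{\kappa_p, \kappa_b, \kappa_a} (1/R), posterior and anterior
#' intrinsic stretches \eqn{f_p, f_a}, bend-region position \eqn{s_0} and
#' width \eqn{w} (units of R), thickness parameter \eqn{\epsilon h}, and
#' the width \eqn{\delta} of the smooth transitions replacing the step
#' discontinuities.  Defaults are the early-invagination scenario
#' (\code{shell_preset("fig5a")}).
#'
#' @param kappa_p,kappa_b,kappa_a intrinsic curvatures (1/R).
#' @param f_p,f_a intrinsic meridional stretches (positive).
#' @param s0 bend-region position, in (0, pi] (units of R).
#' @param w bend-region width (positive, units of R).
#' @param eps_h shell thickness parameter t = eps*h (units of R).
#' @param delta step-smoothing width (units of R).
#' @param model \code{"large_bending"} or \code{"classical"}.
#' @param n_grid default arclength resolution for derived configurations.
#' @return an object of class \code{scenario_params}.
#' @export
scenario_params <- function(kappa_p = 1, kappa_b = -2, kappa_a = 1,
                            f_p = 0.8, f_a = 1, s0 = 1.5, w = 0.2,
                            eps_h = 0.15, delta = 0.05,
                            model = c("large_bending", "classical"),
                            n_grid = 401) {
  model <- match.arg(model)
  stopifnot(w > 0, s0 > 0, s0 <= pi, eps_h > 0, delta > 0,
            f_p > 0, f_a > 0, n_grid >= 50)
  if (s0 - w <= 0)
    stop("bend region [s0 - w, s0] must lie inside (0, pi)")
  out <- list(kappa_p = kappa_p, kappa_b = kappa_b, kappa_a = kappa_a,
              f_p = f_p, f_a = f_a, s0 = s0, w = w, eps_h = eps_h,
              delta = delta, model = model, n_grid = as.integer(n_grid))
  class(out) <- "scenario_params"
  out
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Invagination scenario (", x$model, ")\n", sep = "")
  cat(sprintf("  kappa_p = %g, kappa_b = %g, kappa_a = %g\n",
              x$kappa_p, x$kappa_b, x$kappa_a))
  cat(sprintf("  f_p = %g, f_a = %g, s0 = %g, w = %g\n",
              x$f_p, x$f_a, x$s0, x$w))
  cat(sprintf("  eps_h = %g, delta = %g, n_grid = %d\n",
              x$eps_h, x$delta, x$n_grid))
  invisible(x)
}

# smooth unit step of width delta centred at x = 0
.smooth_step <- function(x, delta) (1 + tanh(x / delta)) / 2

.new_intrinsic <- function(s, fs0, fphi0, kappa_s0, kappa_phi0, t) {
  g0 <- fs0 * fphi0
  out <- data.frame(s = s, fs0 = fs0, fphi0 = fphi0,
                    kappa_s0 = kappa_s0, kappa_phi0 = kappa_phi0,
                    g0 = g0, eta = kappa_s0 * t / (2 * g0))
  attr(out, "t") <- t
  class(out) <- c("intrinsic_config", class(out))
  out
}

#' Intrinsic profiles for Volvox invagination
#'
#' Builds the piecewise intrinsic configuration of the invagination model:
#' meridional intrinsic curvature \eqn{\kappa_s^0} equal to
#' \eqn{\kappa_p} for \eqn{s < s_0 - w}, \eqn{\kappa_b} in the bend region
#' \eqn{[s_0-w, s_0]} (wedge-shaped cells) and \eqn{\kappa_a} beyond;
#' meridional intrinsic stretch \eqn{f_s^0} equal to \eqn{f_p} posterior of
#' \eqn{s_0} (contracting spindle cells) and \eqn{f_a} anterior of it;
#' azimuthal stretch \eqn{f_\phi^0 = 1} and azimuthal curvature
#' \eqn{\kappa_\phi^0} stepping from \eqn{\kappa_p} to \eqn{\kappa_a} at
#' \eqn{s_0} (no bend amplification azimuthally).  Every step is replaced
#' by a tanh transition of width \code{delta}.
#'
#' @param params a \code{scenario_params} object.
#' @param s_grid optional arclength samples; defaults to a uniform grid of
#'   \code{params$n_grid} points on \eqn{[0, \pi]}.
#' @return an \code{intrinsic_config} data frame with columns \code{s, fs0,
#'   fphi0, kappa_s0, kappa_phi0, g0, eta} and attribute \code{"t"}.
#' @export
volvox_intrinsic <- function(params, s_grid = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  if (is.null(s_grid))
    s_grid <- seq(0, pi, length.out = params$n_grid)
  p <- params
  step_bend_on <- .smooth_step(s_grid - (p$s0 - p$w), p$delta)
  step_bend_off <- .smooth_step(s_grid - p$s0, p$delta)
  kappa_s0 <- p$kappa_p + (p$kappa_b - p$kappa_p) * step_bend_on +
    (p$kappa_a - p$kappa_b) * step_bend_off
  fs0 <- p$f_p + (p$f_a - p$f_p) * step_bend_off
  kappa_phi0 <- p$kappa_p + (p$kappa_a - p$kappa_p) * step_bend_off
  .new_intrinsic(s_grid, fs0, rep(1, length(s_grid)), kappa_s0, kappa_phi0,
                 t = p$eps_h)
}

#' Intrinsically compatible sphere
#'
#' Configuration \eqn{f_s^0 = f_\phi^0 = f},
#' \eqn{\kappa_s^0 = \kappa_\phi^0 = 1/(fR)}: a sphere of radius
#' \eqn{fR} is a stress-free embedding of this intrinsic geometry, so the
#' equilibrium solver must recover it with (numerically) zero energy.
#'
#' @param f uniform intrinsic stretch (positive).
#' @param s_grid arclength samples (defaults to 401 points on
#'   \eqn{[0,\pi]}).
#' @param eps_h thickness parameter.
#' @return an \code{intrinsic_config}.
#' @export
compatible_sphere_intrinsic <- function(f, s_grid = NULL, eps_h = 0.15) {
  stopifnot(f > 0)
  if (is.null(s_grid)) s_grid <- seq(0, pi, length.out = 401)
  n <- length(s_grid)
  .new_intrinsic(s_grid, rep(f, n), rep(f, n), rep(1 / f, n), rep(1 / f, n),
                 t = eps_h)
}

#' Large-bending parameter field
#'
#' \eqn{\eta(s) = \kappa_s^0(s)\, t / (2 f_s^0(s) f_\phi^0(s))}: depends on
#' the intrinsic data only, not on the deformed state.  Values with
#' \eqn{|\eta| \ge 1} indicate an intrinsic configuration at or beyond the
#' constriction limit and are flagged with a warning.
#'
#' @param config an \code{intrinsic_config}.
#' @return numeric vector of per-point eta values.
#' @export
eta_field <- function(config) {
  stopifnot(inherits(config, "intrinsic_config"))
  eta <- config$kappa_s0 * attr(config, "t") / (2 * config$g0)
  if (any(abs(eta) >= 1))
    warning("intrinsic configuration reaches the constriction limit ",
            "(max |eta| = ", format(max(abs(eta))), ")")
  eta
}

#' @export
print.intrinsic_config <- function(x, ...) {
  cat("Intrinsic configuration:", nrow(x), "samples, t =",
      format(attr(x, "t")), "\n")
  cat("  kappa_s0 in [", format(min(x$kappa_s0)), ", ",
      format(max(x$kappa_s0)), "]; max |eta| = ",
      format(max(abs(x$eta))), "\n", sep = "")
  invisible(x)
}

#' Scenario presets
#'
#' Named parameter sets used throughout the package:
#' \describe{
#'   \item{fig5a}{early invagination: \eqn{\kappa_p=\kappa_a=1},
#'     \eqn{\kappa_b=-2}, \eqn{f_p=0.8}, \eqn{f_a=1}, \eqn{s_0=1.5},
#'     \eqn{w=0.2}, \eqn{\epsilon h = 0.15}.}
#'   \item{fig5d}{later invagination: as fig5a but \eqn{\kappa_b=-8.5},
#'     \eqn{w=0.5}.}
#'   \item{fig5g-sweep}{bifurcation-diagram base parameters (as fig5a; the
#'     bend curvature \eqn{k=-\kappa_b} and width w are swept).}
#'   \item{identity}{no intrinsic deformation; the undeformed sphere is the
#'     exact ground state.}
#'   \item{compatible-sphere}{parameters of an intrinsically compatible
#'     sphere with f = 1.2 (use [compatible_sphere_intrinsic()] to build
#'     the configuration).}
#' }
#'
#' @param name preset name; with no argument, lists available presets.
#' @return a \code{scenario_params} object (or the preset names).
#' @export
shell_preset <- function(name = NULL) {
  presets <- c("fig5a", "fig5d", "fig5g-sweep", "identity",
               "compatible-sphere")
  if (is.null(name)) return(presets)
  switch(match.arg(name, presets),
    "fig5a" = scenario_params(),
    "fig5d" = scenario_params(kappa_b = -8.5, w = 0.5),
    "fig5g-sweep" = scenario_params(),
    "identity" = scenario_params(kappa_p = 1, kappa_b = 1, kappa_a = 1,
                                 f_p = 1, f_a = 1),
    "compatible-sphere" = scenario_params(kappa_p = 1 / 1.2,
                                          kappa_b = 1 / 1.2,
                                          kappa_a = 1 / 1.2,
                                          f_p = 1.2, f_a = 1.2))
}

#' Read a scenario configuration file
#'
#' JSON configuration with keys exactly \code{kappa_p, kappa_b, kappa_a,
#' f_p, f_a, s0, w, eps_h, delta, model, n_grid} (all optional; defaults as
#' in [scenario_params()]).  Unknown keys are rejected with a message
#' naming them.
#'
#' @param path path to a JSON file.
#' @return a \code{scenario_params} object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path)
  allowed <- c("kappa_p", "kappa_b", "kappa_a", "f_p", "f_a", "s0", "w",
               "eps_h", "delta", "model", "n_grid")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(scenario_params, cfg)
}

#' Read an intrinsic profile override
#'
#' CSV with header \code{s,fs0,fphi0,kappa_s0,kappa_phi0}; builds an
#' \code{intrinsic_config} directly from user-supplied profiles.
#'
#' @param path CSV file path.
#' @param eps_h thickness parameter t.
#' @return an \code{intrinsic_config}.
#' @export
read_intrinsic_profile <- function(path, eps_h = 0.15) {
  d <- utils::read.csv(path)
  need <- c("s", "fs0", "fphi0", "kappa_s0", "kappa_phi0")
  if (!all(need %in% names(d)))
    stop("profile CSV must have columns: ", paste(need, collapse = ","))
  if (any(d$fs0 <= 0) || any(d$fphi0 <= 0))
    stop("intrinsic stretches must be positive")
  .new_intrinsic(d$s, d$fs0, d$fphi0, d$kappa_s0, d$kappa_phi0, t = eps_h)
}
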