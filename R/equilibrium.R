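# Equilibrium shapes by direct minimization of the discretized energy.
#
# Unknowns are the deformed tangent angle psi at interior nodes (pole
# values pinned to 0 and pi) and the log of the meridional stretch at
# interior nodes (pole values set by the zero-slope regularity condition
# fs'(pole) = 0).  The closure constraint int f_s cos(psi) ds = 0 (the
# deformed generator must return to the axis) is enforced by an augmented
# Lagrangian; an optional second constraint pins the posterior-pole
# displacement d (used by the displacement-controlled continuation).
#
# The solver's internal quadrature is trapezoidal throughout, so the
# analytic reverse-mode gradient is exact for the discrete objective; the
# reported energy breakdown uses the same scheme and therefore integrates
# exactly to the minimized objective.

#' Solver control parameters
#'
#' @param maxit inner L-BFGS-B iteration cap.
#' @param factr,pgtol inner optimizer tolerances (see [stats::optim()]).
#' @param ctol constraint tolerance (closure residual and, when active,
#'   displacement residual).
#' @param rho0,rho_max initial and maximal augmented-Lagrangian penalty.
#' @param outer_max maximal number of multiplier updates.
#' @param eta_margin refuse large-bending solves when the intrinsic
#'   configuration has max |eta| above \code{1 - eta_margin} (the theory
#'   loses asymptoticity approaching the constriction limit).
#' @param allow_constriction override the margin with a warning.
#' @param grad_tol reported-convergence threshold on the projected
#'   gradient norm.
#' @param verbose print one line per outer iteration.
#' @return list of control settings.
#' @export
shell_control <- function(maxit = 2000, factr = 10, pgtol = 1e-9,
                          ctol = 1e-8, rho0 = 100, rho_max = 1e7,
                          outer_max = 30, eta_margin = 0.02,
                          allow_constriction = FALSE, grad_tol = 1e-6,
                          verbose = FALSE) {
  list(maxit = maxit, factr = factr, pgtol = pgtol, ctol = ctol,
       rho0 = rho0, rho_max = rho_max, outer_max = outer_max,
       eta_margin = eta_margin, allow_constriction = allow_constriction,
       grad_tol = grad_tol, verbose = verbose)
}

# precomputed quantities shared by all objective evaluations
.eq_setup <- function(intrinsic, model) {
  n <- nrow(intrinsic)
  s <- intrinsic$s
  h <- s[2] - s[1]
  ref <- undeformed_sphere(n_grid = n)
  wtrap <- rep(h, n); wtrap[c(1, n)] <- h / 2
  cf <- .density_coefs(intrinsic$eta, model)
  t <- attr(intrinsic, "t")
  list(n = n, s = s, h = h, ref = ref, wtrap = wtrap,
       wd = .simpson_weights(n, h),
       u = 2 * pi * wtrap * ref$r,
       t = t, model = model,
       fs0 = intrinsic$fs0, fphi0 = intrinsic$fphi0,
       ks0 = intrinsic$kappa_s0, kp0 = intrinsic$kappa_phi0,
       A11 = cf$alpha_bar_ss, A12 = cf$alpha_bar_sphi + cf$alpha_bar_phis,
       A22 = cf$alpha_phiphi,
       B11 = cf$beta_bar_ss, B12 = cf$beta_bar_sphi,
       B21 = cf$beta_phis, B22 = cf$beta_phiphi,
       G11 = cf$gamma_ss, G12 = cf$gamma_sphi + cf$gamma_phis,
       G22 = cf$gamma_phiphi,
       eta = intrinsic$eta, intrinsic = intrinsic)
}

# unpack the parameter vector into full psi and fs fields
.eq_fields <- function(x, sp) {
  n <- sp$n
  m <- n - 2
  psi <- c(0, x[seq_len(m)], pi)
  fs_int <- exp(x[m + seq_len(m)])
  fs <- c(fs_int[1], fs_int, fs_int[m])
  list(psi = psi, fs = fs)
}

# adjoint of the uniform-grid derivative used for kappa_s
.deriv_adjoint <- function(a, h) {
  n <- length(a)
  out <- numeric(n)
  ai <- a[2:(n - 1)]
  out[3:n] <- out[3:n] + ai / (2 * h)
  out[1:(n - 2)] <- out[1:(n - 2)] - ai / (2 * h)
  out[1] <- out[1] - 3 * a[1] / (2 * h)
  out[2] <- out[2] + 4 * a[1] / (2 * h)
  out[3] <- out[3] - a[1] / (2 * h)
  out[n] <- out[n] + 3 * a[n] / (2 * h)
  out[n - 1] <- out[n - 1] - 4 * a[n] / (2 * h)
  out[n - 2] <- out[n - 2] + a[n] / (2 * h)
  out
}

# objective, constraints and analytic gradient of the augmented Lagrangian
.eq_objective <- function(x, sp, lam1, rho, d_target = NULL, lam2 = 0) {
  n <- sp$n
  fl <- .eq_fields(x, sp)
  psi <- fl$psi; fs <- fl$fs
  cp <- cos(psi); sn <- sin(psi)
  g <- fs * cp
  rt <- c(0, cumsum((g[-n] + g[-1]) * sp$h / 2))
  q <- fs * sn
  d_val <- 2 - sum(sp$wd * q)
  c1 <- rt[n]

  inner <- 2:(n - 1)
  fphi <- numeric(n)
  fphi[inner] <- rt[inner] / sp$ref$r[inner]
  fphi[1] <- fs[1]; fphi[n] <- fs[n]
  dpsi <- .deriv_uniform(psi, sp$h)
  ks <- dpsi / fs
  kphi <- numeric(n)
  kphi[inner] <- sn[inner] / rt[inner]
  kphi[c(1, n)] <- ks[c(1, n)]

  es <- (fs - sp$fs0) / sp$fs0
  eph <- (fphi - sp$fphi0) / sp$fphi0
  Ks <- (fs * ks - sp$fs0 * sp$ks0) / (sp$fs0^2 * sp$fphi0)
  Kp <- (fphi * kphi - sp$fphi0 * sp$kp0) / (sp$fs0 * sp$fphi0^2)

  t <- sp$t
  eden <- 0.5 * t * (sp$A11 * es^2 + sp$A12 * es * eph + sp$A22 * eph^2) +
    t^2 * (sp$B11 * es * Ks + sp$B12 * es * Kp +
             sp$B21 * eph * Ks + sp$B22 * eph * Kp) +
    0.5 * t^3 * (sp$G11 * Ks^2 + sp$G12 * Ks * Kp + sp$G22 * Kp^2)
  E <- sum(sp$u * eden)

  val <- E + lam1 * c1 + 0.5 * rho * c1^2
  c2 <- 0
  if (!is.null(d_target)) {
    c2 <- d_val - d_target
    val <- val + lam2 * c2 + 0.5 * rho * c2^2
  }

  # ---- reverse sweep ----
  P_es <- sp$u * (0.5 * t * (2 * sp$A11 * es + sp$A12 * eph) +
                    t^2 * (sp$B11 * Ks + sp$B12 * Kp))
  P_ep <- sp$u * (0.5 * t * (sp$A12 * es + 2 * sp$A22 * eph) +
                    t^2 * (sp$B21 * Ks + sp$B22 * Kp))
  P_Ks <- sp$u * (t^2 * (sp$B11 * es + sp$B21 * eph) +
                    0.5 * t^3 * (2 * sp$G11 * Ks + sp$G12 * Kp))
  P_Kp <- sp$u * (t^2 * (sp$B12 * es + sp$B22 * eph) +
                    0.5 * t^3 * (sp$G12 * Ks + 2 * sp$G22 * Kp))

  a_fs <- P_es / sp$fs0 + P_Ks * ks / (sp$fs0^2 * sp$fphi0)
  a_ks <- P_Ks * fs / (sp$fs0^2 * sp$fphi0)
  a_fphi <- P_ep / sp$fphi0 + P_Kp * kphi / (sp$fs0 * sp$fphi0^2)
  a_kphi <- P_Kp * fphi / (sp$fs0 * sp$fphi0^2)

  dpsi_acc <- numeric(n)
  a_rt <- numeric(n)
  # kappa_phi = sin(psi)/rt on interior nodes
  dpsi_acc[inner] <- dpsi_acc[inner] + a_kphi[inner] * cp[inner] / rt[inner]
  a_rt[inner] <- a_rt[inner] - a_kphi[inner] * sn[inner] / rt[inner]^2
  # fphi = rt/r on interior nodes
  a_rt[inner] <- a_rt[inner] + a_fphi[inner] / sp$ref$r[inner]
  # kappa_s = dpsi/fs
  a_fs <- a_fs - a_ks * ks / fs
  dpsi_acc <- dpsi_acc + .deriv_adjoint(a_ks / fs, sp$h)
  # closure constraint through rt
  a_rt[n] <- a_rt[n] + lam1 + rho * c1
  # cumulative trapezoid adjoint: a_g_i = (h/2) * (T_{i+1} + T_i [i>1])
  Trev <- rev(cumsum(rev(a_rt)))          # T_i = sum_{j>=i} a_rt_j
  # a_g_i = (h/2) (T_{i+1} + T_i [i >= 2]); T_{n+1} = 0
  a_g <- (sp$h / 2) * (c(Trev[-1], 0) + c(0, Trev[-1]))
  # d constraint through q
  a_q <- numeric(n)
  if (!is.null(d_target)) a_q <- -(lam2 + rho * c2) * sp$wd
  # g = fs cos(psi), q = fs sin(psi)
  dpsi_acc <- dpsi_acc - a_g * fs * sn + a_q * fs * cp
  a_fs <- a_fs + a_g * cp + a_q * sn

  m <- n - 2
  grad_psi <- dpsi_acc[inner]
  grad_phi <- (a_fs * fs)[inner]
  grad_phi[1] <- grad_phi[1] + a_fs[1] * fs[1]
  grad_phi[m] <- grad_phi[m] + a_fs[n] * fs[n]

  list(value = val, grad = c(grad_psi, grad_phi), energy = E,
       closure = c1, d = d_val, c2 = c2,
       fields = list(psi = psi, fs = fs, rt = rt,
                     fphi = fphi, ks = ks, kphi = kphi),
       strains = list(es = es, eph = eph, Ks = Ks, Kp = Kp),
       density = eden)
}

# augmented-Lagrangian driver; returns the final evaluation plus
# multipliers and iteration diagnostics
.solve_al <- function(sp, x0, control, d_target = NULL,
                      lam1 = 0, lam2 = 0) {
  rho <- control$rho0
  ev_env <- new.env(parent = emptyenv())
  total_it <- 0L
  cprev <- Inf
  for (outer in seq_len(control$outer_max)) {
    fn <- function(x) {
      ev <- .eq_objective(x, sp, lam1, rho, d_target, lam2)
      assign("last", list(x = x, ev = ev), envir = ev_env)
      ev$value
    }
    gr <- function(x) {
      last <- get0("last", envir = ev_env)
      if (!is.null(last) && identical(last$x, x)) return(last$ev$grad)
      ev <- .eq_objective(x, sp, lam1, rho, d_target, lam2)
      ev$grad
    }
    opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = control$maxit,
                                       factr = control$factr,
                                       pgtol = control$pgtol))
    x0 <- opt$par
    total_it <- total_it + opt$counts[1]
    ev <- .eq_objective(x0, sp, lam1, rho, d_target, lam2)
    cnorm <- max(abs(ev$closure), abs(ev$c2))
    if (control$verbose)
      cat(sprintf("  outer %d: E=%.6e |c|=%.2e rho=%.0e gnorm=%.2e\n",
                  outer, ev$energy, cnorm, rho, max(abs(ev$grad))))
    lam1 <- lam1 + rho * ev$closure
    if (!is.null(d_target)) lam2 <- lam2 + rho * ev$c2
    if (cnorm < control$ctol) break
    if (cnorm > 0.25 * cprev) rho <- min(rho * 10, control$rho_max)
    cprev <- cnorm
  }
  list(x = x0, ev = ev, lam1 = lam1, lam2 = lam2,
       iterations = as.integer(total_it),
       grad_norm = max(abs(ev$grad)),
       converged = cnorm < control$ctol &&
         max(abs(ev$grad)) < control$grad_tol)
}

# extract (psi, log fs) start vector from an init object
.eq_init <- function(init, sp) {
  n <- sp$n
  m <- n - 2
  if (is.null(init))
    return(c(sp$s[2:(n - 1)], numeric(m)))
  if (inherits(init, "shell_equilibrium"))
    init <- init$shape
  if (inherits(init, "midsurface_shape")) {
    if (nrow(init) == n)
      return(c(init$psi[2:(n - 1)], log(init$stretch_s[2:(n - 1)])))
    psi <- stats::approx(init$s, init$psi, xout = sp$s)$y
    fs <- stats::approx(init$s, init$stretch_s, xout = sp$s)$y
    return(c(psi[2:(n - 1)], log(fs[2:(n - 1)])))
  }
  stop("init must be NULL, a midsurface_shape or a shell_equilibrium")
}

#' Equilibrium shape of a morphoelastic shell
#'
#' Computes the equilibrium (energy-minimizing) axisymmetric embedding of a
#' spherical cell sheet with the given intrinsic configuration, under the
#' large-bending or classical energy density.  The discretized energy is
#' minimized over the deformed tangent angle and meridional stretch with
#' pinned pole angles (\eqn{\tilde\psi(0)=0}, \eqn{\tilde\psi(\pi R)=\pi})
#' and the closure constraint \eqn{\int \tilde f_s \cos\tilde\psi\,ds = 0},
#' using L-BFGS-B with an analytic gradient inside an augmented-Lagrangian
#' loop.  The solve is deterministic given the initial shape.
#'
#' @param intrinsic an \code{intrinsic_config}, or a
#'   \code{scenario_params} (converted via [volvox_intrinsic()]).
#' @param model \code{"large_bending"} or \code{"classical"}; defaults to
#'   the scenario's model when \code{intrinsic} is a
#'   \code{scenario_params}, else to \code{"large_bending"}.
#' @param init \code{NULL} (identity embedding), a
#'   \code{midsurface_shape}, or a previous \code{shell_equilibrium}
#'   (natural homotopy for parameter sweeps).
#' @param control a [shell_control()] list.
#' @return an object of class \code{shell_equilibrium} with elements
#'   \code{shape} (the deformed midsurface), \code{strains}, \code{energy}
#'   (integrated breakdown, units \eqn{C R^3}), \code{d} (posterior-pole
#'   displacement, positive for invagination), \code{diagnostics} and the
#'   inputs.
#' @examples
#' \donttest{
#' fit <- shell_equilibrium(shell_preset("fig5a"))
#' fit$d
#' }
#' @export
shell_equilibrium <- function(intrinsic, model = NULL, init = NULL,
                              control = shell_control()) {
  cl <- match.call()
  if (inherits(intrinsic, "scenario_params")) {
    if (is.null(model)) model <- intrinsic$model
    intrinsic <- volvox_intrinsic(intrinsic)
  }
  if (is.null(model)) model <- "large_bending"
  model <- match.arg(model, c("large_bending", "classical"))
  max_eta <- max(abs(intrinsic$eta))
  if (model == "large_bending" && max_eta > 1 - control$eta_margin) {
    if (control$allow_constriction)
      warning("intrinsic configuration close to the constriction limit ",
              "(max |eta| = ", format(max_eta), "); proceeding")
    else
      stop("constriction limit: max |eta| = ", format(max_eta),
           " exceeds 1 - eta_margin = ", format(1 - control$eta_margin),
           "; the large-bending theory loses asymptoticity there ",
           "(set allow_constriction = TRUE to override)")
  }
  sp <- .eq_setup(intrinsic, model)
  x0 <- .eq_init(init, sp)
  fit <- .solve_al(sp, x0, control)
  if (!fit$converged)
    warning("solver did not reach the requested tolerances ",
            "(gradient norm ", format(fit$grad_norm), ", closure ",
            format(fit$ev$closure), "); returning last iterate")
  fl <- fit$ev$fields
  shape <- shape_from_tangent_fields(fl$psi, fl$fs, sp$ref,
                                     closure_tol = Inf)
  strains <- shell_strains(shape, intrinsic, sp$ref)
  # energy breakdown on the solver's own quadrature (matches objective)
  dens <- energy_density(
    strain_field(fit$ev$strains$es, fit$ev$strains$eph,
                 fit$ev$strains$Ks, fit$ev$strains$Kp,
                 eta = sp$eta, t = sp$t),
    t = sp$t, model = model)
  energy <- c(stretch = sum(sp$u * dens$stretch),
              couple = sum(sp$u * dens$couple),
              bend = sum(sp$u * dens$bend),
              total = sum(sp$u * dens$total))
  out <- list(shape = shape, strains = strains, energy = energy,
              d = fit$ev$d, model = model, intrinsic = intrinsic,
              control = control, call = cl,
              solver = list(x = fit$x, lam1 = fit$lam1, setup_model = model),
              diagnostics = list(gradient_norm = fit$grad_norm,
                                 iterations = fit$iterations,
                                 max_eta = max_eta,
                                 closure = fit$ev$closure,
                                 converged = fit$converged,
                                 objective = fit$ev$energy))
  class(out) <- "shell_equilibrium"
  out
}

#' Posterior-pole displacement
#'
#' Displacement \eqn{d} of the posterior pole (\eqn{s = 0}) along the
#' symmetry axis, in the anterior-pole-fixed gauge, signed so that
#' invagination (the posterior pole moving toward the anterior) gives
#' \eqn{d > 0}.  Equivalently \eqn{d = 2R - \int_0^{\pi R} \tilde f_s
#' \sin\tilde\psi\, ds}, which is manifestly invariant under rigid axial
#' translation.
#'
#' @param solution a \code{shell_equilibrium} or a
#'   \code{midsurface_shape}.
#' @param reference undeformed shape (defaults to the unit sphere).
#' @return scalar displacement in units of R.
#' @export
pole_displacement <- function(solution, reference = NULL) {
  if (inherits(solution, "shell_equilibrium")) return(solution$d)
  stopifnot(inherits(solution, "midsurface_shape"))
  h <- solution$s[2] - solution$s[1]
  w <- .simpson_weights(nrow(solution), h)
  2 - sum(w * solution$stretch_s * sin(solution$psi))
}

#' @export
print.shell_equilibrium <- function(x, ...) {
  cat("Morphoelastic shell equilibrium (", x$model, " model)\n", sep = "")
  cat(sprintf("  n = %d, energy = %.6g C R^3, d = %.5g R\n",
              nrow(x$shape), x$energy["total"], x$d))
  cat(sprintf("  max |eta| = %.3g, closure = %.2e, grad norm = %.2e%s\n",
              x$diagnostics$max_eta, x$diagnostics$closure,
              x$diagnostics$gradient_norm,
              if (x$diagnostics$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.shell_equilibrium <- function(object, ...) {
  out <- list(model = object$model, energy = object$energy, d = object$d,
              diagnostics = object$diagnostics,
              strain_ranges = vapply(
                object$strains[c("es", "ephi", "Ks", "Kphi")],
                range, numeric(2)))
  class(out) <- "summary.shell_equilibrium"
  out
}

#' @export
print.summary.shell_equilibrium <- function(x, ...) {
  cat("Equilibrium summary (", x$model, " model)\n", sep = "")
  cat("  energy breakdown (C R^3):\n")
  print(signif(x$energy, 6))
  cat(sprintf("  pole displacement d = %.5g R\n", x$d))
  cat("  strain ranges:\n")
  print(signif(x$strain_ranges, 4))
  cat(sprintf("  iterations %d, gradient norm %.2e, closure %.2e\n",
              x$diagnostics$iterations, x$diagnostics$gradient_norm,
              x$diagnostics$closure))
  invisible(x)
}

#' @export
coef.shell_equilibrium <- function(object, ...) {
  c(d = unname(object$d), object$energy,
    max_eta = object$diagnostics$max_eta)
}

#' @export
plot.shell_equilibrium <- function(x, ...) {
  ref <- undeformed_sphere(n_grid = nrow(x$shape))
  plot(x$shape$r, x$shape$z, type = "l", asp = 1,
       xlab = "r / R", ylab = "z / R",
       main = paste("shell equilibrium,", x$model), ...)
  lines(ref$r, ref$z, lty = 3)
  invisible(x)
}
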