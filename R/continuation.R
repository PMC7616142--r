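# Continuation of equilibrium branches in the (k, d) plane, where
# k = -kappa_b is the magnitude of the intrinsic bend-region curvature and
# d the posterior-pole displacement.
#
# The tracer works in three phases.  (1) A natural up-sweep in k with
# adaptive steps follows the stable branch; a displacement jump that
# persists when the k-step has been refined to its minimum is the
# signature of a fold (saddle-node) — the discontinuous jump in d that a
# natural sweep produces.  (2) If a jump occurred, a mirrored down-sweep
# from the post-jump state follows the upper stable branch back to the
# second fold, where the reverse jump — or a smooth merge with the lower
# branch, when the reverse jump is below the detector's resolution — is
# located.  (3) The unstable middle segment connecting the two folds is
# traced in k: at each k inside the bistable window the unstable
# displacement is bisected between the two stable ones using the sign
# change of the displacement-constraint multiplier (= -dE/dd*), which
# vanishes at every genuine equilibrium.  Folds are reported at the
# jump/merge locations, refined by the middle segment's k extremes.

#' Continuation options
#'
#' @param k_step,k_step_min,k_step_max initial and bounding k increments
#'   for the natural sweeps.
#' @param jump_tol displacement change per k-step that, persisting at the
#'   minimal k increment, is classified as a discontinuous jump (fold).
#' @param d_max stop once the pole displacement exceeds this value.
#' @param max_points cap on branch points per sweep.
#' @param nu_tol tolerance on the displacement-constraint multiplier
#'   (energy slope |dE/dd|) for middle-segment points.
#' @param middle logical: traverse the unstable middle segment through the
#'   fold region (adds the S interior); fold detection and jump
#'   annotation do not require it.
#' @param n_grid arclength resolution for continuation solves.  The
#'   default resolves the profile-smoothing width delta = 0.05 with about
#'   four grid cells.
#' @return list of options.
#' @export
branch_control <- function(k_step = 0.15, k_step_min = 0.02,
                           k_step_max = 0.4, jump_tol = 0.05,
                           d_max = 2, max_points = 250,
                           nu_tol = 1e-6, middle = TRUE, n_grid = 241) {
  list(k_step = k_step, k_step_min = k_step_min, k_step_max = k_step_max,
       jump_tol = jump_tol, d_max = d_max,
       max_points = max_points, nu_tol = nu_tol, middle = middle,
       n_grid = as.integer(n_grid))
}

#' Continue an equilibrium branch in the bend curvature k
#'
#' Traces the branch of equilibrium shapes as the intrinsic bend-region
#' curvature magnitude \eqn{k = -\kappa_b} is swept, recording the
#' posterior-pole displacement \eqn{d}.  Where \eqn{d(k)} is multivalued
#' (S-shaped branch) the natural sweep jumps discontinuously at a fold;
#' both folds are located from the forward and reverse jumps, annotated,
#' and the unstable segment connecting them is traced (bisection of the
#' unstable displacement at fixed k) when \code{branch$middle} is
#' \code{TRUE}.  Under the
#' large-bending model the sweep stops where the intrinsic configuration
#' approaches the constriction limit (\eqn{|\eta| = 1} corresponds to
#' \eqn{k = 2 g^0/(\epsilon h)} in the bend region).
#'
#' @param params a \code{scenario_params}; \code{kappa_b} is overridden by
#'   the sweep.
#' @param k_range numeric length-2: sweep start and upper bound for k.
#' @param model energy model; defaults to \code{params$model}.
#' @param control solver control ([shell_control()]).
#' @param branch continuation options ([branch_control()]).
#' @param verbose print one line per accepted branch point.
#' @return a \code{shell_branch} data frame with columns \code{k, d,
#'   energy_total, max_eta, fold_flag, segment}, and attributes
#'   \code{folds} (fold locations), \code{jumps} (discontinuous jumps in
#'   d under natural k sweeps), \code{truncated} (reason or NA) and
#'   \code{k_eta_cap}.
#' @export
continue_branch <- function(params, k_range = c(1, 10.5), model = NULL,
                            control = shell_control(),
                            branch = branch_control(), verbose = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  if (is.null(model)) model <- params$model
  model <- match.arg(model, c("large_bending", "classical"))
  # branch tracing needs d to ~1e-3; relax the stationarity report
  # threshold accordingly (solves near the constriction cap are stiff)
  control$grad_tol <- max(control$grad_tol, 1e-4)
  s_grid <- seq(0, pi, length.out = branch$n_grid)

  make_sp <- function(k) {
    p <- params; p$kappa_b <- -k; p$model <- model
    .eq_setup(volvox_intrinsic(p, s_grid), model)
  }
  eta_of_k <- function(k) {
    p <- params; p$kappa_b <- -k
    max(abs(volvox_intrinsic(p, s_grid)$eta))
  }
  k_eta_cap <- if (model == "large_bending") {
    stats::uniroot(function(k) eta_of_k(k) - (1 - control$eta_margin),
                   c(min(1, k_range[1]), 4 * k_range[2]),
                   extendInt = "upX")$root
  } else Inf
  k_hi <- min(k_range[2], k_eta_cap)

  nat_eval <- function(k, x0, lam1_0) {
    spk <- make_sp(k)
    fit <- .solve_al(spk, x0, control, lam1 = lam1_0)
    fit$sp <- spk
    fit
  }
  row_of <- function(k, d, fit, segment) {
    data.frame(k = k, d = d, energy_total = fit$ev$energy,
               max_eta = max(abs(fit$sp$eta)), fold_flag = FALSE,
               segment = segment)
  }

  # adaptive natural sweep from a solved state; returns accepted rows,
  # the first jump (if any) and the final state
  sweep_k <- function(k_from, d_from, x, lam1, k_to, segment,
                      stop_at_jump = FALSE) {
    dir <- sign(k_to - k_from)
    kstep <- branch$k_step
    rows <- NULL; jump <- NULL
    k_cur <- k_from; d_cur <- d_from
    truncated <- NA_character_
    while (is.null(rows) || nrow(rows) < branch$max_points) {
      if (dir * (k_to - k_cur) < 1e-9) break
      k_try <- if (dir > 0) min(k_cur + kstep, k_to) else
        max(k_cur - kstep, k_to)
      fit <- nat_eval(k_try, x, lam1)
      dd <- fit$ev$d - d_cur
      if (!fit$converged || abs(dd) > branch$jump_tol) {
        if (kstep / 2 >= branch$k_step_min) { kstep <- kstep / 2; next }
        if (!fit$converged) { truncated <- "solver failure"; break }
        # jump persists at the minimal k increment: fold of the branch
        if (is.null(jump)) {
          jump <- list(k = k_cur, d_from = d_cur, d_to = fit$ev$d,
                       x_pre = x, lam1_pre = lam1)
          if (verbose)
            cat(sprintf("  jump at k = %.4f: d %.4f -> %.4f\n",
                        k_cur, d_cur, fit$ev$d))
          if (stop_at_jump) break
        }
      }
      rows <- rbind(rows, row_of(k_try, fit$ev$d, fit, segment))
      if (verbose)
        cat(sprintf("  k = %.5f  d = %.4f  E = %.5e\n",
                    k_try, fit$ev$d, fit$ev$energy))
      x <- fit$x; lam1 <- fit$lam1
      k_cur <- k_try; d_cur <- fit$ev$d
      if (abs(dd) < 0.3 * branch$jump_tol)
        kstep <- min(kstep * 1.5, branch$k_step_max)
      if (d_cur > branch$d_max) { truncated <- "displacement cap"; break }
    }
    list(rows = rows, jump = jump, x = x, lam1 = lam1,
         k = k_cur, d = d_cur, truncated = truncated)
  }

  # ---- phase 1: natural up-sweep ----
  sp <- make_sp(k_range[1])
  st <- .solve_al(sp, .eq_init(NULL, sp), control)
  st$sp <- sp
  first <- row_of(k_range[1], st$ev$d, st, "lower")
  up <- sweep_k(k_range[1], st$ev$d, st$x, st$lam1, k_hi, "lower")
  rows <- rbind(first, up$rows)
  truncated <- up$truncated
  if (is.na(truncated) && up$k >= k_eta_cap - 1e-8)
    truncated <- "constriction limit"
  jump_up <- up$jump
  jump_dn <- NULL
  middle_rows <- NULL

  if (!is.null(jump_up)) {
    rows$segment[rows$d > jump_up$d_from + 1e-12] <- "upper"
    # ---- phase 2: reverse sweep along the upper branch from the end of
    # the up-sweep back toward the start, stopping at the reverse jump ----
    dn <- sweep_k(up$k, up$d, up$x, up$lam1, k_range[1], "upper",
                  stop_at_jump = TRUE)
    jump_dn <- dn$jump
    if (!is.null(dn$rows)) {
      # near the second fold the reverse jump can be smaller than
      # jump_tol: the descending sweep then slides back onto the lower
      # branch smoothly.  Detect the merge point and treat it as the
      # reverse fold location.
      lower <- rows[rows$segment == "lower", ]
      if (is.null(jump_dn) && nrow(lower) >= 2) {
        d_low <- stats::approx(lower$k, lower$d, xout = dn$rows$k,
                               rule = 2, ties = "ordered")$y
        merged <- which(abs(dn$rows$d - d_low) <
                          pmax(2e-3, 0.01 * abs(d_low)))
        if (length(merged)) {
          j <- merged[1]
          jump_dn <- list(k = dn$rows$k[j], d_from = dn$rows$d[j],
                          d_to = d_low[j])
          dn$rows <- dn$rows[seq_len(j), , drop = FALSE]
        }
      }
      k_covered <- min(rows$k[rows$segment == "upper"])
      keep <- dn$rows$k < k_covered - 1e-9
      if (any(keep)) rows <- rbind(rows, dn$rows[keep, ])
    }
    # ---- phase 3: unstable middle segment between the folds ----
    if (isTRUE(branch$middle) && !is.null(jump_dn)) {
      middle_rows <- .trace_middle(jump_up, jump_dn, rows, make_sp,
                                   control, branch, verbose)
    }
  }

  rows <- .assemble_branch(rows, middle_rows, jump_up, jump_dn)
  attr(rows, "params") <- params
  attr(rows, "model") <- model
  attr(rows, "truncated") <- truncated
  attr(rows, "k_eta_cap") <- k_eta_cap
  class(rows) <- c("shell_branch", class(rows))
  rows
}

# traversal of the unstable segment between the two folds.  At fixed k
# inside the bistable window the energy restricted to the displacement
# slice has its two stable equilibria at the lower- and upper-branch
# displacements; the unstable middle equilibrium sits between them, where
# the displacement-constraint multiplier (-dE/dd) changes sign.  For each
# k the middle displacement is found by bisection on that multiplier
# between the stable displacements; k decreases from the forward fold to
# the reverse one, which is the branch order of the middle segment (d
# need not be monotone along it).
.trace_middle <- function(jump_up, jump_dn, rows, make_sp, control,
                          branch, verbose = FALSE) {
  k_lo <- jump_dn$k; k_hi <- jump_up$k
  if (!(k_lo < k_hi)) return(NULL)
  lower <- rows[rows$segment == "lower", ]
  upper <- rows[rows$segment == "upper", ]
  if (nrow(lower) < 2 || nrow(upper) < 2) return(NULL)
  ks <- seq(k_hi, k_lo, length.out = max(4, ceiling((k_hi - k_lo) / 0.15)))
  ks <- ks[ks > k_lo + 1e-9 & ks < k_hi - 1e-9]
  if (!length(ks)) return(NULL)
  nu_eval <- function(k, d_target, x0, lam1_0, lam2_0) {
    .solve_al(make_sp(k), x0, control, d_target = d_target,
              lam1 = lam1_0, lam2 = lam2_0)
  }
  x <- jump_up$x_pre; lam1 <- jump_up$lam1_pre; lam2 <- 0
  out <- NULL
  # saddle continuity: the unstable displacement emerges from the forward
  # fold and is tracked k-step by k-step, bracketing around its previous
  # location rather than blindly across the whole bistable gap (the
  # multiplier can have spurious discontinuities at basin boundaries of
  # the constrained problem)
  d_prev <- jump_up$d_from
  for (k in ks) {
    d_l <- stats::approx(lower$k, lower$d, xout = k, rule = 2,
                         ties = "ordered")$y
    d_u <- stats::approx(upper$k, upper$d, xout = k, rule = 2,
                         ties = "ordered")$y
    gap <- d_u - d_l
    if (!is.finite(gap) || gap < 6e-3) next
    lo <- max(d_l + 0.05 * gap, d_prev - 0.3 * gap)
    hi <- min(d_u - 0.05 * gap, d_prev + 0.3 * gap)
    if (hi <= lo) { lo <- d_l + 0.05 * gap; hi <- d_u - 0.05 * gap }
    bracket <- c(lo, hi)
    f_lo <- nu_eval(k, bracket[1], x, lam1, lam2)
    f_hi <- nu_eval(k, bracket[2], f_lo$x, f_lo$lam1, f_lo$lam2)
    if (sign(f_lo$lam2) * sign(f_hi$lam2) >= 0) {
      # widen once to the full gap
      bracket <- c(d_l + 0.05 * gap, d_u - 0.05 * gap)
      f_lo <- nu_eval(k, bracket[1], f_lo$x, f_lo$lam1, f_lo$lam2)
      f_hi <- nu_eval(k, bracket[2], f_lo$x, f_lo$lam1, f_lo$lam2)
      if (!is.finite(f_lo$lam2) || !is.finite(f_hi$lam2) ||
          sign(f_lo$lam2) * sign(f_hi$lam2) >= 0) next
    }
    fm <- f_lo
    for (it in 1:14) {
      dm <- mean(bracket)
      fm <- nu_eval(k, dm, fm$x, fm$lam1, fm$lam2)
      if (abs(fm$lam2) < branch$nu_tol || diff(bracket) < 2e-4) break
      if (sign(fm$lam2) == sign(f_lo$lam2)) {
        bracket[1] <- dm; f_lo <- fm
      } else bracket[2] <- dm
    }
    # accept only genuine stationary points, not basin-boundary
    # discontinuities of the constrained multiplier
    if (abs(fm$lam2) > 1e2 * branch$nu_tol) next
    spk <- make_sp(k)
    out <- rbind(out, data.frame(k = k, d = mean(bracket),
                                 energy_total = fm$ev$energy,
                                 max_eta = max(abs(spk$eta)),
                                 fold_flag = FALSE, segment = "middle"))
    if (verbose)
      cat(sprintf("  [middle] k = %.5f  d = %.4f\n", k, mean(bracket)))
    x <- fm$x; lam1 <- fm$lam1; lam2 <- fm$lam2
    d_prev <- mean(bracket)
  }
  out
}

# order the collected points along the branch (lower by d, middle by d,
# upper by d) and annotate folds and jumps
.assemble_branch <- function(rows, middle_rows, jump_up, jump_dn) {
  # lower segment stays in sweep order (d is nearly flat there, so
  # ordering by d would scramble it); the stable upper segment is ordered
  # by k, its branch direction
  lower <- rows[rows$segment == "lower", , drop = FALSE]
  upper <- rows[rows$segment == "upper", , drop = FALSE]
  upper <- upper[order(upper$k), , drop = FALSE]
  out <- rbind(lower, middle_rows, upper)
  # folds live at the detected jumps: the forward jump marks the k-maximum
  # of the lower stable segment, the reverse jump the k-minimum of the
  # upper one.  The middle segment, when traced, refines them by its
  # extremal k values.
  folds <- data.frame(k = numeric(0), d = numeric(0), type = character(0))
  if (!is.null(jump_up)) {
    k_max <- jump_up$k; d_max_fold <- jump_up$d_from
    if (!is.null(middle_rows) && nrow(middle_rows)) {
      i <- which.max(middle_rows$k)
      if (middle_rows$k[i] > k_max) {
        k_max <- middle_rows$k[i]; d_max_fold <- middle_rows$d[i]
      }
    }
    folds <- rbind(folds, data.frame(k = k_max, d = d_max_fold,
                                     type = "max"))
    i_flag <- which.min(abs(out$d - d_max_fold) + abs(out$k - k_max))
    out$fold_flag[i_flag] <- TRUE
  }
  if (!is.null(jump_dn)) {
    k_min <- jump_dn$k; d_min_fold <- jump_dn$d_from
    if (!is.null(middle_rows) && nrow(middle_rows)) {
      i <- which.min(middle_rows$k)
      if (middle_rows$k[i] < k_min) {
        k_min <- middle_rows$k[i]; d_min_fold <- middle_rows$d[i]
      }
    }
    folds <- rbind(folds, data.frame(k = k_min, d = d_min_fold,
                                     type = "min"))
    i_flag <- which.min(abs(out$d - d_min_fold) + abs(out$k - k_min))
    out$fold_flag[i_flag] <- TRUE
  }
  jumps <- NULL
  if (!is.null(jump_up))
    jumps <- data.frame(sweep = "up", k = jump_up$k,
                        d_from = jump_up$d_from, d_to = jump_up$d_to)
  if (!is.null(jump_dn))
    jumps <- rbind(jumps,
                   data.frame(sweep = "down", k = jump_dn$k,
                              d_from = jump_dn$d_from, d_to = jump_dn$d_to))
  attr(out, "folds") <- folds
  attr(out, "jumps") <- jumps
  out
}

#' @export
print.shell_branch <- function(x, ...) {
  folds <- attr(x, "folds")
  cat("Equilibrium branch (", attr(x, "model"), " model): ",
      nrow(x), " points, k in [", format(min(x$k)), ", ",
      format(max(x$k)), "], d in [", format(min(x$d)), ", ",
      format(max(x$d)), "]\n", sep = "")
  if (nrow(folds) == 0) {
    cat("  single-valued: no folds detected\n")
  } else {
    cat("  folds (saddle-node points):\n")
    print(folds, row.names = FALSE)
  }
  jumps <- attr(x, "jumps")
  if (!is.null(jumps)) {
    cat("  discontinuous jumps in d under natural k sweeps:\n")
    print(jumps, row.names = FALSE)
  }
  if (!is.na(attr(x, "truncated")))
    cat("  truncated:", attr(x, "truncated"), "\n")
  invisible(x)
}

#' @export
plot.shell_branch <- function(x, ...) {
  plot(x$k, x$d, type = "p", pch = 20, cex = 0.6,
       xlab = "k = -kappa_b", ylab = "d / R", ...)
  for (seg in unique(x$segment))
    lines(x$k[x$segment == seg], x$d[x$segment == seg])
  folds <- attr(x, "folds")
  if (nrow(folds)) points(folds$k, folds$d, pch = 4, col = 2, cex = 1.4)
  invisible(x)
}

#' Critical bend-region width for fold onset
#'
#' Bisection on the bend-region width w for the appearance of a fold
#' (saddle-node) in the \eqn{(k, d)} equilibrium branch.  Below the
#' critical width the response \eqn{d(k)} is single-valued and
#' invagination proceeds continuously as the bend curvature grows; above
#' it the branch is S-shaped and natural sweeps of k produce discontinuous
#' jumps in d.  The large-bending critical width exceeds the classical
#' one: the geometry of large bending stabilizes invagination.
#'
#' Fold presence is decided by the natural-sweep jump detector of
#' [continue_branch()] (a displacement jump persisting at the minimal
#' k-step); the middle-segment traversal is disabled for speed.
#'
#' @param params scenario parameters (width overridden by the bisection).
#' @param w_interval numeric length-2 bracketing the onset (no fold at the
#'   lower end, fold at the upper end — checked).
#' @param model energy model.
#' @param tol bisection tolerance on w.
#' @param k_range,control,branch passed to [continue_branch()].
#' @param verbose print one line per bisection step.
#' @return the critical width (midpoint of the final bracket), with the
#'   bracket in attribute \code{"bracket"}.
#' @export
critical_width <- function(params, w_interval = c(0.3, 0.9), model = NULL,
                           tol = 0.05, k_range = c(1, 10.5),
                           control = shell_control(),
                           branch = branch_control(), verbose = FALSE) {
  if (is.null(model)) model <- params$model
  branch$middle <- FALSE
  branch$d_max <- min(branch$d_max, 1.2)
  has_fold <- function(w) {
    p <- params; p$w <- w
    br <- continue_branch(p, k_range = k_range, model = model,
                          control = control, branch = branch)
    nrow(attr(br, "folds")) > 0
  }
  lo <- w_interval[1]; hi <- w_interval[2]
  if (has_fold(lo)) stop("no bracket: fold already present at w = ", lo)
  if (!has_fold(hi)) stop("no bracket: no fold found at w = ", hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- has_fold(mid)
    if (verbose) cat(sprintf("  w = %.4f: %s\n", mid,
                             if (fm) "folded" else "single-valued"))
    if (fm) hi <- mid else lo <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  out
}
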