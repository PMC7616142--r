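# Equilibrium solver: ground states, stationarity, convergence, gauge

test_that("identity scenario recovers the undeformed sphere", {
  fit <- shell_equilibrium(shell_preset("identity"))
  expect_lt(fit$energy["total"], 1e-8)
  expect_lt(abs(fit$d), 1e-3)
  ref <- undeformed_sphere(n_grid = nrow(fit$shape))
  expect_lt(max(abs(fit$shape$r - ref$r)), 1e-4)
  expect_lt(abs(fit$diagnostics$closure), 1e-8)
  expect_true(fit$diagnostics$converged)
})

test_that("compatible intrinsic sphere relaxes to its stress-free
          embedding", {
  fit <- shell_equilibrium(compatible_sphere_intrinsic(1.2))
  expect_lt(fit$energy["total"], 1e-8)
  ref <- undeformed_sphere(n_grid = nrow(fit$shape))
  inner <- 30:370
  expect_lt(max(rel_err(fit$shape$r[inner], 1.2 * ref$r[inner])), 1e-4)
  expect_lt(max(rel_err(fit$shape$stretch_s, 1.2)), 1e-4)
})

test_that("solutions are stationary points of the discretized energy", {
  p <- shell_preset("fig5a"); p$n_grid <- 121L
  fit <- shell_equilibrium(p)
  sp <- morphoshell:::.eq_setup(fit$intrinsic, fit$model)
  ev <- morphoshell:::.eq_objective(fit$solver$x, sp,
                                    lam1 = fit$solver$lam1, rho = 0)
  set.seed(3)
  for (i in 1:20) {
    u <- rnorm(length(ev$grad))
    u <- u / sqrt(sum(u^2))
    expect_lt(abs(sum(ev$grad * u)), 10 * fit$control$grad_tol)
  }
})

test_that("energy breakdown integrates exactly to the minimized
          objective", {
  fit <- shell_equilibrium(shell_preset("fig5a"))
  expect_equal(unname(fit$energy["total"]), fit$diagnostics$objective,
               tolerance = 1e-12)
  expect_equal(unname(fit$energy["total"]),
               unname(fit$energy["stretch"] + fit$energy["couple"] +
                        fit$energy["bend"]),
               tolerance = 1e-12)
})

test_that("early-invagination models agree closely; classical invaginates
          more at the later stage", {
  fa <- shell_equilibrium(shell_preset("fig5a"), model = "large_bending")
  fc <- shell_equilibrium(shell_preset("fig5a"), model = "classical")
  expect_lt(rel_err(fa$d, fc$d), 0.05)
  fdL <- shell_equilibrium(shell_preset("fig5d"), model = "large_bending")
  fdC <- shell_equilibrium(shell_preset("fig5d"), model = "classical")
  expect_gt(fdC$d, fdL$d)
  expect_equal(fdL$diagnostics$max_eta, 0.797, tolerance = 1e-2)
})

test_that("models agree to under 1% in the small-bending regime", {
  p <- scenario_params(kappa_b = -1.5, f_p = 0.9, w = 0.4, eps_h = 0.05)
  expect_lt(max(abs(volvox_intrinsic(p)$eta)), 0.05)
  dl <- shell_equilibrium(p, model = "large_bending")$d
  dc <- shell_equilibrium(p, model = "classical")$d
  expect_lt(abs(dl - dc) / abs(dl), 0.01)
})

test_that("pole displacement halves under doubled resolution stay within
          0.5%", {
  p <- shell_preset("fig5a")
  p$n_grid <- 201L
  d1 <- shell_equilibrium(p)$d
  p$n_grid <- 401L
  d2 <- shell_equilibrium(p)$d
  expect_lt(rel_err(d1, d2), 0.005)
})

test_that("pole displacement is a gauge-invariant functional", {
  fit <- shell_equilibrium(shell_preset("fig5a"))
  sh <- fit$shape
  expect_equal(pole_displacement(sh), fit$d, tolerance = 1e-10)
  translated <- sh
  translated$z <- sh$z + 0.37      # rigid translation along the axis
  expect_equal(pole_displacement(translated), pole_displacement(sh))
  expect_lt(abs(pole_displacement(undeformed_sphere(n_grid = 201))), 1e-8)
})

test_that("solver refuses configurations at the constriction limit", {
  p <- scenario_params(kappa_b = -11, w = 0.5)      # |eta| beyond 1
  expect_error(shell_equilibrium(p, model = "large_bending"),
               "constriction")
  # inside the guard band but beyond the asymptoticity margin the
  # refusal is overridable with a warning
  p2 <- scenario_params(kappa_b = -10.5, w = 0.5)   # max |eta| ~ 0.984
  expect_error(shell_equilibrium(p2, model = "large_bending"),
               "constriction")
  w <- capture_warnings(
    shell_equilibrium(p2, model = "large_bending",
                      control = shell_control(allow_constriction = TRUE,
                                              maxit = 200,
                                              outer_max = 3)))
  expect_true(any(grepl("constriction", w)))
  # the classical model has no eta restriction
  fitc <- suppressWarnings(
    shell_equilibrium(p, model = "classical",
                      control = shell_control(maxit = 400,
                                              outer_max = 4)))
  expect_s3_class(fitc, "shell_equilibrium")
})

test_that("the solve is deterministic given the initial shape", {
  p <- shell_preset("fig5a"); p$n_grid <- 121L
  f1 <- shell_equilibrium(p)
  f2 <- shell_equilibrium(p)
  expect_identical(f1$d, f2$d)
  expect_identical(f1$energy, f2$energy)
  # warm start from a previous solution is accepted
  f3 <- shell_equilibrium(p, init = f1)
  expect_equal(f3$d, f1$d, tolerance = 1e-6)
})

test_that("solution methods print, summarize and expose coefficients", {
  p <- shell_preset("identity"); p$n_grid <- 121L
  fit <- shell_equilibrium(p)
  expect_output(print(fit), "equilibrium")
  expect_output(print(summary(fit)), "breakdown")
  co <- coef(fit)
  expect_true(all(c("d", "total", "max_eta") %in% names(co)))
})
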