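# Coefficient functions of the quadratic energy form and k(eta)

test_that("classical-limit anchors and closed-form values are exact", {
  cf0 <- shell_coefficients(0)
  expect_equal(cf0$alpha_bar_ss, 4)
  expect_equal(cf0$alpha_bar_sphi, 2)
  expect_equal(cf0$alpha_bar_phis, 2)
  expect_equal(cf0$alpha_ss, 4)
  expect_equal(cf0$alpha_sphi, 2)
  expect_equal(cf0$alpha_phiphi, 4)
  expect_equal(cf0$gamma_ss, 1 / 3)
  expect_equal(cf0$gamma_sphi, 1 / 6)
  expect_equal(cf0$gamma_phiphi, 1 / 3)
  for (nm in c("beta_ss", "beta_sphi", "beta_phis", "beta_phiphi",
               "beta_bar_ss", "beta_bar_sphi"))
    expect_equal(cf0[[nm]], 0, info = nm)
  # closed form away from zero
  expect_equal(shell_coefficients(0.5)$alpha_bar_ss, 64 / 9,
               tolerance = 1e-12)
  expect_equal(shell_coefficients(0.5)$alpha_bar_sphi, 32 / 9,
               tolerance = 1e-12)
})

test_that("symmetric pairs are identical and all fields stay finite", {
  eta <- c(eta_grid(0.07), 0.999, -0.999, 1 - 1e-6, -(1 - 1e-6))
  cf <- shell_coefficients(eta)
  expect_identical(cf$alpha_sphi, cf$alpha_phis)
  expect_identical(cf$gamma_sphi, cf$gamma_phis)
  expect_identical(cf$alpha_bar_sphi, cf$alpha_bar_phis)
  expect_true(all(vapply(cf, function(x) all(is.finite(x)), logical(1))))
  expect_error(shell_coefficients(1 - 1e-8), "constriction")
  expect_error(shell_coefficients(1.2), "constriction")
})

test_that("stretching-form discriminant equals -48/(1-eta^2)^2", {
  eta <- eta_grid(0.02)
  cf <- shell_coefficients(eta)
  disc <- (cf$alpha_bar_sphi + cf$alpha_bar_phis)^2 -
    4 * cf$alpha_bar_ss * cf$alpha_phiphi
  expect_lt(max(rel_err(disc, -48 / (1 - eta^2)^2)), 1e-9)
  # bending form negative discriminant: positive definite bending energy
  bdisc <- (cf$gamma_sphi + cf$gamma_phis)^2 -
    4 * cf$gamma_ss * cf$gamma_phiphi
  expect_true(all(bdisc < 0))
})

test_that("series and closed-form branches agree across the switch", {
  # evaluation switches branches at |eta| = 1e-2; both must agree in a
  # window around it, and with the independent series oracle
  eta <- c(seq(-0.03, -0.008, by = 0.002), seq(0.008, 0.03, by = 0.002))
  cf <- shell_coefficients(eta)
  for (nm in setdiff(names(cf), c("eta", "alpha_phis", "gamma_phis",
                                  "alpha_bar_phis"))) {
    ser <- coefficient_series(nm, 12)
    oracle <- vapply(eta, function(e) sum(ser * e^(0:12)), numeric(1))
    expect_lt(max(abs(cf[[nm]] - oracle) / pmax(abs(oracle), 1)), 1e-9)
  }
})

test_that("coefficients have the parity of the series oracle", {
  eta <- seq(0.05, 0.9, by = 0.05)
  p <- shell_coefficients(eta)
  m <- shell_coefficients(-eta)
  even <- c("alpha_ss", "alpha_sphi", "alpha_phiphi", "gamma_ss",
            "gamma_sphi", "gamma_phiphi", "alpha_bar_ss", "alpha_bar_sphi")
  odd <- c("beta_ss", "beta_sphi", "beta_phis", "beta_phiphi",
           "beta_bar_ss", "beta_bar_sphi")
  for (nm in even)
    expect_lt(max(rel_err(m[[nm]], p[[nm]])), 1e-12)
  for (nm in odd)
    expect_lt(max(rel_err(m[[nm]], -p[[nm]])), 1e-12)
  # the oracle's expansions have matching parity structure
  for (nm in even)
    expect_true(all(coefficient_series(nm, 11)[c(2, 4, 6, 8, 10, 12)] == 0))
  for (nm in odd)
    expect_true(all(coefficient_series(nm, 12)[c(1, 3, 5, 7, 9, 11, 13)] == 0))
})

test_that("series oracle reproduces hand-derived expansion terms", {
  expect_equal(coefficient_series("gamma_ss", 2), c(1 / 3, 0, 13 / 20))
  expect_equal(coefficient_series("beta_phis", 1), c(0, -5 / 6))
  expect_equal(coefficient_series("alpha_ss", 0), 4)
  expect_equal(coefficient_series("k_eta", 0), 13 / 5)
  expect_error(coefficient_series("nope"), "unknown")
})

test_that("k(eta) interpolates between 13/5 and 3", {
  expect_equal(k_eta(0), 13 / 5)
  expect_equal(k_eta(c(-1, 1)), c(3, 3))
  eta <- seq(-0.999, 0.999, by = 0.007)
  k <- k_eta(eta)
  expect_true(all(k > 13 / 5 - 1e-12 & k < 3))
  expect_gt(k_eta(0.5), 13 / 5)
  expect_lt(k_eta(0.5), 3)
  # even in eta, and increasing in |eta|
  expect_equal(k_eta(-0.3), k_eta(0.3), tolerance = 1e-13)
  expect_true(all(diff(k_eta(seq(0, 1, by = 0.01))) > 0))
  # series/closed-form consistency around the branch switch at 0.08
  e <- c(0.07, 0.075, 0.085, 0.09)
  ser <- coefficient_series("k_eta", 12)
  expect_lt(max(abs(k_eta(e) -
                      vapply(e, function(x) sum(ser * x^(0:12)),
                             numeric(1)))), 1e-10)
  expect_error(k_eta(1.01), "admissible")
})

test_that("divergence scaling removes the (1-|eta|)^-2 blow-up", {
  # scaled alpha_bar_ss = 4/(1+eta)^2 stays bounded and tends to 1
  s1 <- divergence_scaled_set(0.999)
  s2 <- divergence_scaled_set(0.9999)
  expect_lt(rel_err(s1$alpha_bar_ss, s2$alpha_bar_ss), 0.01)
  expect_equal(s2$alpha_bar_ss, 4 / (1 + 0.9999)^2, tolerance = 1e-10)
  expect_equal(s2$alpha_bar_ss, 1, tolerance = 2e-4)
  # at moderate eta the scaling is just the (1-|eta|)^2 factor
  expect_equal(as.numeric(divergence_scaled_set(0.5)[1, -1]),
               as.numeric(shell_coefficients(0.5)[1, -1]) * 0.25,
               tolerance = 1e-14)
  expect_error(divergence_scaled_set(0), "0 <")
  # every scaled coefficient remains bounded approaching the limit
  far <- shell_coefficients(c(0.999, 0.9999), scaled = TRUE)
  expect_true(all(vapply(far[-1], function(x) all(abs(x) < 10),
                         logical(1))))
})
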