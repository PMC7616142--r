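# Strain measures, energy densities, classical limit and excess formulas

make_sphere_pair <- function(f = 1, n = 201, eps_h = 0.15) {
  ref <- undeformed_sphere(n_grid = n)
  sh <- shape_from_tangent_fields(ref$psi, rep(f, n), ref,
                                  closure_tol = Inf)
  ic <- volvox_intrinsic(scenario_params(kappa_p = 1, kappa_b = 1,
                                         kappa_a = 1, f_p = 1, f_a = 1,
                                         eps_h = eps_h),
                         s_grid = ref$s)
  list(ref = ref, sh = sh, ic = ic)
}

test_that("identity embedding has zero strains and zero energy", {
  g <- make_sphere_pair(1)
  st <- shell_strains(g$sh, g$ic, g$ref)
  for (nm in c("es", "ephi", "Ks", "Kphi", "Ls", "Lphi"))
    expect_lt(max(abs(st[[nm]])), 1e-8)
  dens <- energy_density(st)
  expect_lt(max(abs(dens$total)), 1e-16)
  expect_lt(abs(total_energy(g$sh, g$ic)), 1e-12)
})

test_that("inflating a sphere is pure stretching: K vanishes, L does not", {
  f <- 1.2
  g <- make_sphere_pair(f)
  st <- shell_strains(g$sh, g$ic, g$ref)
  expect_lt(max(abs(st$Ks)), 1e-10)
  expect_lt(max(abs(st$Kphi[2:200])), 1e-8)
  expect_gt(min(abs(st$Ls)), 0.1)          # (1/f - 1) / 1, nonzero
  # small uniform inflation: L_s = L_phi = -delta + O(delta^2)
  del <- 1e-3
  g2 <- make_sphere_pair(1 + del)
  st2 <- shell_strains(g2$sh, g2$ic, g2$ref)
  expect_equal(mean(st2$Ls), -del, tolerance = 2 * del)
  expect_lt(max(abs(st2$Ls + del)), 2 * del^2 / (1 - del))
})

test_that("L and K strain families obey their exact pointwise relation", {
  # L_s - K_s = -kappa_s_tilde * e_s / g0, from the definitions
  ref <- undeformed_sphere(n_grid = 151)
  psi <- ref$s + 0.08 * sin(2 * ref$s)
  fs <- 1 + 0.1 * sin(ref$s)^2
  sh <- shape_from_tangent_fields(psi, fs, ref, closure_tol = Inf)
  ic <- volvox_intrinsic(scenario_params(), s_grid = ref$s)
  st <- shell_strains(sh, ic, ref)
  lhs <- st$Ls - st$Ks
  rhs <- -sh$kappa_s * st$es / ic$g0
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("large-bending density approaches the classical one as eta -> 0", {
  rs <- random_strains(40)
  for (eta in c(1e-2, 1e-3)) {
    st <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = eta, t = 0.15)
    dl <- energy_density(st, model = "large_bending")$total
    dc <- energy_density(st, model = "classical")$total
    # difference is O(eta^2) because beta-couplings are odd... the
    # leading deviation of the alpha/gamma moduli is eta^2 but the
    # couplings contribute at O(eta); both vanish
    expect_lt(max(abs(dl - dc)), 50 * eta * max(abs(dc)))
  }
  st3 <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = 1e-3, t = 0.15)
  st4 <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = 1e-4, t = 0.15)
  d3 <- energy_density(st3)$total - energy_density(st3, model = "classical")$total
  d4 <- energy_density(st4)$total - energy_density(st4, model = "classical")$total
  # halving... reducing eta tenfold shrinks the gap about tenfold (the
  # odd coupling term dominates the difference)
  expect_lt(max(abs(d4)), 0.2 * max(abs(d3)))
})

test_that("classical density is the thin Hookean shell form", {
  # Poisson ratio 1/2 and modulus E = 3C give stretching modulus 4 C t and
  # bending modulus C t^3 / 3
  rs <- random_strains(30)
  t <- 0.15
  st <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = 0.6, t = t)
  dens <- energy_density(st, model = "classical")
  expect_equal(dens$stretch,
               0.5 * (4 * t) * (rs$es^2 + rs$es * rs$ephi + rs$ephi^2),
               tolerance = 1e-13)
  expect_equal(dens$bend,
               0.5 * (t^3 / 3) * (rs$Ks^2 + rs$Ks * rs$Kphi + rs$Kphi^2),
               tolerance = 1e-13)
  expect_true(all(dens$couple == 0))
})

test_that("eps-bookkeeping and physical forms of the density coincide", {
  # physical form: strains e = eps E, curvature strains as literal
  # formulas, thickness t = eps h.  Paper form: (C/2) eps^3 { h [alpha E^2
  # ...] + 2 h^2 [beta E K ...] + h^3 [gamma K^2 ...] }.  The two must be
  # identical monomial by monomial.
  eps <- 0.05; h <- 3; t <- eps * h
  rs <- random_strains(20)
  eta <- 0.37
  cf <- shell_coefficients(eta)
  st <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = eta, t = t)
  phys <- energy_density(st, t = t)$total
  Es <- rs$es / eps; Ep <- rs$ephi / eps
  paper <- 0.5 * eps^3 * (
    h * (cf$alpha_bar_ss * Es^2 +
           (cf$alpha_bar_sphi + cf$alpha_bar_phis) * Es * Ep +
           cf$alpha_phiphi * Ep^2) +
      2 * h^2 * (cf$beta_bar_ss * Es * rs$Ks + cf$beta_bar_sphi * Es * rs$Kphi +
                   cf$beta_phis * Ep * rs$Ks + cf$beta_phiphi * Ep * rs$Kphi) +
      h^3 * (cf$gamma_ss * rs$Ks^2 +
               (cf$gamma_sphi + cf$gamma_phis) * rs$Ks * rs$Kphi +
               cf$gamma_phiphi * rs$Kphi^2))
  expect_equal(phys, paper, tolerance = 1e-13)
})

test_that("energy density is a positive semidefinite quadratic form", {
  for (eta in eta_grid(0.06)) {
    M <- density_form_matrix(eta)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
              -1e-12)
  }
  # random sampling of the density itself
  rs <- random_strains(2000, seed = 5)
  etas <- rep(eta_grid(0.1), length.out = 2000)
  st <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = etas, t = 0.15)
  expect_true(all(energy_density(st)$total >= -1e-15))
  expect_true(all(energy_density(st)$stretch >= 0))
  expect_true(all(energy_density(st)$bend >= 0))
})

test_that("excess formulas equal direct large-minus-classical differences", {
  rs <- random_strains(50)
  for (eta in c(-0.9, -0.5, -0.1, 0.1, 0.45, 0.8, 0.95)) {
    st <- strain_field(rs$es, rs$ephi, rs$Ks, rs$Kphi, eta = eta, t = 0.15)
    ex <- energy_excess(st)
    dl <- energy_density(st, model = "large_bending")
    dc <- energy_density(st, model = "classical")
    scale <- pmax(abs(dl$stretch), abs(dc$stretch), 1e-8)
    expect_lt(max(abs(dl$stretch - dc$stretch - ex$stretch_excess) / scale),
              1e-9)
    scale_b <- pmax(abs(dl$bend), abs(dc$bend), 1e-8)
    expect_lt(max(abs(dl$bend - dc$bend - ex$bend_excess) / scale_b), 1e-9)
    expect_true(all(ex$stretch_excess >= 0))
  }
})

test_that("excess signs follow the special deformation directions", {
  eta <- 0.6
  # stretch excess vanishes exactly iff e_phi = -2 e_s
  st0 <- strain_field(0.1, -0.2, 1, 1, eta = eta, t = 0.15)
  expect_equal(energy_excess(st0)$stretch_excess, 0)
  st1 <- strain_field(0.1, -0.19, 1, 1, eta = eta, t = 0.15)
  expect_gt(energy_excess(st1)$stretch_excess, 0)
  # bend excess negative iff Ks*Kphi < 0 and k(eta)|Ks| < |Kphi| < 3|Ks|
  k <- k_eta(eta)
  inside <- strain_field(0, 0, 1, -(k + 3) / 2, eta = eta, t = 0.15)
  expect_lt(energy_excess(inside)$bend_excess, 0)
  outside1 <- strain_field(0, 0, 1, -(k - 0.05), eta = eta, t = 0.15)
  expect_gt(energy_excess(outside1)$bend_excess, 0)
  outside2 <- strain_field(0, 0, 1, -3.05, eta = eta, t = 0.15)
  expect_gt(energy_excess(outside2)$bend_excess, 0)
  same_sign <- strain_field(0, 0, 1, 2.8, eta = eta, t = 0.15)
  expect_gt(energy_excess(same_sign)$bend_excess, 0)
})

test_that("density stays bounded at near-constriction for the special
          deformations", {
  es <- 0.1
  st <- strain_field(es, -2 * es, 1, -3, eta = 0.99, t = 0.15)
  bounded <- energy_density(st)$total
  expect_lt(abs(bounded), 1)
  # generic strains diverge like (1-|eta|)^-2 instead
  stg <- strain_field(es, es, 1, 1, eta = 0.99, t = 0.15)
  expect_gt(energy_density(stg)$total, 50 * abs(bounded))
})

test_that("total energy integrates with fourth-order accuracy", {
  E_at <- function(n) {
    ref <- undeformed_sphere(n_grid = n)
    psi <- ref$s + 0.1 * sin(2 * ref$s)
    fs <- 1 + 0.05 * sin(ref$s)
    sh <- shape_from_tangent_fields(psi, fs, ref, closure_tol = Inf)
    ic <- volvox_intrinsic(scenario_params(), s_grid = ref$s)
    total_energy(sh, ic, reference = ref)
  }
  e1 <- E_at(101); e2 <- E_at(201); e3 <- E_at(401)
  expect_gt(abs(e1 - e2) / abs(e2 - e3), 8)   # ~16 for fourth order
  # uniform-inflation closed form: constant density times sphere area
  g <- make_sphere_pair(1.1, n = 201)
  st <- shell_strains(g$sh, g$ic, g$ref)
  dens <- energy_density(st)$total[100]
  expect_equal(total_energy(g$sh, g$ic), 4 * pi * dens, tolerance = 1e-6)
})

test_that("per-point strain tables serialize with the documented columns", {
  g <- make_sphere_pair(1.05, n = 101)
  st <- shell_strains(g$sh, g$ic, g$ref)
  f <- tempfile(fileext = ".csv")
  write_strain_table(st, f)
  d <- read.csv(f)
  expect_identical(names(d),
                   c("s", "es", "ephi", "Ks", "Kphi", "eta", "e_stretch",
                     "e_couple", "e_bend", "e_total"))
  expect_equal(d$e_total, d$e_stretch + d$e_couple + d$e_bend,
               tolerance = 1e-12)
})
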