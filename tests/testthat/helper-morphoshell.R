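# shared helpers: relative error, quick solver settings, random strain
# samples under a fixed seed

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# strain tuples used by the energy-identity checks
random_strains <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(es = rnorm(n, sd = 0.2), ephi = rnorm(n, sd = 0.2),
             Ks = rnorm(n, sd = 2), Kphi = rnorm(n, sd = 2))
}

eta_grid <- function(step = 0.05) {
  g <- seq(-0.95, 0.95, by = step)
  g[abs(g) > 1e-12]
}

# quadratic-form matrix of the energy density at one eta, in the scaled
# variables (sqrt(t) e_s, sqrt(t) e_phi, sqrt(t^3) K_s, sqrt(t^3) K_phi)
density_form_matrix <- function(eta, model = "large_bending") {
  cf <- shell_coefficients(if (model == "classical") 0 else eta)
  A12 <- (cf$alpha_bar_sphi + cf$alpha_bar_phis) / 2
  G12 <- (cf$gamma_sphi + cf$gamma_phis) / 2
  matrix(c(cf$alpha_bar_ss, A12, cf$beta_bar_ss, cf$beta_bar_sphi,
           A12, cf$alpha_phiphi, cf$beta_phis, cf$beta_phiphi,
           cf$beta_bar_ss, cf$beta_phis, cf$gamma_ss, G12,
           cf$beta_bar_sphi, cf$beta_phiphi, G12, cf$gamma_phiphi),
         4, 4)
}
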