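# Shared fixtures: reference populations used across the suite.

# balanced population, exchangeable nutrients
params_symmetric <- function(rho = 0)
  model1_params(4350, 4350, 500, 500, rho)

# 15% protein share of 8700 kJ, constant variance
params_reference <- function(rho = 0)
  model1_params(1305, 7395, 500, 500, rho)

# share/dispersion-ratio population: ID_V = 125, ID_U = idr * 125
params_idr <- function(share, idr, rho = 0, total = 8700) {
  mu_U <- share * total
  mu_V <- total - mu_U
  suppressWarnings(model1_params(mu_U, mu_V, sqrt(idr * 125 * mu_U),
                                 sqrt(125 * mu_V), rho))
}

# generative model at a target proportion mean/SD with the standard
# energy-anchored intercept and residual variance
params_gen <- function(mu_W = 0.2, sigma_W = 0.05, L = -0.5,
                       sigma_eps2 = log(8700) * 0.02) {
  sh <- beta_from_moments(mu_W, sigma_W)
  model2_params(sh[["kappa"]], sh[["tau"]], L,
                alpha_for_energy(mu_W, L), sigma_eps2)
}

# uniform proportion density as a pl_density (Beta(1,1))
unif_density <- function()
  pl_density(function(w) stats::dunif(w), c(1e-13, 1 - 1e-13), tol = 1e-10)
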