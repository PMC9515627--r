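test_that("beta moment inversion round-trips and rejects infeasible input", {
  expect_equal(unname(beta_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  for (mu in c(0.15, 0.35, 0.8)) {
    for (s in c(0.01, 0.03, 0.1)) {
      sh <- beta_from_moments(mu, s)
      k <- sh[["kappa"]]; t <- sh[["tau"]]
      expect_equal(k / (k + t), mu, tolerance = 1e-12)
      expect_equal(sqrt(k * t / ((k + t)^2 * (k + t + 1))), s,
                   tolerance = 1e-12)
    }
  }
  expect_error(beta_from_moments(0.5, 0.8), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "mu_W")
})

test_that("log-beta moments match the digamma/trigamma closed forms", {
  lp <- log_proportion_stats(1, 1)
  expect_equal(lp$moments$mean, -1, tolerance = 1e-8)
  expect_equal(lp$moments$variance, 1, tolerance = 1e-8)
  for (k in c(0.8, 3, 12.6)) {
    for (t in c(1.5, 9, 50.4)) {
      lp <- log_proportion_stats(k, t)
      expect_lt(abs(lp$density$mass - 1), 1e-5)
      expect_equal(lp$moments$mean, digamma(k) - digamma(k + t),
                   tolerance = 1e-8)
      expect_equal(lp$moments$variance, trigamma(k) - trigamma(k + t),
                   tolerance = 1e-8)
    }
  }
})

test_that("log energy is exactly normal when leverage is absent", {
  p <- params_gen(L = 0)
  le <- log_energy_density(p)
  expect_equal(le$moments$mean, p$alpha, tolerance = 1e-8)
  expect_equal(le$moments$variance, p$sigma_eps2, tolerance = 1e-8)
  ys <- seq(p$alpha - 2, p$alpha + 2, length.out = 21)
  expect_equal(le$density$pdf(ys), dnorm(ys, p$alpha, sqrt(p$sigma_eps2)),
               tolerance = 1e-10)
})

test_that("at complete leverage with vanishing noise, var(Y) -> var(log W)", {
  sh <- beta_from_moments(0.2, 0.05)
  vX <- trigamma(sh[["kappa"]]) - trigamma(sh[["kappa"]] + sh[["tau"]])
  p <- model2_params(sh[["kappa"]], sh[["tau"]], -1,
                     alpha_for_energy(0.2, -1), 1e-8)
  le <- log_energy_density(p)
  expect_equal(le$moments$variance, vX, tolerance = 1e-4)
})

test_that("log-energy density matches Monte-Carlo draws of the leverage law", {
  p <- params_gen(0.2, 0.05, -0.5)
  le <- log_energy_density(p)
  expect_lt(abs(le$density$mass - 1), 1e-5)
  set.seed(5)
  y <- p$alpha + p$L * log(rbeta(1e6, p$kappa, p$tau)) +
    rnorm(1e6, 0, sqrt(p$sigma_eps2))
  expect_equal(le$moments$mean, mean(y), tolerance = 0.005)
  expect_equal(le$moments$variance, var(y), tolerance = 0.005)
})

test_that("natural-scale energy moments reproduce lognormal closed forms", {
  mu <- log(8000); s2 <- 0.05
  fY <- pl_density(function(y) dnorm(y, mu, sqrt(s2)),
                   mu + c(-8, 8) * sqrt(s2), tol = 1e-10)
  m <- energy_moments_natural(fY)
  expect_equal(m$mean, exp(mu + s2 / 2), tolerance = 1e-6)
  expect_equal(m$variance, expm1(s2) * exp(2 * mu + s2), tolerance = 1e-6)
})

test_that("intake moments obey the exact identities and match simulation", {
  p <- params_gen(0.2, 0.05, -0.5)
  m <- intake_moments(p)
  expect_identical(m$mu_V, m$mu_Z - m$mu_U)          # mean decomposition
  expect_identical(m$sigma_XY, p$L * m$sigma_X2)     # exact covariance
  set.seed(11)
  w <- rbeta(1e5, p$kappa, p$tau)
  z <- exp(p$alpha + p$L * log(w) + rnorm(1e5, 0, sqrt(p$sigma_eps2)))
  u <- z * w; v <- z * (1 - w)
  expect_equal(m$mu_U, mean(u), tolerance = 0.10)
  expect_equal(m$sigma_U2, var(u), tolerance = 0.10)
  expect_equal(m$mu_V, mean(v), tolerance = 0.10)
  expect_equal(m$sigma_V2, var(v), tolerance = 0.10)
})

test_that("complete leverage with vanishing noise pins protein intake", {
  sh <- beta_from_moments(0.15, 0.05)
  p <- model2_params(sh[["kappa"]], sh[["tau"]], -1,
                     alpha_for_energy(0.15, -1), 1e-9)
  m <- intake_moments(p)
  expect_lt(m$sigma_logU2, 1e-6)
  ds <- idr_from_model(p)
  expect_lt(ds$idr, 0.01)
})

test_that("weaker leverage moves the dispersion ratio toward one", {
  idr_at <- function(L) idr_from_model(params_gen(0.15, 0.07, L))$idr
  expect_lt(idr_at(-1), idr_at(-0.1))
  g <- idr_grid(L_grid = c(-1, -0.6, -0.2), sigmaW_grid = c(0.03, 0.07),
                muW_grid = c(0.125, 0.2))
  for (mu in unique(g$mu_W)) {
    for (s in unique(g$sigma_W)) {
      sl <- g[g$mu_W == mu & g$sigma_W == s, ]
      sl <- sl[order(sl$L), ]
      expect_true(all(diff(sl$idr_model) >= 0),
                  label = sprintf("IDR non-decreasing in L at (%.3f, %.2f)",
                                  mu, s))
    }
  }
})

test_that("model IDR tracks simulated IDR and reruns are identical", {
  g1 <- idr_grid(L_grid = c(-1, -0.4), sigmaW_grid = 0.05, muW_grid = 0.15,
                 simulate = TRUE, n_sim = 50000L, seed = 33)
  g2 <- idr_grid(L_grid = c(-1, -0.4), sigmaW_grid = 0.05, muW_grid = 0.15,
                 simulate = TRUE, n_sim = 50000L, seed = 33)
  expect_identical(g1, g2)
  expect_equal(g1$idr_model, g1$idr_sim, tolerance = 0.15)
})
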