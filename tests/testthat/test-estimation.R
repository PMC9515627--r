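strict_defence_table <- function(protein = 1305)
  intake_table(rep(protein, 60), seq(2000, 10000, length.out = 60))

test_that("strict protein defence is recovered as complete leverage", {
  fit <- fit_leverage(strict_defence_table())
  expect_lt(abs(fit$L_hat - (-1)), 1e-10)
  expect_lt(abs(fit$P_hat - 1305), 1e-6)
  pw <- fit_power_law(strict_defence_table())
  expect_equal(pw$L_hat, -1, tolerance = 1e-6)
  expect_equal(pw$P_hat, 1305, tolerance = 1e-6)
})

test_that("power law fit recovers a noiseless generating law exactly", {
  p <- seq(0.08, 0.4, length.out = 80)
  E <- 9000 * p^-0.3
  tab <- intake_table(E * p, E * (1 - p))
  pw <- fit_power_law(tab)
  expect_equal(pw$L_hat, -0.3, tolerance = 1e-6)
  expect_equal(pw$P_hat, 9000, tolerance = 1e-6)
  ll <- fit_leverage(tab)
  expect_equal(ll$L_hat, pw$L_hat, tolerance = 1e-6)
  expect_equal(ll$P_hat, pw$P_hat, tolerance = 1e-6)
})

test_that("log-log and power-law estimators agree under lognormal noise", {
  tab <- simulate_pl_generative(params_gen(0.2, 0.05, -0.5), 20000, seed = 8)
  ll <- fit_leverage(tab)
  pw <- fit_power_law(tab)
  expect_lt(abs(pw$L_hat - ll$L_hat), 2 * ll$se_L)
})

test_that("generative leverage strength is recovered within 2 SE", {
  tab <- simulate_pl_generative(params_gen(0.2, 0.05, -0.5), 100000,
                                seed = 15)
  fit <- fit_leverage(tab)
  expect_lt(abs(fit$L_hat - (-0.5)), 2 * fit$se_L)
})

test_that("replicate simulations show consistency and calibrated SEs", {
  n_rep <- 50
  for (L in c(0, -0.5, -1)) {
    p <- params_gen(0.2, 0.05, L)
    ests <- vapply(seq_len(n_rep), function(i) {
      tab <- simulate_pl_generative(p, 5000, seed = 1000 * abs(L) + i)
      f <- fit_leverage(tab)
      c(f$L_hat, f$se_L)
    }, numeric(2))
    expect_lt(abs(mean(ests[1, ]) - L), 0.01)
    covered <- mean(abs(ests[1, ] - L) <= 2 * ests[2, ])
    expect_gte(covered, 0.90)
  }
})

test_that("adjusting for an injected confounder restores the slope", {
  set.seed(2026)
  n <- 20000
  sh <- beta_from_moments(0.2, 0.05)
  w <- rbeta(n, sh[["kappa"]], sh[["tau"]])
  x <- log(w)
  # confounder tracks dietary composition and independently shifts energy
  conf <- (x - mean(x)) / sd(x) + rnorm(n, 0, 0.7)
  L <- -0.5
  y <- alpha_for_energy(0.2, L) + L * x + 0.1 * conf +
    rnorm(n, 0, sqrt(log(8700) * 0.02))
  z <- exp(y)
  tab <- intake_table(z * w, z * (1 - w), covariates = data.frame(conf = conf))
  naive <- fit_leverage(tab)
  adjusted <- fit_leverage(tab, covariates = "conf")
  expect_gt(abs(naive$L_hat - L), 2 * naive$se_L)      # visibly biased
  expect_lt(abs(adjusted$L_hat - L), 2 * adjusted$se_L)
  expect_identical(adjusted$covariates_adjusted, "conf")
})

test_that("invalid designs and intakes produce informative errors", {
  bad <- data.frame(protein_kj = c(100, -5, 200, 0),
                    nonprotein_kj = c(1000, 1000, 1000, 1000))
  expect_error(fit_leverage(bad), "row")
  expect_error(fit_leverage(strict_defence_table()[1:2, ]), "at least 3")
  tab <- simulate_pl_generative(params_gen(), 100, seed = 1)
  tab$dup <- log(tab$w)   # exactly collinear with the predictor
  expect_error(fit_leverage(tab, covariates = "dup"), "collinear")
  expect_error(fit_leverage(tab, covariates = "absent"), "not found")
})

test_that("dispersion summary uses unbiased variances and handles limits", {
  tab <- intake_table(rep(1305, 10), seq(2000, 6000, length.out = 10))
  ds <- dispersion_summary(tab)
  expect_identical(ds$id_U, 0)
  expect_identical(ds$idr, 0)
  np <- seq(2000, 6000, length.out = 10)
  expect_equal(ds$id_V, var(np) / mean(np), tolerance = 1e-12)
  tiny <- simulate_pl_generative(params_gen(0.15, 0.05, -1,
                                            sigma_eps2 = 1e-8),
                                 20000, seed = 4)
  expect_lt(dispersion_summary(tiny)$idr, 0.01)
})

test_that("sample IDR of generative cohorts matches the model IDR", {
  for (L in c(-1, -0.4)) {
    p <- params_gen(0.15, 0.05, L)
    model <- idr_from_model(p)$idr
    tab <- simulate_pl_generative(p, 100000, seed = 62)
    expect_equal(dispersion_summary(tab)$idr, model, tolerance = 0.10)
  }
})

test_that("coefficient-of-variation ratio is plain arithmetic with guards", {
  expect_equal(cvr(0.2, 0.2)$cvr, 1.0)
  expect_equal(cvr(0.24, 0.25)$cvr, 0.96)
  expect_equal(cvr(0.3, 0.15)$cvr, 2.0)
  expect_error(cvr(-0.1, 0.2), "positive")
  expect_error(cvr(0.2, 0), "positive")
})

test_that("fitted-model methods behave like a standard modelling object", {
  tab <- simulate_pl_generative(params_gen(), 2000, seed = 30)
  fit <- fit_leverage(tab)
  expect_named(coef(fit), c("L", "alpha"))
  expect_length(residuals(fit), fit$n_used)
  expect_equal(unname(predict(fit, newdata = tab)[1]),
               unname(predict(fit)[1]), tolerance = 1e-12)
  ci <- confint(fit)
  expect_true(ci["L", 1] < fit$L_hat && fit$L_hat < ci["L", 2])
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "intake_table")
  refit <- fit_leverage(sims[[1]])
  expect_lt(abs(refit$L_hat - fit$L_hat), 4 * fit$se_L)
  expect_output(print(summary(fit)), "Spearman")
})
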