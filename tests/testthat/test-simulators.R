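test_that("identical seed and parameters give identical tables", {
  p <- params_reference()
  expect_identical(suppressWarnings(simulate_bivariate_normal(p, 5000, seed = 3)),
                   suppressWarnings(simulate_bivariate_normal(p, 5000, seed = 3)))
  expect_identical(simulate_bivariate_lognormal(p, 5000, seed = 3),
                   simulate_bivariate_lognormal(p, 5000, seed = 3))
  g <- params_gen()
  expect_identical(simulate_pl_generative(g, 5000, seed = 3),
                   simulate_pl_generative(g, 5000, seed = 3))
})

test_that("normal simulator hits its target moments and correlation", {
  p <- model1_params(1305, 7395, 500, 500, 0.3)
  n <- 20000
  tab <- suppressWarnings(simulate_bivariate_normal(p, n, seed = 7))
  expect_lt(abs(mean(tab$protein_kj) - 1305), 3 * 500 / sqrt(n))
  expect_lt(abs(mean(tab$nonprotein_kj) - 7395), 3 * 500 / sqrt(n))
  r <- cor(tab$protein_kj, tab$nonprotein_kj)
  # Fisher-z standard error for a sample correlation
  expect_lt(abs(atanh(r) - atanh(0.3)), 3 / sqrt(n - 3))
})

test_that("exclusion bookkeeping is exact and warnings fire when material", {
  p <- model1_params(1305, 7395, 100, 500, 0)   # mean is 13 sd above zero
  tab <- simulate_bivariate_normal(p, 20000, seed = 2)
  pr <- attr(tab, "provenance")
  expect_identical(pr$n_excluded, 0L)
  expect_identical(nrow(tab) + pr$n_excluded, pr$n_requested)

  wide <- suppressWarnings(model1_params(500, 7395, 250, 500, 0))
  expect_warning(tab2 <- simulate_bivariate_normal(wide, 20000, seed = 2),
                 "excluded")
  pr2 <- attr(tab2, "provenance")
  expect_gt(pr2$n_excluded, 0L)
  expect_identical(nrow(tab2) + pr2$n_excluded, pr2$n_requested)
  expect_true(all(tab2$protein_kj > 0 & tab2$nonprotein_kj > 0))
})

test_that("lognormal simulator matches natural-scale targets with no exclusions", {
  p <- model1_params(1305, 7395, 500, 500, 0)
  n <- 20000
  tab <- simulate_bivariate_lognormal(p, n, seed = 9)
  expect_identical(attr(tab, "provenance")$n_excluded, 0L)
  expect_true(all(tab$protein_kj > 0))
  expect_lt(abs(mean(tab$protein_kj) - 1305), 3 * 500 / sqrt(n))
  expect_lt(abs(mean(tab$nonprotein_kj) - 7395), 3 * 500 / sqrt(n))
  # SD of a sample SD is roughly s / sqrt(2n) for near-normal data
  expect_lt(abs(sd(tab$protein_kj) - 500), 5 * 500 / sqrt(2 * n))
  expect_lt(abs(sd(tab$nonprotein_kj) - 500), 5 * 500 / sqrt(2 * n))
})

test_that("lognormal copula hits the natural-scale correlation", {
  p <- model1_params(1305, 7395, 500, 500, 0.6)
  n <- 50000
  tab <- simulate_bivariate_lognormal(p, n, seed = 13)
  r <- cor(tab$protein_kj, tab$nonprotein_kj)
  expect_lt(abs(r - 0.6), 3 * (1 - 0.6^2) / sqrt(n))
})

test_that("unattainable lognormal correlations error with the bounds", {
  skewed <- suppressWarnings(model1_params(100, 7395, 300, 500, -0.9))
  err <- tryCatch(simulate_bivariate_lognormal(skewed, 100, seed = 1),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "range")
})

test_that("generative simulator reconstructs its own proportions exactly", {
  p <- params_gen(0.2, 0.05, -0.5)
  tab <- simulate_pl_generative(p, 5000, seed = 21)
  expect_equal(tab$protein_kj / (tab$protein_kj + tab$nonprotein_kj),
               tab$w, tolerance = 1e-14)
  expect_identical(attr(tab, "provenance")$n_excluded, 0L)
  fit <- fit_leverage(tab)
  expect_lt(abs(fit$L_hat - (-0.5)), 2 * fit$se_L)
})

test_that("sample IDR falls with stronger generative leverage", {
  idr_at <- function(L) {
    tab <- simulate_pl_generative(params_gen(0.15, 0.05, L), 100000,
                                  seed = 77)
    dispersion_summary(tab)$idr
  }
  expect_lt(idr_at(-1), idr_at(-0.1))
})

test_that("intake tables round-trip through CSV with provenance", {
  p <- params_gen()
  tab <- simulate_pl_generative(p, 50, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_intake_csv(tab, path)
  back <- read_intake_csv(path)
  expect_equal(back$protein_kj, tab$protein_kj, tolerance = 1e-12)
  expect_equal(back$w, tab$w, tolerance = 1e-12)
  expect_identical(attr(back, "provenance")$generator, "pl_generative")
  unlink(path)
})
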