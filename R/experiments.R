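#' Configuration for a computational experiment
#'
#' Bundles grids, cohort sizes, seed and output directory for the
#' experiment runners.  Defaults keep a full run modest; pass denser
#' grids for publication-resolution surfaces.
#'
#' @param share_grid Protein shares of total energy.
#' @param rho_grid Intake correlations.
#' @param idr_grid Index-of-dispersion ratios (dispersion-ratio
#'   experiments).
#' @param L_grid,sigmaW_grid,muW_grid Leverage-generative grids.
#' @param n Cohort size per grid point for simulation stages.
#' @param seed Base seed; required whenever a stage is stochastic.
#' @param total Mean total energy (kJ).
#' @param sigma_eps2 Residual variance for the generative model.
#' @param out_dir Optional directory; runners write their CSV there.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(share_grid = seq(0.05, 0.95, by = 0.05),
                              rho_grid = c(0, 0.3, 0.6, 0.9),
                              idr_grid = seq(0.2, 1.8, by = 0.2),
                              L_grid = seq(-1, -0.1, by = 0.1),
                              sigmaW_grid = c(0.03, 0.05, 0.07),
                              muW_grid = c(0.125, 0.15, 0.175, 0.2),
                              n = 20000L, seed = NULL, total = 8700,
                              sigma_eps2 = log(8700) * 0.02,
                              out_dir = NULL) {
  stopifnot(length(share_grid) > 0, length(rho_grid) > 0)
  structure(list(share_grid = share_grid, rho_grid = rho_grid,
                 idr_grid = idr_grid, L_grid = L_grid,
                 sigmaW_grid = sigmaW_grid, muW_grid = muW_grid,
                 n = as.integer(n), seed = seed, total = total,
                 sigma_eps2 = sigma_eps2, out_dir = out_dir),
            class = "experiment_config")
}

.write_grid <- function(df, config, name) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
  }
  df
}

#' Expected leverage across protein shares: constant variance vs constant ID
#'
#' Evaluates the null-model expected leverage coefficient over protein
#' share and intake correlation, once holding both intake variances
#' constant (sigma 500 kJ) and once holding both indices of dispersion
#' constant (100 kJ).  Under constant variance, any share below 50%
#' yields a positive expected slope despite the absence of leverage;
#' under equal dispersion with uncorrelated intakes the expected slope is
#' zero across all shares.
#'
#' @param config An [experiment_config()].
#' @return Data frame with columns `panel` (`"constant_variance"` /
#'   `"constant_ID"`), `protein_share`, `rho_uv`, `expected_L`, `flag`.
#' @export
run_share_experiment <- function(config = experiment_config()) {
  a <- leverage_grid(config$share_grid, 1, config$rho_grid,
                     mode = "constant_variance", total = config$total)
  b <- leverage_grid(config$share_grid, 1, config$rho_grid,
                     mode = "constant_ID", total = config$total)
  a$panel <- "constant_variance"
  b$panel <- "constant_ID"
  out <- rbind(a, b)[, c("panel", "protein_share", "rho_uv", "expected_L",
                         "flag")]
  .write_grid(out, config, "expected_L_share")
}

#' Expected leverage across dispersion ratios
#'
#' Null-model expected leverage over protein share, index-of-dispersion
#' ratio (non-protein ID fixed at 125 kJ) and intake correlation.  With
#' uncorrelated intakes, a spurious leverage signal (negative slope)
#' appears exactly where protein dispersion is below non-protein
#' dispersion.
#'
#' @param config An [experiment_config()].
#' @return Data frame with `protein_share`, `idr`, `rho_uv`,
#'   `expected_L`, `flag`.
#' @export
run_dispersion_experiment <- function(config = experiment_config()) {
  out <- leverage_grid(config$share_grid, config$idr_grid, config$rho_grid,
                       mode = "free_IDR", total = config$total)
  .write_grid(out, config, "expected_L_idr")
}

#' Analytic expected leverage versus simulated regression slopes
#'
#' For every point of the dispersion-ratio grid, pairs the analytic
#' expected leverage with the OLS slope of the log-log leverage
#' regression fitted to a simulated cohort, under both a bivariate
#' normal and a bivariate lognormal intake model.  Subjects with
#' non-positive normal draws are excluded before fitting, mirroring the
#' analytic treatment of the positive part of the ratio density.
#'
#' @param config An [experiment_config()]; `config$seed` must be set and
#'   `config$n` subjects are simulated per point.
#' @return Data frame with `distribution`, `protein_share`, `idr`,
#'   `rho_uv`, `expected_L`, `simulated_L`, `n_used`, `seed`.
#' @export
run_null_validation <- function(config = experiment_config(seed = 1)) {
  if (is.null(config$seed)) stop("config$seed is required")
  g <- expand.grid(protein_share = config$share_grid,
                   idr = config$idr_grid, rho_uv = config$rho_grid,
                   distribution = c("normal", "lognormal"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$expected_L <- NA_real_
  g$simulated_L <- NA_real_
  g$n_used <- NA_integer_
  g$seed <- config$seed + seq_len(nrow(g))
  g$flag <- ""
  for (i in seq_len(nrow(g))) {
    mu_U <- g$protein_share[i] * config$total
    mu_V <- config$total - mu_U
    s <- .grid_sigmas("free_IDR", mu_U, mu_V, g$idr[i])
    p <- suppressWarnings(model1_params(mu_U, mu_V, s[1], s[2],
                                        g$rho_uv[i]))
    el <- tryCatch(expected_leverage(p), error = identity)
    if (inherits(el, "error")) { g$flag[i] <- conditionMessage(el); next }
    g$expected_L[i] <- el$expected_L
    tab <- tryCatch(suppressWarnings(
      if (g$distribution[i] == "normal")
        simulate_bivariate_normal(p, config$n, seed = g$seed[i])
      else simulate_bivariate_lognormal(p, config$n, seed = g$seed[i])),
      error = identity)
    if (inherits(tab, "error")) { g$flag[i] <- conditionMessage(tab); next }
    ft <- fit_leverage(tab)
    g$simulated_L[i] <- ft$L_hat
    g$n_used[i] <- ft$n_used
  }
  .write_grid(g, config, "expected_vs_simulated_L")
}

#' Model versus simulated dispersion ratios under generative leverage
#'
#' Runs [idr_grid()] with simulation enabled over the generative-model
#' grids: for each combination of leverage slope, proportion mean and
#' proportion SD, reports the analytic index-of-dispersion ratio and the
#' sample IDR of a simulated cohort.
#'
#' @param config An [experiment_config()]; `config$seed` must be set.
#'   Simulated cohorts use `max(config$n, 100000)` subjects per point.
#' @return Data frame from [idr_grid()] with `idr_model`, `idr_sim`.
#' @export
run_generative_validation <- function(config = experiment_config(seed = 1, n = 100000L)) {
  if (is.null(config$seed)) stop("config$seed is required")
  out <- idr_grid(config$L_grid, config$sigmaW_grid, config$muW_grid,
                  sigma_eps2 = config$sigma_eps2, energy = config$total,
                  simulate = TRUE, n_sim = max(config$n, 100000L),
                  seed = config$seed)
  .write_grid(out, config, "idr_model_vs_sim")
}
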