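#' Parameters of the bivariate-normal intake model
#'
#' Describes a population in which per-subject protein energy intake
#' \eqn{U} and non-protein energy intake \eqn{V} (both in kJ/day) are
#' jointly normal with means `mu_U`, `mu_V`, standard deviations
#' `sigma_U`, `sigma_V` and correlation `rho_UV`.  This is the null model
#' under which the expected leverage coefficient is derived: no
#' behavioural regulation links total intake to dietary composition, yet
#' the log-log regression slope need not be zero.
#'
#' A normal intake model is well posed only while the mass below zero is
#' negligible; a warning is issued when the coefficient of variation of
#' either intake reaches 0.5, where truncation effects become visible.
#'
#' @param mu_U,mu_V Mean protein and non-protein energy intake (kJ, > 0).
#' @param sigma_U,sigma_V Intake standard deviations (kJ, > 0).
#' @param rho_UV Correlation between protein and non-protein intake.
#' @return An object of class `"model1_params"`.
#' @examples
#' model1_params(1305, 7395, 500, 500, 0.3)
#' @export
model1_params <- function(mu_U, mu_V, sigma_U, sigma_V, rho_UV = 0) {
  stopifnot(is.numeric(mu_U), is.numeric(mu_V), is.numeric(sigma_U),
            is.numeric(sigma_V), is.numeric(rho_UV))
  if (mu_U <= 0 || mu_V <= 0) stop("mean intakes must be strictly positive")
  if (sigma_U <= 0 || sigma_V <= 0) stop("intake SDs must be strictly positive")
  if (abs(rho_UV) > 1) stop("rho_UV must lie in [-1, 1]")
  cv <- c(U = sigma_U / mu_U, V = sigma_V / mu_V)
  if (any(cv >= 0.5))
    warning("coefficient of variation of ", paste(names(cv)[cv >= 0.5],
            collapse = " and "), " is >= 0.5; the normal intake model ",
            "places non-negligible mass below zero here", call. = FALSE)
  structure(list(mu_U = mu_U, mu_V = mu_V, sigma_U = sigma_U,
                 sigma_V = sigma_V, rho_UV = rho_UV),
            class = "model1_params")
}

#' @export
print.model1_params <- function(x, ...) {
  cat("Bivariate-normal intake model\n",
      "  protein:     mean ", x$mu_U, " kJ, sd ", x$sigma_U, " kJ\n",
      "  non-protein: mean ", x$mu_V, " kJ, sd ", x$sigma_V, " kJ\n",
      "  correlation: ", x$rho_UV, "\n", sep = "")
  invisible(x)
}

#' Moments of total energy intake under the bivariate-normal model
#'
#' Total energy \eqn{Z = U + V} is normal with
#' \eqn{\mu_Z = \mu_U + \mu_V} and
#' \eqn{\sigma_Z^2 = \sigma_U^2 + \sigma_V^2 + 2\sigma_{UV}}; protein and
#' total intake have covariance
#' \eqn{\sigma_{UZ} = \sigma_U^2 + \sigma_{UV}} and correlation
#' \eqn{\rho_{UZ} = \sigma_{UZ}/(\sigma_U \sigma_Z)}.  All closed form,
#' no quadrature.
#'
#' @param params A [model1_params()] object.
#' @return Object of class `"energy_moments"`: list with `mu_Z`,
#'   `sigma_Z`, `sigma_UZ`, `rho_UZ`.
#' @export
energy_moments <- function(params) {
  stopifnot(inherits(params, "model1_params"))
  sigma_UV <- params$rho_UV * params$sigma_U * params$sigma_V
  mu_Z <- params$mu_U + params$mu_V
  sigma_Z <- sqrt(params$sigma_U^2 + params$sigma_V^2 + 2 * sigma_UV)
  sigma_UZ <- params$sigma_U^2 + sigma_UV
  structure(list(mu_Z = mu_Z, sigma_Z = sigma_Z, sigma_UZ = sigma_UZ,
                 rho_UZ = sigma_UZ / (params$sigma_U * sigma_Z)),
            class = "energy_moments")
}

#' @export
print.energy_moments <- function(x, ...) {
  cat("Total-energy moments: mu_Z ", x$mu_Z, " kJ, sigma_Z ",
      format(x$sigma_Z, digits = 8), " kJ, rho_UZ ",
      format(x$rho_UZ, digits = 6), "\n", sep = "")
  invisible(x)
}

# log density of W = U/Z for (U, Z) bivariate normal, derived by direct
# integration of |z| f_{U,Z}(wz, z) over z.  With
#   A(w) = (sigma_Z^2 w^2 - 2 sigma_UZ w + sigma_U^2) / D,
#   B(w) = (w mu_U sigma_Z^2 - sigma_UZ (mu_U + w mu_Z) + mu_Z sigma_U^2) / D,
#   C    = (sigma_Z^2 mu_U^2 - 2 sigma_UZ mu_U mu_Z + mu_Z^2 sigma_U^2) / D,
#   D    = (1 - rho_UZ^2) sigma_U^2 sigma_Z^2,
# the density is K * (2/A(w)) * M(1, 1/2, B(w)^2 / (2 A(w))) with
# K = exp(-C/2) / (2 pi sigma_U sigma_Z sqrt(1 - rho_UZ^2)); evaluated on
# the log scale because the Kummer argument grows like 1/CV^2.
.ratio_log_pdf <- function(w, mu_U, mu_Z, sigma_U, sigma_Z, sigma_UZ) {
  one_m_r2 <- 1 - (sigma_UZ / (sigma_U * sigma_Z))^2
  D <- one_m_r2 * sigma_U^2 * sigma_Z^2
  den <- sigma_Z^2 * w^2 - 2 * sigma_UZ * w + sigma_U^2
  C_half <- (sigma_Z^2 * mu_U^2 - 2 * sigma_UZ * mu_U * mu_Z +
               mu_Z^2 * sigma_U^2) / (2 * D)
  B_num <- w * mu_U * sigma_Z^2 - sigma_UZ * (mu_U + w * mu_Z) +
    mu_Z * sigma_U^2
  zeta <- B_num^2 / (2 * D * den)
  -log(2 * pi * sigma_U * sigma_Z * sqrt(one_m_r2)) - C_half +
    log(2 * D / den) + .log_kummer_M_1_half(zeta)
}

#' Density of the proportion of energy from protein
#'
#' Exact density of \eqn{W = U/(U+V)} when protein intake \eqn{U} and
#' non-protein intake \eqn{V} are bivariate normal: the density of a ratio
#' of two correlated normal variables (\eqn{U} and \eqn{Z = U + V}),
#' expressed through Kummer's confluent hypergeometric function.  Support
#' bounds are located by stepping outward from the central ratio
#' \eqn{\mu_U/\mu_Z} until the tail mass falls below `tail_tol`; all
#' moment integrals are taken over that interval.
#'
#' The ratio of normals has, strictly, full real support with power-law
#' tails whose coefficient is of order \eqn{e^{-\mu_Z^2/2\sigma_Z^2}};
#' for realistic intake parameters this is far below the tail tolerance,
#' so the truncated interval carries all measurable mass.
#'
#' @param params A [model1_params()] object.
#' @param tol Quadrature tolerance for integrals of the returned density.
#' @param tail_tol Probability mass allowed outside the support interval.
#' @return A [pl_density()] for \eqn{W}.
#' @examples
#' d <- proportion_density(model1_params(1305, 7395, 500, 500, 0.3))
#' density_moments(d)
#' @export
proportion_density <- function(params, tol = 1e-8, tail_tol = 1e-9) {
  stopifnot(inherits(params, "model1_params"))
  em <- energy_moments(params)
  pdf <- function(w) exp(.ratio_log_pdf(w, params$mu_U, em$mu_Z,
                                        params$sigma_U, em$sigma_Z,
                                        em$sigma_UZ))
  w0 <- params$mu_U / em$mu_Z
  # first-order delta-method SD of W, used as the expansion step scale
  s2 <- w0^2 * (params$sigma_U^2 / params$mu_U^2 + em$sigma_Z^2 / em$mu_Z^2 -
                  2 * em$sigma_UZ / (params$mu_U * em$mu_Z))
  scale <- sqrt(max(s2, (0.02 * w0)^2))
  support <- expand_support(pdf, w0, scale, tail_tol = tail_tol)
  pl_density(pdf, support, tol = tol, tail_tol = tail_tol)
}

#' Expected leverage coefficient under the no-leverage null
#'
#' Computes the slope one should expect from the log-log leverage
#' regression (log total energy on log proportion of energy from protein)
#' when intakes are bivariate normal and no leverage mechanism operates.
#' The chain is: mean of \eqn{W} from the exact ratio density; covariance
#' \eqn{\sigma_{WZ} = \mu_U - \mu_W \mu_Z}; a first-order (Taylor)
#' approximation of the log-scale covariance
#' \eqn{\sigma_{XY} = \log(1 + \sigma_{WZ}/(\mu_W \mu_Z))}; and the
#' expected slope \eqn{E(L) = \sigma_{XY}/\sigma_X^2}, with
#' \eqn{\sigma_X^2} the variance of \eqn{\log W}.
#'
#' The variance of \eqn{\log W} is computed on the positive part of the
#' ratio density, renormalized to the retained mass.  This mirrors the
#' treatment of simulated cohorts, where subjects with non-positive
#' simulated intakes are excluded before fitting; the retained mass is
#' returned so callers can flag parameter sets where the normal model
#' leaks appreciably below zero.
#'
#' @param params A [model1_params()] object.
#' @param tol Quadrature tolerance.
#' @return Object of class `"leverage_null"`: list with `expected_L`,
#'   `sigma_WZ`, `rho_WZ`, `sigma_XY`, `mu_W`, `sigma_W2`, `sigma_X2`,
#'   `pos_mass` (mass of the ratio density retained on the positive axis)
#'   and the input `params`.
#' @examples
#' expected_leverage(model1_params(1305, 7395, 361, 962, 0))
#' @export
expected_leverage <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "model1_params"))
  em <- energy_moments(params)
  dW <- proportion_density(params, tol = tol)
  mW <- density_moments(dW)
  # positive part, renormalized: matches exclusion of non-positive intakes
  dX <- log_transform_density(dW, neg_mass_tol = 1)
  mX <- density_moments(dX, renormalize = TRUE)
  sigma_WZ <- params$mu_U - mW$mean * em$mu_Z
  ratio <- sigma_WZ / (mW$mean * em$mu_Z)
  if (ratio <= -1)
    stop("log-scale covariance undefined: sigma_WZ/(mu_W mu_Z) = ",
         format(ratio, digits = 6), " <= -1 for mu_U = ", params$mu_U,
         ", mu_V = ", params$mu_V)
  sigma_XY <- log1p(ratio)
  structure(list(expected_L = sigma_XY / mX$variance,
                 sigma_WZ = sigma_WZ,
                 rho_WZ = sigma_WZ / (sqrt(mW$variance) * em$sigma_Z),
                 sigma_XY = sigma_XY,
                 mu_W = mW$mean, sigma_W2 = mW$variance,
                 sigma_X2 = mX$variance, pos_mass = dX$mass,
                 params = params),
            class = "leverage_null")
}

#' @export
print.leverage_null <- function(x, ...) {
  cat("Expected leverage under the no-leverage null\n")
  cat("  E(L)      ", format(x$expected_L, digits = 6), "\n")
  cat("  mu_W      ", format(x$mu_W, digits = 6),
      " sigma_W2 ", format(x$sigma_W2, digits = 6), "\n")
  cat("  sigma_WZ  ", format(x$sigma_WZ, digits = 6),
      " rho_WZ ", format(x$rho_WZ, digits = 4), "\n")
  cat("  sigma_XY  ", format(x$sigma_XY, digits = 6),
      " sigma_X2 ", format(x$sigma_X2, digits = 6), "\n")
  if (x$pos_mass < 0.999)
    cat("  note: only ", format(x$pos_mass, digits = 6),
        " of the ratio density lies above zero\n", sep = "")
  invisible(x)
}

# sigma_U, sigma_V implied by a share/dispersion mode at a grid point
.grid_sigmas <- function(mode, mu_U, mu_V, idr, sigma = 500, id_V = 125,
                         id_const = 100) {
  switch(mode,
    constant_variance = c(sigma, sigma),
    constant_ID = sqrt(id_const * c(mu_U, mu_V)),
    free_IDR = sqrt(c(idr * id_V * mu_U, id_V * mu_V)),
    stop("unknown mode '", mode, "'"))
}

#' Expected leverage over a grid of population conditions
#'
#' Evaluates [expected_leverage()] across protein shares, dispersion
#' ratios and intake correlations, under one of three variance regimes:
#' `"constant_variance"` (\eqn{\sigma_U = \sigma_V}, default 500 kJ),
#' `"constant_ID"` (equal index of dispersion, default 100 kJ, for both
#' nutrients) and `"free_IDR"` (non-protein index of dispersion fixed,
#' default 125 kJ, protein index a multiple `idr` of it).
#'
#' Grid points where the log-scale covariance is undefined, or where more
#' than 0.1% of the ratio density lies below zero (so the normal intake
#' model itself is strained), are flagged in the output rather than
#' dropped.
#'
#' @param share_grid Protein shares of total energy, in (0, 1); values are
#'   clipped to \[0.01, 0.99\].
#' @param idr_grid Index-of-dispersion ratios (used by mode `"free_IDR"`,
#'   otherwise a single placeholder of 1).
#' @param rho_grid Correlations between protein and non-protein intake.
#' @param mode Variance regime, see Details.
#' @param total Mean total energy intake in kJ (default 8700, a
#'   recommended adult daily intake).
#' @param sigma,id_V,id_const Mode-specific dispersion settings.
#' @param tol Quadrature tolerance passed through.
#' @return A data frame with columns `protein_share`, `idr`, `rho_uv`,
#'   `expected_L`, `flag`.
#' @export
leverage_grid <- function(share_grid = seq(0.05, 0.95, by = 0.05),
                          idr_grid = 1,
                          rho_grid = c(0, 0.3, 0.6, 0.9),
                          mode = c("constant_variance", "constant_ID",
                                   "free_IDR"),
                          total = 8700, sigma = 500, id_V = 125,
                          id_const = 100, tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(length(share_grid) > 0, length(rho_grid) > 0,
            length(idr_grid) > 0)
  share_grid <- pmin(pmax(share_grid, 0.01), 0.99)
  if (mode != "free_IDR") idr_grid <- 1
  g <- expand.grid(protein_share = share_grid, idr = idr_grid,
                   rho_uv = rho_grid, KEEP.OUT.ATTRS = FALSE)
  g$expected_L <- NA_real_
  g$flag <- ""
  for (i in seq_len(nrow(g))) {
    mu_U <- g$protein_share[i] * total
    mu_V <- total - mu_U
    s <- .grid_sigmas(mode, mu_U, mu_V, g$idr[i], sigma, id_V, id_const)
    p <- suppressWarnings(model1_params(mu_U, mu_V, s[1], s[2], g$rho_uv[i]))
    res <- tryCatch(expected_leverage(p, tol = tol), error = identity)
    if (inherits(res, "error")) {
      g$flag[i] <- conditionMessage(res)
    } else {
      g$expected_L[i] <- res$expected_L
      if (res$pos_mass < 0.999)
        g$flag[i] <- sprintf("pos_mass=%.4f", res$pos_mass)
    }
  }
  g
}
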