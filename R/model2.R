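#' Parameters of the leverage-generative intake model
#'
#' Forward model that assumes protein leverage is operating: the
#' proportion of energy from protein \eqn{W} follows a Beta(`kappa`,
#' `tau`) distribution, and log total energy intake is generated by the
#' leverage law \eqn{Y = \alpha + L \log W + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma_\varepsilon^2)}.  `L` is the
#' leverage slope (\eqn{-1} = complete leverage, 0 = none) and
#' \eqn{e^\alpha} is the natural-scale constant of the power law
#' \eqn{E = P p^L}.
#'
#' @param kappa,tau Beta shape parameters (> 0) of the protein
#'   proportion.
#' @param L Leverage slope, typically in \[-1, 0\].
#' @param alpha Intercept of the leverage law on the log-kJ scale
#'   (\eqn{\alpha = \log P}).
#' @param sigma_eps2 Residual variance of the leverage law on the log
#'   scale (> 0).
#' @return Object of class `"model2_params"`.
#' @seealso [beta_from_moments()] to derive `kappa`, `tau` from a target
#'   mean and SD of the proportion; [alpha_for_energy()] for the
#'   convention that pins modal total intake to a target energy.
#' @export
model2_params <- function(kappa, tau, L, alpha, sigma_eps2) {
  stopifnot(is.numeric(kappa), is.numeric(tau), is.numeric(L),
            is.numeric(alpha), is.numeric(sigma_eps2))
  if (kappa <= 0 || tau <= 0) stop("beta shapes must be strictly positive")
  if (sigma_eps2 <= 0) stop("residual variance must be strictly positive")
  structure(list(kappa = kappa, tau = tau, L = L, alpha = alpha,
                 sigma_eps2 = sigma_eps2), class = "model2_params")
}

#' @export
print.model2_params <- function(x, ...) {
  mu_W <- x$kappa / (x$kappa + x$tau)
  cat("Leverage-generative intake model\n",
      "  W ~ Beta(", format(x$kappa, digits = 6), ", ",
      format(x$tau, digits = 6), ")  [mean ", format(mu_W, digits = 4),
      "]\n  log E = ", format(x$alpha, digits = 6), " + ",
      format(x$L, digits = 4), " log W + eps,  var(eps) = ",
      format(x$sigma_eps2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Beta shape parameters from a mean and standard deviation
#'
#' Standard moment inversion: for target mean \eqn{\mu_W} and variance
#' \eqn{\sigma_W^2 < \mu_W(1-\mu_W)},
#' \eqn{\nu = \mu_W(1-\mu_W)/\sigma_W^2 - 1}, \eqn{\kappa = \mu_W \nu},
#' \eqn{\tau = (1-\mu_W)\nu}.
#'
#' @param mu_W Target mean proportion, in (0, 1).
#' @param sigma_W Target standard deviation; `sigma_W^2` must be below
#'   the feasibility bound `mu_W * (1 - mu_W)`.
#' @return Named numeric vector `c(kappa, tau)`.
#' @examples
#' beta_from_moments(0.5, sqrt(1 / 12))  # uniform: c(1, 1)
#' @export
beta_from_moments <- function(mu_W, sigma_W) {
  stopifnot(is.numeric(mu_W), is.numeric(sigma_W))
  if (mu_W <= 0 || mu_W >= 1) stop("mu_W must lie strictly in (0, 1)")
  bound <- mu_W * (1 - mu_W)
  if (sigma_W <= 0 || sigma_W^2 >= bound)
    stop("infeasible proportion variance: need 0 < sigma_W^2 < ",
         "mu_W(1-mu_W) = ", format(bound, digits = 6))
  nu <- bound / sigma_W^2 - 1
  c(kappa = mu_W * nu, tau = (1 - mu_W) * nu)
}

#' Intercept pinning the leverage law to a target energy intake
#'
#' Convention used throughout the model grids: the natural-scale constant
#' is \eqn{P = E_0 / \mu_W^L}, i.e. \eqn{\alpha = \log E_0 - L \log
#' \mu_W}, so the deterministic kernel of the leverage law passes through
#' `energy` kJ at the mean proportion.
#'
#' @param mu_W Mean proportion of energy from protein.
#' @param L Leverage slope.
#' @param energy Target energy in kJ (default 8700).
#' @return The intercept \eqn{\alpha} on the log scale.
#' @export
alpha_for_energy <- function(mu_W, L, energy = 8700) {
  log(energy) - L * log(mu_W)
}

# support of log W for a beta proportion, via extreme quantiles
.logbeta_support <- function(kappa, tau, q = 1e-13) {
  c(log(stats::qbeta(q, kappa, tau)),
    log(stats::qbeta(q, kappa, tau, lower.tail = FALSE)))
}

#' Density and moments of the log protein proportion under a beta model
#'
#' For \eqn{W \sim} Beta(`kappa`, `tau`), returns the density of
#' \eqn{X = \log W} by the method of transformation,
#' \eqn{f_X(x) = f_W(e^x) e^x}, with mean and variance computed by
#' quadrature.  (Closed forms via digamma/trigamma exist and are used as
#' oracles in the test suite; the quadrature path exercises the same
#' machinery used for densities with no closed form.)
#'
#' @param kappa,tau Beta shape parameters (> 0).
#' @param tol Quadrature tolerance.
#' @return List with elements `density` (a [pl_density()]) and `moments`
#'   (a `pl_moments`).
#' @export
log_proportion_stats <- function(kappa, tau, tol = 1e-10) {
  stopifnot(kappa > 0, tau > 0)
  pdf <- function(x) stats::dbeta(exp(x), kappa, tau) * exp(x)
  d <- pl_density(pdf, .logbeta_support(kappa, tau), tol = tol)
  list(density = d, moments = density_moments(d))
}

#' Density and moments of log total energy under the leverage law
#'
#' Log total energy is \eqn{Y = \alpha + L X + \varepsilon} with
#' \eqn{X = \log W} log-beta and \eqn{\varepsilon} normal.  The density
#' is the convolution of the rescaled-and-shifted log-beta density with
#' the normal residual kernel,
#' \eqn{f_Y(y) = \int f_X(x)\, \phi(y - \alpha - L x;\,
#' \sigma_\varepsilon)\, dx}, evaluated by fixed Gauss-Legendre
#' quadrature over the log-beta support.  `L = 0` is the degenerate case
#' \eqn{Y = \alpha + \varepsilon}, handled as a pure normal.
#'
#' @param params A [model2_params()] object.
#' @param tol Quadrature tolerance for moments of the returned density.
#' @param n_nodes Number of Gauss-Legendre nodes for the convolution.
#' @return List with `density` (a [pl_density()] for \eqn{Y}) and
#'   `moments`.
#' @export
log_energy_density <- function(params, tol = 1e-9, n_nodes = 400L) {
  stopifnot(inherits(params, "model2_params"))
  se <- sqrt(params$sigma_eps2)
  a <- params$alpha
  L <- params$L
  if (L == 0) {
    pdf <- function(y) stats::dnorm(y, a, se)
    d <- pl_density(pdf, c(a - 10 * se, a + 10 * se), tol = tol)
    return(list(density = d, moments = density_moments(d)))
  }
  xs <- .logbeta_support(params$kappa, params$tau)
  # exact first two moments of Y locate the support
  mX <- digamma(params$kappa) - digamma(params$kappa + params$tau)
  vX <- trigamma(params$kappa) - trigamma(params$kappa + params$tau)
  mY <- a + L * mX
  sY <- sqrt(L^2 * vX + params$sigma_eps2)
  ys <- sort(a + L * xs)
  # node spacing must resolve the normal kernel; when the residual is
  # negligible against the leverage term, drop to the pure change of
  # variables Y = alpha + L X (error O(sigma_eps^2 / var Y))
  n_need <- ceiling(4 * abs(L) * (xs[2] - xs[1]) / se)
  if (n_need > 8000L) {
    pdf <- function(y) {
      x <- (y - a) / L
      stats::dbeta(exp(x), params$kappa, params$tau) * exp(x) / abs(L)
    }
    d <- pl_density(pdf, ys, tol = tol)
    return(list(density = d, moments = density_moments(d)))
  }
  n_nodes <- max(n_nodes, n_need)
  gl <- pracma::gaussLegendre(n_nodes, xs[1], xs[2])
  wfx <- gl$w * stats::dbeta(exp(gl$x), params$kappa, params$tau) * exp(gl$x)
  nodes <- a + L * gl$x
  pdf <- function(y)
    vapply(y, function(yy) sum(wfx * stats::dnorm(yy - nodes, 0, se)),
           numeric(1))
  lo <- ys[1] - 8 * se
  hi <- ys[2] + 8 * se
  d <- pl_density(pdf, c(max(lo, mY - 12 * sY), min(hi, mY + 12 * sY)),
                  tol = tol)
  list(density = d, moments = density_moments(d))
}

#' Natural-scale energy moments from a log-energy density
#'
#' Transforms a density of \eqn{Y = \log Z} to the natural scale,
#' \eqn{f_Z(z) = f_Y(\log z)/z}, and returns the mean and variance of
#' total energy \eqn{Z} by quadrature.
#'
#' @param f_Y A [pl_density()] for log total energy.
#' @return A `pl_moments` for \eqn{Z} in kJ.
#' @export
energy_moments_natural <- function(f_Y) {
  stopifnot(inherits(f_Y, "pl_density"))
  pdf_z <- function(z) f_Y$pdf(log(z)) / z
  d <- pl_density(pdf_z, exp(f_Y$support), tol = f_Y$tol)
  density_moments(d)
}

#' Intake moments implied by the leverage-generative model
#'
#' Propagates the model parameters to means and variances of protein
#' intake \eqn{U = ZW}, non-protein intake \eqn{V = Z(1-W)} and their
#' logs, using log-scale addition plus a lognormal-style back-transform:
#' \eqn{\mu_{\log U} = \mu_X + \mu_Y},
#' \eqn{\sigma^2_{\log U} = \sigma_X^2 + \sigma_Y^2 + 2 L \sigma_X^2}
#' (the covariance \eqn{\sigma_{XY} = L\sigma_X^2} is exact), then
#' \eqn{\mu_U = \exp(\mu_{\log U} + \sigma^2_{\log U}/2)} and
#' \eqn{\sigma_U^2 = (e^{\sigma^2_{\log U}} - 1)\mu_U^2}.  The
#' non-protein mean is exact, \eqn{\mu_V = \mu_Z - \mu_U}; its variance
#' is approximated on the log scale through the log non-protein
#' proportion \eqn{S = \log(1 - W)} and the Taylor covariance
#' \eqn{\sigma_{SY} = \log(1 - (\mu_U - \mu_Z\mu_W) /
#' ((1-\mu_W)\mu_Z))}.
#'
#' The back-transform assumes log-scale normality, which holds only
#' approximately (log W is log-beta, not normal); the approximation is
#' validated against simulation in the package tests.
#'
#' @param params A [model2_params()] object.
#' @param tol Quadrature tolerance.
#' @param n_nodes Gauss-Legendre nodes for the log-energy convolution.
#' @return Object of class `"model2_moments"`: list of all log- and
#'   natural-scale means/variances and log-scale covariances.
#' @export
intake_moments <- function(params, tol = 1e-9, n_nodes = 400L) {
  stopifnot(inherits(params, "model2_params"))
  k <- params$kappa; t <- params$tau; L <- params$L
  mu_W <- k / (k + t)
  lps <- log_proportion_stats(k, t, tol = max(tol, 1e-10))
  mu_X <- lps$moments$mean; sigma_X2 <- lps$moments$variance
  led <- log_energy_density(params, tol = tol, n_nodes = n_nodes)
  mu_Y <- led$moments$mean; sigma_Y2 <- led$moments$variance
  mz <- energy_moments_natural(led$density)
  mu_Z <- mz$mean; sigma_Z2 <- mz$variance
  sigma_XY <- L * sigma_X2
  mu_logU <- mu_X + mu_Y
  sigma_logU2 <- sigma_X2 + sigma_Y2 + 2 * sigma_XY
  mu_U <- exp(mu_logU + sigma_logU2 / 2)
  sigma_U2 <- (exp(sigma_logU2) - 1) * mu_U^2
  mu_V <- mu_Z - mu_U
  # S = log(1 - W): log-beta with shapes swapped
  lqs <- log_proportion_stats(t, k, tol = max(tol, 1e-10))
  mu_S <- lqs$moments$mean; sigma_S2 <- lqs$moments$variance
  cov_1mW_Z <- -(mu_U - mu_Z * mu_W)
  arg <- 1 + cov_1mW_Z / ((1 - mu_W) * mu_Z)
  if (arg <= 0)
    stop("log-scale covariance sigma_SY undefined: argument ",
         format(arg, digits = 6), " <= 0 (mu_U = ", format(mu_U),
         ", mu_Z = ", format(mu_Z), ", mu_W = ", format(mu_W), ")")
  sigma_SY <- log(arg)
  sigma_logV2 <- sigma_S2 + sigma_Y2 + 2 * sigma_SY
  sigma_V2 <- (exp(sigma_logV2) - 1) * mu_V^2
  structure(list(mu_X = mu_X, sigma_X2 = sigma_X2,
                 mu_Y = mu_Y, sigma_Y2 = sigma_Y2,
                 mu_Z = mu_Z, sigma_Z2 = sigma_Z2,
                 mu_logU = mu_logU, sigma_logU2 = sigma_logU2,
                 mu_U = mu_U, sigma_U2 = sigma_U2,
                 mu_V = mu_V, sigma_V2 = sigma_V2,
                 mu_S = mu_S, sigma_S2 = sigma_S2,
                 sigma_XY = sigma_XY, sigma_SY = sigma_SY,
                 mu_W = mu_W, params = params),
            class = "model2_moments")
}

#' @export
print.model2_moments <- function(x, ...) {
  cat("Leverage-generative intake moments\n")
  cat(sprintf("  protein:      mean %8.1f kJ, var %.4g\n", x$mu_U, x$sigma_U2))
  cat(sprintf("  non-protein:  mean %8.1f kJ, var %.4g\n", x$mu_V, x$sigma_V2))
  cat(sprintf("  total energy: mean %8.1f kJ, var %.4g\n", x$mu_Z, x$sigma_Z2))
  invisible(x)
}

#' Index-of-dispersion ratio implied by the leverage-generative model
#'
#' The index of dispersion (ID) of an intake is its variance divided by
#' its mean; the index-of-dispersion ratio IDR = ID of protein / ID of
#' non-protein summarizes how much more tightly protein intake is
#' regulated than non-protein intake.  Strong leverage (L near -1)
#' compresses protein intake variance and drives the IDR toward 0; absent
#' leverage the IDR tends toward 1.
#'
#' @param params A [model2_params()] object.
#' @param ... Passed to [intake_moments()].
#' @return Object of class `"dispersion_summary"`: list with `id_U`,
#'   `id_V`, `idr`.
#' @export
idr_from_model <- function(params, ...) {
  m <- intake_moments(params, ...)
  new_dispersion_summary(m$sigma_U2 / m$mu_U, m$sigma_V2 / m$mu_V)
}

new_dispersion_summary <- function(id_U, id_V) {
  structure(list(id_U = id_U, id_V = id_V, idr = id_U / id_V),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("Dispersion: ID(protein) %.4g kJ, ID(non-protein) %.4g kJ, IDR %.4g\n",
              x$id_U, x$id_V, x$idr))
  invisible(x)
}

#' Model and simulated IDR over a grid of leverage conditions
#'
#' Evaluates the index-of-dispersion ratio implied by the
#' leverage-generative model over a grid of leverage slopes and beta
#' proportion parameters, optionally paired with the sample IDR of a
#' simulated cohort at each grid point.  The intercept follows the
#' [alpha_for_energy()] convention (deterministic kernel through
#' `energy` kJ at the mean proportion) and the residual variance defaults
#' to `log(8700) * 0.02`.
#'
#' @param L_grid Leverage slopes.
#' @param sigmaW_grid Proportion standard deviations.
#' @param muW_grid Proportion means.
#' @param sigma_eps2 Residual variance on the log scale.
#' @param energy Energy anchor in kJ for the intercept rule.
#' @param simulate If `TRUE`, also simulate `n_sim` subjects per grid
#'   point with [simulate_pl_generative()] and report the sample IDR.
#' @param n_sim Cohort size per grid point when simulating.
#' @param seed Base seed; point `i` uses `seed + i` so the grid is
#'   reproducible point-by-point.
#' @param ... Passed to [intake_moments()].
#' @return Data frame with columns `mu_W`, `sigma_W`, `L`, `idr_model`
#'   and, when simulating, `idr_sim` and `seed`.
#' @export
idr_grid <- function(L_grid = seq(-1, -0.1, by = 0.1),
                     sigmaW_grid = c(0.03, 0.05, 0.07),
                     muW_grid = c(0.125, 0.15, 0.175, 0.2),
                     sigma_eps2 = log(8700) * 0.02,
                     energy = 8700,
                     simulate = FALSE, n_sim = 100000L, seed = NULL, ...) {
  stopifnot(length(L_grid) > 0, length(sigmaW_grid) > 0, length(muW_grid) > 0)
  g <- expand.grid(mu_W = muW_grid, sigma_W = sigmaW_grid, L = L_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$idr_model <- NA_real_
  if (simulate) {
    g$idr_sim <- NA_real_
    g$seed <- if (is.null(seed)) NA_integer_ else seed + seq_len(nrow(g))
  }
  for (i in seq_len(nrow(g))) {
    sh <- beta_from_moments(g$mu_W[i], g$sigma_W[i])
    p <- model2_params(sh[["kappa"]], sh[["tau"]], g$L[i],
                       alpha_for_energy(g$mu_W[i], g$L[i], energy),
                       sigma_eps2)
    g$idr_model[i] <- idr_from_model(p, ...)$idr
    if (simulate) {
      tab <- simulate_pl_generative(p, n = n_sim,
                                    seed = if (is.null(seed)) NULL
                                           else g$seed[i])
      g$idr_sim[i] <- dispersion_summary(tab)$idr
    }
  }
  g
}
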