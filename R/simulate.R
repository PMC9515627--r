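#' Per-subject intake table
#'
#' Data frame of per-subject protein and non-protein energy intakes (kJ)
#' with generation provenance attached: generator name, parameters, seed,
#' number of subjects requested and number excluded.  Every retained
#' record has strictly positive intakes, and
#' `n_retained + n_excluded = n_requested`.
#'
#' @param protein_kj,nonprotein_kj Positive intakes in kJ.
#' @param covariates Optional data frame of per-subject covariates.
#' @param provenance List describing how the table was generated.
#' @return Object of classes `"intake_table"` and `"data.frame"` with
#'   columns `subject_id`, `protein_kj`, `nonprotein_kj` and any
#'   covariates.
#' @export
intake_table <- function(protein_kj, nonprotein_kj, covariates = NULL,
                         provenance = list()) {
  stopifnot(is.numeric(protein_kj), is.numeric(nonprotein_kj),
            length(protein_kj) == length(nonprotein_kj))
  if (any(protein_kj <= 0) || any(nonprotein_kj <= 0))
    stop("intake_table(): all retained intakes must be strictly positive")
  out <- data.frame(subject_id = seq_along(protein_kj),
                    protein_kj = protein_kj,
                    nonprotein_kj = nonprotein_kj)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(out))
    out <- cbind(out, covariates)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("intake_table", "data.frame")
  out
}

#' @export
print.intake_table <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat("Intake table: ", nrow(x), " subjects", sep = "")
  if (!is.null(pr$generator))
    cat(" (", pr$generator, ", ", pr$n_excluded, " of ", pr$n_requested,
        " draws excluded, seed ",
        if (is.null(pr$seed)) "none" else pr$seed, ")", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Simulate a cohort with bivariate-normal intakes
#'
#' Draws `n` subjects with protein and non-protein energy intake from the
#' bivariate normal distribution described by `params`.  Because a normal
#' intake model can produce negative draws, any subject with a
#' non-positive intake on either axis is excluded and counted in the
#' table's provenance; a warning is emitted when exclusions exceed 0.1%
#' of `n`.
#'
#' @param params A [model1_params()] object.
#' @param n Number of subjects to draw (>= 2).
#' @param seed Optional integer seed; identical seed and parameters give
#'   an identical table.
#' @return An [intake_table()].
#' @examples
#' tab <- simulate_bivariate_normal(model1_params(1305, 7395, 361, 962, 0),
#'                                  n = 1000, seed = 1)
#' dispersion_summary(tab)
#' @export
simulate_bivariate_normal <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "model1_params"), n >= 2)
  .set_seed(seed)
  s_uv <- params$rho_UV * params$sigma_U * params$sigma_V
  S <- matrix(c(params$sigma_U^2, s_uv, s_uv, params$sigma_V^2), 2)
  d <- MASS::mvrnorm(n, c(params$mu_U, params$mu_V), S)
  keep <- d[, 1] > 0 & d[, 2] > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0.001 * n)
    warning(sprintf("%d of %d simulated subjects (%.2f%%) had non-positive intakes and were excluded",
                    n_excluded, n, 100 * n_excluded / n), call. = FALSE)
  intake_table(d[keep, 1], d[keep, 2],
               provenance = list(generator = "bivariate_normal",
                                 params = unclass(params), seed = seed,
                                 n_requested = as.integer(n), n_excluded = n_excluded))
}

# natural-scale (m, s) -> lognormal log-scale (meanlog, sdlog)
.lnorm_pars <- function(m, s) {
  s2 <- log1p(s^2 / m^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a cohort with bivariate-lognormal intakes
#'
#' Draws `n` subjects with lognormal protein and non-protein intakes via
#' a Gaussian copula.  Under the default `"natural"` convention the
#' log-scale parameters are chosen so the natural-scale means and SDs
#' match `params`, and the log-scale correlation is adjusted analytically
#' so the natural-scale correlation hits `rho_UV`: for lognormals with
#' log-scale sds \eqn{s_1, s_2} and log-scale correlation \eqn{r},
#' \eqn{\mathrm{cor}(U,V) = (e^{r s_1 s_2} - 1)/
#' \sqrt{(e^{s_1^2}-1)(e^{s_2^2}-1)}}, which is inverted for \eqn{r}.
#' Correlations outside the attainable lognormal range are an error
#' stating the bounds.  Under the `"log"` convention `params` is read as
#' the mean/SD/correlation of the underlying normal on the log scale and
#' exponentiated directly.
#'
#' All draws are positive by construction, so no exclusions occur.
#'
#' @param params A [model1_params()] object (interpreted per
#'   `convention`).
#' @param n Number of subjects (>= 2).
#' @param seed Optional integer seed.
#' @param convention `"natural"` (default) or `"log"`, see Details.
#' @return An [intake_table()].
#' @export
simulate_bivariate_lognormal <- function(params, n, seed = NULL,
                                         convention = c("natural", "log")) {
  stopifnot(inherits(params, "model1_params"), n >= 2)
  convention <- match.arg(convention)
  if (convention == "log") {
    tab <- simulate_bivariate_normal(
      suppressWarnings(model1_params(params$mu_U, params$mu_V,
                                     params$sigma_U, params$sigma_V,
                                     params$rho_UV)), n, seed)
    out <- intake_table(exp(tab$protein_kj), exp(tab$nonprotein_kj),
                        provenance = list(generator = "bivariate_lognormal",
                                          convention = "log",
                                          params = unclass(params),
                                          seed = seed, n_requested = as.integer(n),
                                          n_excluded = 0L))
    return(out)
  }
  pu <- .lnorm_pars(params$mu_U, params$sigma_U)
  pv <- .lnorm_pars(params$mu_V, params$sigma_V)
  s1 <- pu[["sdlog"]]; s2 <- pv[["sdlog"]]
  denom <- sqrt(expm1(s1^2) * expm1(s2^2))
  r_target <- params$rho_UV
  arg <- 1 + r_target * denom
  r_lo <- (exp(-s1 * s2) - 1) / denom
  r_hi <- (exp(s1 * s2) - 1) / denom
  if (arg <= 0 || abs(log(arg) / (s1 * s2)) > 1)
    stop(sprintf("natural-scale correlation %.4f is outside the attainable lognormal range [%.4f, %.4f]",
                 r_target, r_lo, r_hi))
  r_log <- log(arg) / (s1 * s2)
  .set_seed(seed)
  S <- matrix(c(1, r_log, r_log, 1), 2)
  zz <- MASS::mvrnorm(n, c(0, 0), S)
  u <- exp(pu[["meanlog"]] + s1 * zz[, 1])
  v <- exp(pv[["meanlog"]] + s2 * zz[, 2])
  intake_table(u, v,
               provenance = list(generator = "bivariate_lognormal",
                                 convention = "natural",
                                 params = unclass(params), seed = seed,
                                 n_requested = as.integer(n), n_excluded = 0L))
}

#' Simulate a cohort from the leverage-generative model
#'
#' Draws proportions \eqn{W \sim} Beta(`kappa`, `tau`) and residuals
#' \eqn{\varepsilon \sim N(0, \sigma_\varepsilon^2)}, forms log total
#' energy \eqn{Y = \alpha + L \log W + \varepsilon}, total energy
#' \eqn{Z = e^Y}, and splits it as \eqn{U = ZW}, \eqn{V = Z(1-W)}.  All
#' intakes are positive by construction; no exclusions are possible.
#' The drawn proportion is returned as covariate `w` (it equals
#' `protein_kj / (protein_kj + nonprotein_kj)` to machine precision).
#'
#' @param params A [model2_params()] object.
#' @param n Number of subjects (>= 2).
#' @param seed Optional integer seed.
#' @return An [intake_table()] with covariate column `w`.
#' @examples
#' sh <- beta_from_moments(0.2, 0.05)
#' p <- model2_params(sh[["kappa"]], sh[["tau"]], L = -0.5,
#'                    alpha = alpha_for_energy(0.2, -0.5),
#'                    sigma_eps2 = log(8700) * 0.02)
#' tab <- simulate_pl_generative(p, n = 2000, seed = 7)
#' coef(fit_leverage(tab))
#' @export
simulate_pl_generative <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "model2_params"), n >= 2)
  .set_seed(seed)
  w <- stats::rbeta(n, params$kappa, params$tau)
  eps <- stats::rnorm(n, 0, sqrt(params$sigma_eps2))
  y <- params$alpha + params$L * log(w) + eps
  z <- exp(y)
  intake_table(z * w, z * (1 - w), covariates = data.frame(w = w),
               provenance = list(generator = "pl_generative",
                                 params = unclass(params), seed = seed,
                                 n_requested = as.integer(n), n_excluded = 0L))
}

#' Write an intake table with its provenance header
#'
#' Serializes an [intake_table()] as CSV preceded by commented JSON
#' provenance lines (`# provenance: {...}`), so a table can be shared and
#' re-read without losing how it was generated.
#'
#' @param table An [intake_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intake_csv <- function(table, path) {
  stopifnot(inherits(table, "intake_table"))
  pr <- attr(table, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(pr))
    writeLines(paste("# provenance:",
                     jsonlite::toJSON(pr, auto_unbox = TRUE, digits = NA)),
               con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Read an intake table written by [write_intake_csv()]
#'
#' @param path CSV path; commented provenance lines are restored.
#' @return An [intake_table()].
#' @export
read_intake_csv <- function(path) {
  first <- readLines(path, n = 1L)
  pr <- list()
  if (startsWith(first, "# provenance:"))
    pr <- jsonlite::fromJSON(sub("^# provenance: ", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  covs <- df[, setdiff(names(df), c("subject_id", "protein_kj",
                                    "nonprotein_kj")), drop = FALSE]
  intake_table(df$protein_kj, df$nonprotein_kj,
               covariates = if (ncol(covs)) covs else NULL,
               provenance = pr)
}
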