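#' Estimate the strength of protein leverage from an intake table
#'
#' Fits the leverage law on the log scale: ordinary least squares of
#' \eqn{y_i = \log E_i} (log total energy, kJ) on
#' \eqn{x_i = \log p_i} (log proportion of energy from protein), with
#' optional covariate columns added as a multiple regression to adjust
#' for confounders such as age or sex.  The slope is the leverage
#' coefficient \eqn{L} (\eqn{-1} = complete protein leverage, 0 = none)
#' and the back-transformed intercept \eqn{\hat P = e^{\hat\alpha}}
#' estimates the leveraged protein target in kJ.  Natural logarithms are
#' used throughout, so the intercept is on the log-kJ scale.
#'
#' @param table An [intake_table()] (or data frame with columns
#'   `protein_kj` and `nonprotein_kj`); all used records must have
#'   strictly positive intakes.
#' @param covariates Character vector of covariate column names to
#'   adjust for.
#' @return An object of class `"leverage_fit"` with components
#'   `L_hat`, `alpha_hat`, `P_hat`, `se_L`, `resid_var`, `n_used`,
#'   `covariates_adjusted`, `method`, and the underlying `lm` fit.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`,
#'   `residuals()`, `plot()`, `confint()` and `simulate()`.
#' @examples
#' # strict protein defence: constant protein, varying non-protein
#' tab <- intake_table(rep(1305, 50), seq(2000, 10000, length.out = 50))
#' fit <- fit_leverage(tab)
#' fit       # slope -1, P_hat 1305 kJ
#' @export
fit_leverage <- function(table, covariates = NULL) {
  df <- .check_intakes(table)
  if (nrow(df) < 3) stop("need at least 3 records to fit the leverage law")
  dat <- data.frame(y = log(df$protein_kj + df$nonprotein_kj),
                    x = log(df$protein_kj /
                              (df$protein_kj + df$nonprotein_kj)))
  if (!is.null(covariates)) {
    missing_cols <- setdiff(covariates, names(df))
    if (length(missing_cols))
      stop("covariate column(s) not found: ",
           paste(missing_cols, collapse = ", "))
    dat <- cbind(dat, df[covariates])
  }
  fml <- stats::reformulate(c("x", covariates), response = "y")
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  # noiseless data (e.g. strict defence) triggers R's perfect-fit warning;
  # the coefficients are exact there, so muffle just that message
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(L_hat = unname(coef(fit)["x"]),
                 alpha_hat = unname(coef(fit)["(Intercept)"]),
                 P_hat = exp(unname(coef(fit)["(Intercept)"])),
                 se_L = sm$coefficients["x", "Std. Error"],
                 resid_var = sm$sigma^2,
                 n_used = nrow(dat),
                 covariates_adjusted = covariates %||% character(),
                 method = "loglog",
                 fit = fit, data = dat),
            class = "leverage_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_intakes <- function(table) {
  df <- as.data.frame(table)
  if (!all(c("protein_kj", "nonprotein_kj") %in% names(df)))
    stop("table must have columns 'protein_kj' and 'nonprotein_kj'")
  bad <- which(df$protein_kj <= 0 | df$nonprotein_kj <= 0 |
                 !is.finite(df$protein_kj) | !is.finite(df$nonprotein_kj))
  if (length(bad))
    stop("non-positive or missing intakes in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  df
}

#' Fit the power-law form of the leverage relationship
#'
#' Nonlinear least squares of total energy on the proportion of energy
#' from protein on the natural scale, \eqn{E = P p^L}, initialized from
#' the log-log fit.  Compared with [fit_leverage()] this weights absolute
#' rather than relative deviations in energy; on noiseless power-law data
#' the two agree exactly.
#'
#' @param table An [intake_table()] or compatible data frame.
#' @return A `"leverage_fit"` object with `method = "powerlaw"` (no
#'   covariate adjustment; the underlying fit is an `nls` object).
#' @export
fit_power_law <- function(table) {
  df <- .check_intakes(table)
  start_fit <- fit_leverage(df)
  dat <- data.frame(E = df$protein_kj + df$nonprotein_kj,
                    p = df$protein_kj / (df$protein_kj + df$nonprotein_kj))
  fit <- tryCatch(
    minpack.lm::nlsLM(E ~ P * p^L, data = dat,
                      start = list(P = start_fit$P_hat, L = start_fit$L_hat),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  sm <- summary(fit)
  structure(list(L_hat = unname(cf["L"]),
                 alpha_hat = log(unname(cf["P"])),
                 P_hat = unname(cf["P"]),
                 se_L = sm$coefficients["L", "Std. Error"],
                 resid_var = sm$sigma^2,
                 n_used = nrow(dat),
                 covariates_adjusted = character(),
                 method = "powerlaw",
                 fit = fit, data = dat),
            class = "leverage_fit")
}

#' @export
print.leverage_fit <- function(x, digits = 4, ...) {
  cat("Protein-leverage fit (", x$method, ")\n", sep = "")
  cat("  L_hat  ", format(x$L_hat, digits = digits),
      "  (se ", format(x$se_L, digits = digits), ")\n", sep = "")
  cat("  P_hat  ", format(x$P_hat, digits = max(digits, 6)),
      " kJ  (alpha_hat ", format(x$alpha_hat, digits = digits), ")\n",
      sep = "")
  cat("  n ", x$n_used,
      if (length(x$covariates_adjusted))
        paste0(", adjusted for ",
               paste(x$covariates_adjusted, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.leverage_fit <- function(object, ...) {
  c(L = object$L_hat, alpha = object$alpha_hat)
}

#' @export
residuals.leverage_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
predict.leverage_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$fit, ...))
  df <- .check_intakes(newdata)
  if (object$method == "powerlaw") {
    nd <- data.frame(p = df$protein_kj / (df$protein_kj + df$nonprotein_kj))
  } else {
    nd <- data.frame(x = log(df$protein_kj /
                               (df$protein_kj + df$nonprotein_kj)))
    covs <- object$covariates_adjusted
    if (length(covs)) nd <- cbind(nd, df[covs])
  }
  predict(object$fit, newdata = nd, ...)
}

#' @export
confint.leverage_fit <- function(object, parm, level = 0.95, ...) {
  ci <- suppressMessages(confint(object$fit, level = level, ...))
  rownames(ci) <- sub("^x$", "L", sub("^\\(Intercept\\)$", "alpha",
                                      rownames(ci)))
  rownames(ci) <- sub("^P$", "P", rownames(ci))
  ci
}

#' @export
summary.leverage_fit <- function(object, ...) {
  sp <- stats::cor(object$data[[if (object$method == "powerlaw") "p" else "x"]],
                   object$data[[if (object$method == "powerlaw") "E" else "y"]],
                   method = "spearman")
  structure(list(fit = object, spearman = sp,
                 lm_summary = summary(object$fit)),
            class = "summary.leverage_fit")
}

#' @export
print.summary.leverage_fit <- function(x, ...) {
  print(x$fit)
  cat("  Spearman cor(log p, log E): ", format(x$spearman, digits = 4),
      "  (rank-based leverage diagnostic)\n", sep = "")
  cat("\n")
  print(x$lm_summary)
  invisible(x)
}

#' @export
plot.leverage_fit <- function(x, ...) {
  if (x$method == "powerlaw") {
    graphics::plot(x$data$p, x$data$E, xlab = "proportion energy from protein",
                   ylab = "total energy (kJ)", pch = 16,
                   col = grDevices::adjustcolor("grey30", 0.4), ...)
    p_seq <- seq(min(x$data$p), max(x$data$p), length.out = 200)
    graphics::lines(p_seq, x$P_hat * p_seq^x$L_hat, col = "firebrick",
                    lwd = 2)
  } else {
    graphics::plot(x$data$x, x$data$y, xlab = "log proportion from protein",
                   ylab = "log total energy", pch = 16,
                   col = grDevices::adjustcolor("grey30", 0.4), ...)
    graphics::abline(x$alpha_hat, x$L_hat, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate intake tables from a fitted leverage law
#'
#' Parametric simulation conditional on the observed proportions: new log
#' total energies are drawn from the fitted leverage law with Gaussian
#' residuals at the fitted residual variance, and split into protein and
#' non-protein energy by the observed proportions.
#'
#' @param object A `"leverage_fit"` from [fit_leverage()].
#' @param nsim Number of replicate tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [intake_table()] objects.
#' @export
simulate.leverage_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$method != "loglog")
    stop("simulate() is only implemented for the log-log fit")
  .set_seed(seed)
  p <- exp(object$data$x)
  mu <- as.numeric(predict(object$fit))
  lapply(seq_len(nsim), function(i) {
    e <- exp(mu + stats::rnorm(length(mu), 0, sqrt(object$resid_var)))
    intake_table(e * p, e * (1 - p),
                 provenance = list(generator = "leverage_fit_simulate",
                                   seed = seed, n_requested = length(mu),
                                   n_excluded = 0L))
  })
}

#' Sample dispersion summary of an intake table
#'
#' Index of dispersion (unbiased sample variance over sample mean) for
#' protein and non-protein intake, and their ratio (IDR).  An IDR well
#' below 1 indicates protein intake is more tightly regulated than
#' non-protein intake, the dispersion signature of protein leverage.
#'
#' @param table An [intake_table()] or compatible data frame (n >= 2).
#' @return A `"dispersion_summary"` object.
#' @export
dispersion_summary <- function(table) {
  df <- .check_intakes(table)
  if (nrow(df) < 2) stop("need at least 2 records")
  new_dispersion_summary(stats::var(df$protein_kj) / mean(df$protein_kj),
                         stats::var(df$nonprotein_kj) /
                           mean(df$nonprotein_kj))
}

#' Coefficient-of-variation ratio between measurement methods
#'
#' Compares the dispersion of intakes measured by objective biomarkers
#' with that measured by a dietary assessment tool (DAT):
#' CVR = CV(biomarker) / CV(DAT).  A CVR near 1 indicates the DAT
#' captures between-subject intake variation as faithfully as the
#' biomarker does.
#'
#' @param cv_biomarker,cv_dat Positive coefficients of variation.
#' @return Object of class `"cvr_summary"`: list with `cv_biomarker`,
#'   `cv_dat`, `cvr`.
#' @examples
#' cvr(0.24, 0.25)  # 0.96
#' @export
cvr <- function(cv_biomarker, cv_dat) {
  stopifnot(is.numeric(cv_biomarker), is.numeric(cv_dat))
  if (any(cv_biomarker <= 0) || any(cv_dat <= 0))
    stop("coefficients of variation must be strictly positive")
  structure(list(cv_biomarker = cv_biomarker, cv_dat = cv_dat,
                 cvr = cv_biomarker / cv_dat), class = "cvr_summary")
}

#' @export
print.cvr_summary <- function(x, ...) {
  cat(sprintf("CVR %.4g  (CV biomarker %.4g / CV DAT %.4g)\n",
              x$cvr, x$cv_biomarker, x$cv_dat))
  invisible(x)
}
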