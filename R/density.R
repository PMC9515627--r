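#' One-dimensional probability density with an explicit quadrature contract
#'
#' Container used throughout the package for analytically derived densities
#' (proportion of energy from protein, its log, log total energy, and so
#' on).  The support bounds delimit the region carrying at least
#' `1 - tail_tol` of the probability mass; all moment integrals are taken
#' over that region.  Construction fails if the density does not integrate
#' to 1 within `norm_tol` on its stated support, and the achieved integral
#' is reported in the error message.
#'
#' @param pdf Vectorised function of one numeric argument returning
#'   non-negative densities.
#' @param support Numeric length-2 vector `c(lo, hi)` bounding the region
#'   that carries at least `1 - tail_tol` of the mass.
#' @param tol Absolute/relative quadrature tolerance used for integrals of
#'   this density.
#' @param tail_tol Mass allowed outside `support`.
#' @param norm_tol Permitted deviation of the integral over `support`
#'   from 1.
#' @param check When `FALSE` the normalization check is skipped (used
#'   internally for deliberately sub-normalized truncations).
#' @return An object of class `"pl_density"`: a list with elements `pdf`,
#'   `support`, `tol`, `tail_tol` and `mass` (the achieved integral).
#' @seealso [density_moments()], [log_transform_density()]
#' @export
pl_density <- function(pdf, support, tol = 1e-8, tail_tol = 1e-9,
                       norm_tol = 1e-5, check = TRUE) {
  stopifnot(is.function(pdf), is.numeric(support), length(support) == 2L,
            support[1] < support[2], tol > 0)
  mass <- quad(pdf, support[1], support[2], tol)
  if (check && abs(mass - 1) > norm_tol)
    stop("density failed to normalize on [", format(support[1]), ", ",
         format(support[2]), "]: integral is ", format(mass, digits = 10))
  structure(list(pdf = pdf, support = support, tol = tol,
                 tail_tol = tail_tol, mass = mass),
            class = "pl_density")
}

#' @export
print.pl_density <- function(x, ...) {
  cat("<pl_density> support [", format(x$support[1], digits = 6), ", ",
      format(x$support[2], digits = 6), "], mass ",
      format(x$mass, digits = 8), ", tol ", format(x$tol), "\n", sep = "")
  invisible(x)
}

# Adaptive quadrature with the package-wide error contract: a
# non-convergent integral is reported together with its estimate and
# error bound instead of being returned silently.
quad <- function(f, lo, hi, tol = 1e-8) {
  res <- tryCatch(
    stats::integrate(f, lo, hi, rel.tol = tol, abs.tol = tol,
                     subdivisions = 400L, stop.on.error = FALSE),
    error = function(e) stop("quadrature failed on [", format(lo), ", ",
                             format(hi), "]: ", conditionMessage(e)))
  if (!res$message %in% c("OK", "maximum number of subdivisions reached") ||
      !is.finite(res$value))
    stop("quadrature did not converge on [", format(lo), ", ", format(hi),
         "]: estimate ", format(res$value), " +/- ", format(res$abs.error),
         " (", res$message, ")")
  res$value
}

# Locate an interval around `center` carrying all but `tail_tol` of the
# mass of `pdf`, by stepping outward in units of `scale` and stopping once
# the newly added shell on a side contributes less than tail_tol / 4.
expand_support <- function(pdf, center, scale, tail_tol = 1e-9,
                           step = 4, max_steps = 80L) {
  lo <- center - 2 * step * scale
  hi <- center + 2 * step * scale
  for (i in seq_len(max_steps)) {
    new_lo <- lo - step * scale
    shell <- quad(pdf, new_lo, lo, tol = tail_tol / 10)
    lo <- new_lo
    if (shell < tail_tol / 4) break
  }
  for (i in seq_len(max_steps)) {
    new_hi <- hi + step * scale
    shell <- quad(pdf, hi, new_hi, tol = tail_tol / 10)
    hi <- new_hi
    if (shell < tail_tol / 4) break
  }
  c(lo, hi)
}

#' Mean and variance of a density by adaptive quadrature
#'
#' @param d A [pl_density()] object.
#' @param renormalize Divide by the achieved mass on the support.  The
#'   default `FALSE` is correct for fully normalized densities; `TRUE` is
#'   used for densities deliberately truncated to a sub-region (for
#'   example the positive part of a ratio-of-normals density, mirroring
#'   the exclusion of non-positive simulated intakes).
#' @return An object of class `"pl_moments"`: list with `mean` and
#'   `variance`.
#' @export
density_moments <- function(d, renormalize = FALSE) {
  stopifnot(inherits(d, "pl_density"))
  m0 <- if (renormalize) d$mass else 1
  mu <- quad(function(x) x * d$pdf(x), d$support[1], d$support[2], d$tol) / m0
  v <- quad(function(x) (x - mu)^2 * d$pdf(x), d$support[1], d$support[2],
            d$tol) / m0
  structure(list(mean = mu, variance = v), class = "pl_moments")
}

#' @export
print.pl_moments <- function(x, ...) {
  cat("<pl_moments> mean ", format(x$mean, digits = 8), ", variance ",
      format(x$variance, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Density of the natural log of a positive random variable
#'
#' Given the density \eqn{f_W} of a variable supported on the positive
#' reals, returns the density of \eqn{X = \log W} by the method of
#' transformation, \eqn{f_X(x) = f_W(e^x) e^x}.  Used to move the
#' proportion-of-energy-from-protein density onto the scale of the
#' log-log leverage regression.
#'
#' @param d A [pl_density()] whose support lies in the positive reals, up
#'   to the tail-mass convention: mass on the non-positive axis up to
#'   `neg_mass_tol` is truncated away, more is an error.
#' @param neg_mass_tol Largest tolerated probability mass at or below
#'   zero.  The error message names the offending mass.
#' @return A [pl_density()] for \eqn{\log W}.  When mass was truncated at
#'   zero the returned object records the retained mass in its `mass`
#'   field (the normalization check is applied to that retained mass).
#' @export
log_transform_density <- function(d, neg_mass_tol = 1e-9) {
  stopifnot(inherits(d, "pl_density"))
  lo <- d$support[1]
  neg_mass <- 0
  if (lo <= 0) {
    neg_mass <- quad(d$pdf, lo, 0, d$tol)
    if (neg_mass > neg_mass_tol)
      stop("density carries mass ", format(neg_mass, digits = 6),
           " on the non-positive axis; log transform undefined beyond the ",
           format(neg_mass_tol), " tail tolerance")
    # clip just above zero; the excluded mass is within the caller's tolerance
    lo <- d$support[2] * 1e-12
  }
  pdf_x <- function(x) d$pdf(exp(x)) * exp(x)
  # truncation beyond the normalization tolerance leaves a deliberately
  # sub-normalized density; its retained mass is recorded, not rejected
  pl_density(pdf_x, c(log(lo), log(d$support[2])), tol = d$tol,
             tail_tol = d$tail_tol, norm_tol = 1e-5,
             check = neg_mass <= 1e-5)
}
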