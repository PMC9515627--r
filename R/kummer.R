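#' Kummer's confluent hypergeometric function of the first kind
#'
#' Evaluates \eqn{M(\theta, \gamma, \zeta) = \sum_{k\ge 0}
#' (\theta)_k/(\gamma)_k \cdot \zeta^k/k!}, where \eqn{(a)_k} is the rising
#' factorial.  This function appears in the exact density of a ratio of two
#' correlated normal random variables, which is how the proportion of energy
#' from protein is distributed when protein and non-protein intakes are
#' jointly normal (see [proportion_density()]).
#'
#' Three evaluation strategies are used, chosen by argument:
#' the defining power series for moderate \eqn{\zeta \ge 0}; the Kummer
#' transformation \eqn{M(\theta,\gamma,\zeta) = e^\zeta
#' M(\gamma-\theta,\gamma,-\zeta)} for negative \eqn{\zeta} (where the raw
#' series suffers catastrophic cancellation); and the large-argument
#' asymptotic expansion \eqn{M \sim \Gamma(\gamma)/\Gamma(\theta)\,
#' e^\zeta \zeta^{\theta-\gamma}\sum_k (\gamma-\theta)_k(1-\theta)_k /
#' (k!\,\zeta^k)} for \eqn{\zeta > 50}, truncated at its smallest term.
#' Intake densities generate very large positive arguments, so the
#' large-argument branch is evaluated on the log scale and overflow of the
#' final value is signalled as an error rather than returned as `Inf`.
#'
#' @param theta Numerator parameter (scalar).
#' @param gamma Denominator parameter; must not be zero or a negative
#'   integer (the series is undefined there).
#' @param zeta Argument (scalar).
#' @return The value of \eqn{M(\theta,\gamma,\zeta)} as a double.
#' @examples
#' kummer_M(1, 0.5, 0)       # 1
#' kummer_M(2, 2, 1)         # exp(1): theta == gamma collapses the series
#' kummer_M(1, 0.5, 2)
#' @export
kummer_M <- function(theta, gamma, zeta) {
  stopifnot(is.numeric(theta), is.numeric(gamma), is.numeric(zeta),
            length(theta) == 1L, length(gamma) == 1L, length(zeta) == 1L,
            is.finite(theta), is.finite(gamma), is.finite(zeta))
  if (gamma <= 0 && abs(gamma - round(gamma)) < .Machine$double.eps * 4)
    stop("kummer_M(): 'gamma' must not be zero or a negative integer (got ",
         gamma, ")")
  if (theta == gamma) {
    out <- exp(zeta)
    if (!is.finite(out))
      stop("kummer_M(): overflow, log of result is ", zeta)
    return(out)
  }
  if (zeta == 0) return(1)
  if (zeta < 0) {
    # Kummer transformation: alternating series at -zeta is stable
    if (-zeta > 50) {
      lg <- .kummer_log_asymptotic(gamma - theta, gamma, -zeta) + zeta
      return(exp(lg))           # underflows gracefully to 0 for deep negatives
    }
    return(exp(zeta) * .kummer_series(gamma - theta, gamma, -zeta))
  }
  if (zeta <= 50) return(.kummer_series(theta, gamma, zeta))
  lg <- .kummer_log_asymptotic(theta, gamma, zeta)
  if (lg > log(.Machine$double.xmax))
    stop("kummer_M(): overflow, log of result is ", format(lg))
  exp(lg)
}

# Defining series; terms are positive for zeta > 0 so summation is stable.
.kummer_series <- function(a, b, z, tol = 1e-16, kmax = 2000L) {
  term <- 1
  total <- 1
  for (k in seq_len(kmax)) {
    term <- term * (a + k - 1) / (b + k - 1) * z / k
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  warning("kummer_M(): series did not reach tolerance after ", kmax, " terms")
  total
}

# log of the large-z asymptotic expansion, truncated at the smallest term.
# Requires z > 0 and gamma(a) finite.
.kummer_log_asymptotic <- function(a, b, z, kmax = 60L) {
  s <- 1
  term <- 1
  prev <- Inf
  for (k in seq_len(kmax)) {
    term <- term * (b - a + k - 1) * (k - a) / (k * z)
    if (abs(term) > prev) break   # divergent asymptotic tail: stop at minimum
    s <- s + term
    prev <- abs(term)
    if (abs(term) < 1e-16 * abs(s)) break
  }
  lgamma(b) - lgamma(a) + z + (a - b) * log(z) + log(s)
}

# log M(1, 1/2, z) for z >= 0 via the closed form
#   M(1, 1/2, z) = 1 + sqrt(pi z) e^z erf(sqrt z),
# stable for the large arguments produced by the ratio density kernel.
.log_kummer_M_1_half <- function(z) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  small <- z < 1e-12
  out <- numeric(length(z))
  out[small] <- log1p(2 * z[small])
  zl <- z[!small]
  out[!small] <- zl + log(sqrt(pi * zl) * erf(sqrt(zl)) + exp(-zl))
  out
}
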