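#' Cohen's f-squared from partial eta-squared
#'
#' `f2 = eta2 / (1 - eta2)`, the conversion used by repeated-measures power
#' calculators.
#'
#' @param eta_sq Partial eta-squared, strictly between 0 and 1.
#' @return f-squared.
#' @export
effect_size_f2 <- function(eta_sq) {
  if (any(eta_sq <= 0 | eta_sq >= 1)) stop("eta_sq must be in (0, 1)")
  eta_sq / (1 - eta_sq)
}

#' Specification for a repeated-measures power analysis
#'
#' Bundles the quantities entering the within-subjects noncentral-F power
#' computation: effect size, alpha, target power, number of measurements `m`,
#' correlation among repeated measures `rho`, and nonsphericity `epsilon`.
#' The defaults `rho = 0.5` and `epsilon = 1` are the conventional values
#' assumed when a study reports only eta-squared, alpha, power and `m`.
#'
#' @param eta_sq Partial eta-squared in (0, 1).
#' @param alpha Type-I error probability in (0, 1).
#' @param target_power Desired power in (0, 1).
#' @param m Number of repeated measurements (>= 2).
#' @param rho Correlation among repeated measures in (0, 1).
#' @param epsilon Nonsphericity correction in (0, 1].
#' @return A `power_spec` list.
#' @export
power_spec <- function(eta_sq, alpha = 0.05, target_power = 0.80, m = 2,
                       rho = 0.5, epsilon = 1) {
  stopifnot(
    eta_sq > 0, eta_sq < 1, alpha > 0, alpha < 1,
    target_power > 0, target_power < 1, m >= 2, rho > 0, rho < 1,
    epsilon > 0, epsilon <= 1
  )
  structure(
    list(
      eta_sq = eta_sq, alpha = alpha, target_power = target_power,
      m = m, rho = rho, epsilon = epsilon
    ),
    class = "power_spec"
  )
}

#' Power of a within-subjects repeated-measures F test
#'
#' Noncentral-F power for a within-subjects factor with `m` levels measured
#' on `n` subjects: noncentrality `lambda = f2 * n * m / (1 - rho)`,
#' numerator df `(m - 1) * epsilon`, denominator df
#' `(n - 1) * (m - 1) * epsilon`; power is the probability that a noncentral
#' F variate exceeds the central critical value at `alpha`.
#'
#' @param spec A [power_spec()].
#' @param n Number of subjects (>= 2).
#' @return Achieved power.
#' @export
rm_power <- function(spec, n) {
  stopifnot(inherits(spec, "power_spec"), n >= 2)
  f2 <- effect_size_f2(spec$eta_sq)
  lambda <- f2 * n * spec$m / (1 - spec$rho)
  df1 <- (spec$m - 1) * spec$epsilon
  df2 <- (n - 1) * (spec$m - 1) * spec$epsilon
  if (df2 < 1) stop("denominator df below 1; increase n")
  crit <- stats::qf(1 - spec$alpha, df1, df2)
  structure(
    stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE),
    lambda = lambda, df1 = df1, df2 = df2, f_crit = crit
  )
}

#' Minimal sample size reaching the target power
#'
#' Smallest integer `n` with `rm_power(spec, n) >= target_power`.
#'
#' @param spec A [power_spec()].
#' @param n_max Search cap (an error is raised if the target power is not
#'   reached by `n_max`).
#' @return Integer sample size.
#' @export
min_n <- function(spec, n_max = 10000L) {
  stopifnot(inherits(spec, "power_spec"))
  for (n in 2:n_max) {
    df2 <- (n - 1) * (spec$m - 1) * spec$epsilon
    if (df2 < 1) next
    if (rm_power(spec, n) >= spec$target_power) {
      return(as.integer(n))
    }
  }
  stop(
    "target power ", spec$target_power, " not reached by n = ", n_max,
    " (power there: ", signif(rm_power(spec, n_max), 4), ")"
  )
}
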