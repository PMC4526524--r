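# Phenotype-level statistics: Welch t-test on sperm concentrations,
# group-mean fold-change, and the power t-test fixing the minimal detectable
# difference.

#' Welch two-sample t-test
#'
#' Accepts either raw value vectors or summary statistics (`list(mean =,
#' sd =, n =)`). Raw vectors are passed to [stats::t.test()]; summary
#' statistics use the Welch formula `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`
#' with Welch-Satterthwaite degrees of freedom directly. Two groups with zero
#' variance and equal means return p = 1 by convention.
#'
#' @param a,b numeric vectors, or lists with elements mean, sd, n (n >= 2).
#' @return list(t, df, p).
#' @export
welch_t_test <- function(a, b) {
  as_stats <- function(x) {
    if (is.numeric(x)) {
      if (length(x) < 2L) .stopf("each group needs n >= 2")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    } else {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      if (x$n < 2L) .stopf("each group needs n >= 2")
      x
    }
  }
  sa <- as_stats(a); sb <- as_stats(b)
  if (sa$sd == 0 && sb$sd == 0) {
    if (sa$mean == sb$mean) return(list(t = 0, df = sa$n + sb$n - 2, p = 1))
    return(list(t = sign(sa$mean - sb$mean) * Inf, df = sa$n + sb$n - 2, p = 0))
  }
  if (is.numeric(a) && is.numeric(b)) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  se2 <- sa$sd^2 / sa$n + sb$sd^2 / sb$n
  t <- (sa$mean - sb$mean) / sqrt(se2)
  df <- se2^2 / (sa$sd^4 / (sa$n^2 * (sa$n - 1)) + sb$sd^4 / (sb$n^2 * (sb$n - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Power specification for the two-sample t-test
#'
#' @param n per-group sample size (>= 2).
#' @param sd common standard deviation (millions spermatozoa per ml in the
#'   phenotype analysis).
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power 1 - beta (default 0.80).
#' @export
power_spec <- function(n, sd, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(n = n, sd = sd, alpha = alpha, power = power),
            class = "power_spec")
}

# Achieved power of the two-sided two-sample t-test (equal-variance
# convention, df = 2n - 2) at mean difference delta, via the noncentral t.
.t_test_power <- function(delta, n, sd, alpha) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp = ncp) + stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Minimal detectable mean difference of the two-sample t-test
#'
#' Solves the noncentral-t power equation (df = 2n - 2) by bisection for the
#' smallest delta at which the two-sided test at level `alpha` attains the
#' requested power. Delta scales linearly in `sd` and decreases in `n`,
#' `alpha`; the achieved power at the returned delta reproduces the request
#' to the solver tolerance (1e-6 relative).
#'
#' @param spec a [power_spec()] (or its fields given separately).
#' @return delta, in the units of `sd`.
#' @export
minimal_detectable_delta <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  f <- function(d) .t_test_power(d, spec$n, spec$sd, spec$alpha) - spec$power
  hi <- spec$sd
  while (f(hi) < 0 && hi < spec$sd * 1e6) hi <- hi * 2
  if (f(hi) < 0) .stopf("requested power unattainable at this n/sd/alpha")
  r <- stats::uniroot(f, c(0, hi), tol = 1e-6 * hi)
  r$root
}

#' Fold-change of group means
#'
#' Ratio treated / control, with a display value rounded to one decimal.
#'
#' @param treated_mean,control_mean group means (control must be positive).
#' @return list(ratio, display).
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (control_mean <= 0) .stopf("control mean must be positive")
  r <- treated_mean / control_mean
  list(ratio = r, display = round(r, 1))
}
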