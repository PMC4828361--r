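#' Descriptive group summary
#'
#' Mean and sample standard deviation (n - 1 denominator) with the group
#' size, the summary form in which grouped movement results are reported.
#'
#' @param samples numeric vector, length >= 2.
#' @return object of class `group_summary`: `mean`, `sd`, `n`.
#' @export
describe <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2)
    stop("describe() needs at least 2 finite samples")
  group_summary(mean(samples), stats::sd(samples), length(samples))
}

#' @rdname describe
#' @param mean,sd,n summary components (sd >= 0, n >= 2).
#' @export
group_summary <- function(mean, sd, n) {
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.3f +/- %.3f (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

# shared t machinery driven by (mean, sd, n) pairs
t_from_moments <- function(m1, s1, n1, m2, s2, n2, variant, alpha) {
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) stop("t statistic undefined: zero variance and equal means")
    t <- sign(m1 - m2) * Inf
    df <- n1 + n2 - 2
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {                              # welch
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, alpha = alpha,
                 significant = p < alpha, variant = variant,
                 mean_diff = m1 - m2), class = "t_test_result")
}

#' Independent two-sample t-test from raw samples
#'
#' Pooled-variance (default) or Welch two-sample t-test with a two-sided p
#' value from the t distribution.
#'
#' @param a,b numeric sample vectors (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @param alpha significance level for the `significant` flag.
#' @return object of class `t_test_result`: `t`, `df`, `p`, `alpha`,
#'   `significant`, `variant`, `mean_diff`.
#' @export
t_test_raw <- function(a, b, variant = c("pooled", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  ga <- describe(a); gb <- describe(b)
  t_from_moments(ga$mean, ga$sd, ga$n, gb$mean, gb$sd, gb$n, variant, alpha)
}

#' Independent two-sample t-test from summary statistics
#'
#' Same formulas as [t_test_raw()] driven by printed group summaries
#' (mean, SD, n), the only form in which grouped movement results are
#' usually published.
#'
#' @param g1,g2 `group_summary` objects (or lists with `mean`, `sd`, `n`).
#' @inheritParams t_test_raw
#' @return a `t_test_result`.
#' @export
t_test_from_summary <- function(g1, g2, variant = c("pooled", "welch"),
                                alpha = 0.05) {
  variant <- match.arg(variant)
  t_from_moments(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n, variant, alpha)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.3f, df = %.2f, p = %.4g%s\n",
              x$variant, x$t, x$df, x$p,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  invisible(x)
}
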