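#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Standard BCa interval for a scalar statistic of a sample: the bias
#' correction `z0` is the normal quantile of the proportion of bootstrap
#' statistics below the observed value, the acceleration `a` comes from the
#' jackknife skewness, and the interval endpoints are quantiles of the
#' bootstrap distribution at the adjusted levels. Deterministic given
#' `seed`. A degenerate bootstrap distribution (all resampled statistics
#' equal) collapses to a point interval with a warning.
#'
#' @param x Sample vector (resampling unit = element; at least 2 values).
#' @param statistic Function mapping a sample to a scalar.
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Length-2 numeric vector `c(lower, upper)`, with attributes `z0`
#'   and `acceleration`.
#' @examples
#' bca_interval(rnorm(50), mean, n_resamples = 999, seed = 7)
#' @export
bca_interval <- function(x, statistic, n_resamples = 5000L, level = 0.95,
                         seed = 1L) {
  n <- length(x)
  if (n < 2L) abort_input("BCa needs a sample of at least 2 values.")
  est <- statistic(x)
  if (!is.finite(est)) abort_input("The statistic is not finite on the sample.")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot_stats <- vapply(seq_len(n_resamples),
                       function(i) statistic(x[sample.int(n, n, replace = TRUE)]),
                       numeric(1))

  if (all(boot_stats == boot_stats[1])) {
    warning("Degenerate bootstrap distribution; returning a point interval.",
            call. = FALSE)
    out <- c(boot_stats[1], boot_stats[1])
    attr(out, "z0") <- 0
    attr(out, "acceleration") <- 0
    return(out)
  }

  prop <- (sum(boot_stats < est) + 0.5 * sum(boot_stats == est)) / n_resamples
  prop <- min(max(prop, 1 / (2 * n_resamples)), 1 - 1 / (2 * n_resamples))
  z0 <- qnorm(prop)

  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  jd <- mean(jack) - jack
  denom <- sum(jd^2)^1.5
  a <- if (denom == 0) 0 else sum(jd^3) / (6 * denom)

  alpha <- (1 - level) / 2
  z <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  out <- unname(quantile(boot_stats, probs = adj, type = 7))
  attr(out, "z0") <- z0
  attr(out, "acceleration") <- a
  out
}
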