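#' Akaike and Bayesian information criteria
#'
#' `AIC = -2*loglik + 2*k` and `BIC = -2*loglik + k*log(N)` with `k` free
#' parameters and `N` persons, so `BIC - AIC = k*(log(N) - 2)` exactly.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param n_parameters Number of free parameters `k` (>= 0).
#' @param n_persons Number of persons `N` (>= 1).
#' @return A one-row tibble with columns `AIC` and `BIC`.
#' @examples
#' information_criteria(-2791.778, 24, 499)
#' @export
information_criteria <- function(log_likelihood, n_parameters, n_persons) {
  if (n_parameters < 0) abort_input("`n_parameters` must be >= 0.")
  if (n_persons < 1) abort_input("`n_persons` must be >= 1.")
  tibble::tibble(AIC = -2 * log_likelihood + 2 * n_parameters,
                 BIC = -2 * log_likelihood + n_parameters * log(n_persons))
}

# is `nested` a restriction of `full`? (same items/data size; lag terms of
# the nested structure a subset of the full structure's)
is_nested_lags <- function(nested, full) {
  if (nested$n_items != full$n_items) return(FALSE)
  if (nested$n_coef >= full$n_coef + 1L) return(FALSE)
  a <- paste(nested$terms$item, nested$terms$lag)
  b <- paste(full$terms$item, full$terms$lag)
  all(a %in% b)
}

#' Likelihood-ratio test between nested fitted models
#'
#' `chi^2 = 2 * (loglik_full - loglik_nested)` referred to a chi-squared
#' distribution with `df` = difference in free parameters (no boundary
#' correction). The nested model's lag terms must be a subset of the full
#' model's and both fits must use the same data. A slightly negative
#' statistic (optimizer noise) is floored at 0 with a warning.
#'
#' @param fit_nested,fit_full `arirt_fit` objects for the restricted and the
#'   richer model.
#' @return A one-row tibble with `statistic`, `df`, `p.value`, per-model
#'   AIC/BIC, and `preferred_aic` / `preferred_bic` labels.
#' @export
lr_test <- function(fit_nested, fit_full) {
  if (!inherits(fit_nested, "arirt_fit") || !inherits(fit_full, "arirt_fit")) {
    abort_input("Both arguments must be arirt_fit objects.")
  }
  if (fit_nested$n_persons != fit_full$n_persons ||
      fit_nested$n_items != fit_full$n_items) {
    abort_input("Fits are not on the same data (person/item counts differ).")
  }
  if (!is_nested_lags(fit_nested$model$lags, fit_full$model$lags) ||
      fit_full$n_parameters <= fit_nested$n_parameters) {
    abort_input("Models are not nested: the first fit must restrict the second's lag structure.")
  }
  df <- fit_full$n_parameters - fit_nested$n_parameters
  stat <- 2 * (fit_full$log_likelihood - fit_nested$log_likelihood)
  if (stat < 0) {
    warning(sprintf("Negative LRT statistic (%.3g) floored at 0 (optimization noise).",
                    stat), call. = FALSE)
    stat <- 0
  }
  ic_n <- information_criteria(fit_nested$log_likelihood,
                               fit_nested$n_parameters, fit_nested$n_persons)
  ic_f <- information_criteria(fit_full$log_likelihood,
                               fit_full$n_parameters, fit_full$n_persons)
  tibble::tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    aic_nested = ic_n$AIC, aic_full = ic_f$AIC,
    bic_nested = ic_n$BIC, bic_full = ic_f$BIC,
    preferred_aic = ifelse(ic_f$AIC < ic_n$AIC, "full", "nested"),
    preferred_bic = ifelse(ic_f$BIC < ic_n$BIC, "full", "nested")
  )
}

#' @export
anova.arirt_fit <- function(object, ...) {
  fits <- list(object, ...)
  if (length(fits) != 2L) abort_input("Supply exactly two fits to compare.")
  lr_test(fits[[1]], fits[[2]])
}

#' Wald z test of a parameter estimate
#'
#' @param estimate Parameter estimate(s).
#' @param se Positive standard error(s).
#' @return A tibble with `estimate`, `std.error`, `statistic` (z =
#'   estimate/se), and two-sided normal `p.value`.
#' @examples
#' wald_test(0.572, 0.107)
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) abort_input("Standard errors must be positive.")
  z <- estimate / se
  tibble::tibble(estimate = estimate, std.error = se, statistic = z,
                 p.value = 2 * pnorm(-abs(z)))
}

#' Odds ratio of a logit-scale coefficient
#'
#' @param coefficient Finite coefficient(s) on the logit scale.
#' @return `exp(coefficient)`.
#' @examples
#' odds_ratio(0.667) # 1.948
#' @export
odds_ratio <- function(coefficient) {
  if (any(!is.finite(coefficient))) abort_input("Coefficient must be finite.")
  exp(coefficient)
}

#' Compare item parameters between two models fit to the same items
#'
#' For slopes and thresholds separately: the per-model means, the Pearson
#' correlation across models, and a paired t test (two-sided, df = p - 1) of
#' the difference `bank_b - bank_a`. Also reported: the correlation between
#' the two between-model difference vectors (slope differences vs threshold
#' differences) and the within-model slope-threshold correlations.
#'
#' @param bank_a,bank_b [item_bank()]s (or data frames with `slope` and
#'   `threshold`) for the same `p >= 3` items.
#' @return A list of class `item_parameter_comparison` with elements
#'   `by_parameter` (tibble: parameter, mean_a, mean_b, pearson_r,
#'   statistic, df, p.value), `difference_correlation`, and `within_model`
#'   (tibble of slope-threshold correlations per model).
#' @export
compare_item_parameters <- function(bank_a, bank_b) {
  if (nrow(bank_a) != nrow(bank_b)) abort_input("Banks differ in item count.")
  p <- nrow(bank_a)
  if (p < 3L) abort_input("At least 3 items are needed for correlations.")
  one <- function(name) {
    a <- bank_a[[name]]; b <- bank_b[[name]]
    tt <- stats::t.test(b, a, paired = TRUE)
    tibble::tibble(parameter = name, mean_a = mean(a), mean_b = mean(b),
                   pearson_r = cor(a, b),
                   statistic = unname(tt$statistic), df = p - 1L,
                   p.value = tt$p.value)
  }
  d_slope <- bank_b$slope - bank_a$slope
  d_thr <- bank_b$threshold - bank_a$threshold
  # constant difference vectors (e.g. identical banks) have no correlation
  diff_cor <- if (sd(d_slope) == 0 || sd(d_thr) == 0) NA_real_ else
    cor(d_slope, d_thr)
  structure(
    list(
      by_parameter = dplyr::bind_rows(one("slope"), one("threshold")),
      difference_correlation = diff_cor,
      within_model = tibble::tibble(
        model = c("a", "b"),
        slope_threshold_r = c(cor(bank_a$slope, bank_a$threshold),
                              cor(bank_b$slope, bank_b$threshold))
      )
    ),
    class = "item_parameter_comparison"
  )
}

#' @export
print.item_parameter_comparison <- function(x, ...) {
  cat("<item_parameter_comparison>\n")
  print(x$by_parameter)
  cat(sprintf("correlation of between-model differences: %.3f\n",
              x$difference_correlation))
  print(x$within_model)
  invisible(x)
}
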