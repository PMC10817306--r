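#' Monte-Carlo simulation study for a nested model comparison
#'
#' Repeatedly simulates data from a generating model, fits a nested pair of
#' lag structures to each replicate, and records the likelihood-ratio test
#' of the richer structure together with the Wald z test of its single
#' added lag coefficient (when the pair differs by one parameter). With the
#' generating model equal to the null this estimates the type-I error rate;
#' with a lag effect present it estimates power. Per-replicate seeds are
#' derived from `seed` once, up front, so the study is reproducible and
#' order-independent.
#'
#' @param generating_model An [arirt_model()] to simulate from.
#' @param n_persons Persons per replicate.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param null_lags,alt_lags [lag_structure()]s for the nested and the full
#'   model (defaults: plain 2PL vs fixed lag-1).
#' @param alpha Test level (default .05).
#' @param seed Master seed.
#' @param quadrature_points Quadrature points used for the replicate fits
#'   (default 21; adequate for test lengths around a dozen items).
#' @param standard_errors Compute SEs per replicate (needed for the Wald
#'   rate; default TRUE).
#' @return An object of class `arirt_study`: a list with `replicates` (a
#'   tibble with per-replicate log-likelihoods, LRT statistic and p-value,
#'   Wald p-value, convergence flags, and the alt-model estimates as a
#'   list-column), `alpha`, `n_persons`, and the generating model.
#'   Use [glance()] for aggregate rejection rates and [recovery_summary()]
#'   for parameter recovery.
#' @export
run_simulation_study <- function(generating_model, n_persons, n_replicates,
                                 null_lags = NULL, alt_lags = NULL,
                                 alpha = 0.05, seed = 1L,
                                 quadrature_points = 21L,
                                 standard_errors = TRUE) {
  if (n_replicates < 1L) abort_input("`n_replicates` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort_input("`alpha` must be in (0, 1).")
  p <- n_items_of(generating_model)
  if (is.null(null_lags)) null_lags <- lag_structure(p, 0L, "none")
  if (is.null(alt_lags)) alt_lags <- lag_structure(p, 1L, "fixed")
  if (!is_nested_lags(null_lags, alt_lags)) {
    abort_input("`null_lags` must be nested in `alt_lags`.")
  }

  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  single_added <- alt_lags$n_coef - null_lags$n_coef == 1L
  added_label <- if (single_added) setdiff(lag_coef_labels(alt_lags),
                                           lag_coef_labels(null_lags))[1]

  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    x <- simulate_responses(generating_model, n_persons, seed = child_seeds[r])
    f0 <- fit_arirt(x, lags = null_lags, quadrature_points = quadrature_points,
                    standard_errors = FALSE)
    # warm-start the richer model at the null optimum with zero lag effects:
    # cheap, deterministic, and guarantees loglik_alt >= loglik_null
    warm <- arirt_model(f0$model$bank, alt_lags, rep(0, alt_lags$n_coef))
    f1 <- fit_arirt(x, lags = alt_lags, quadrature_points = quadrature_points,
                    start = warm,
                    standard_errors = standard_errors && single_added)
    lrt <- suppressWarnings(lr_test(f0, f1))
    wald_p <- NA_real_
    if (single_added && standard_errors) {
      se <- f1$std_errors[added_label]
      if (is.finite(se) && se > 0) {
        wald_p <- wald_test(f1$estimates[added_label], se)$p.value
      }
    }
    tibble::tibble(
      replicate = r, seed = child_seeds[r],
      converged_null = f0$converged, converged_alt = f1$converged,
      loglik_null = f0$log_likelihood, loglik_alt = f1$log_likelihood,
      statistic = lrt$statistic, df = lrt$df, p.value = lrt$p.value,
      wald_p = wald_p,
      estimates_alt = list(f1$estimates)
    )
  })

  structure(
    list(replicates = reps, alpha = alpha, n_persons = n_persons,
         generating_model = generating_model,
         null_lags = null_lags, alt_lags = alt_lags, seed = seed),
    class = "arirt_study"
  )
}

#' @method tidy arirt_study
#' @export
tidy.arirt_study <- function(x, ...) x$replicates

#' Aggregate rejection rates of a simulation study
#'
#' Rates are computed over replicates in which both fits converged; the
#' denominator is reported alongside.
#'
#' @param x An `arirt_study`.
#' @param ... Unused.
#' @return A one-row tibble with `n_replicates`, `n_converged`,
#'   `lrt_rejection_rate`, `wald_rejection_rate` (NA when Wald tests were
#'   not available), and `alpha`.
#' @method glance arirt_study
#' @export
glance.arirt_study <- function(x, ...) {
  reps <- x$replicates
  ok <- reps$converged_null & reps$converged_alt
  wald_ok <- ok & !is.na(reps$wald_p)
  tibble::tibble(
    n_replicates = nrow(reps),
    n_converged = sum(ok),
    lrt_rejection_rate = mean(reps$p.value[ok] < x$alpha),
    wald_rejection_rate = if (any(wald_ok)) mean(reps$wald_p[wald_ok] < x$alpha) else NA_real_,
    alpha = x$alpha
  )
}

#' @export
print.arirt_study <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<arirt_study> %d replicates, N = %d, alpha = %.3f\n",
              g$n_replicates, x$n_persons, x$alpha))
  cat(sprintf("converged: %d/%d; LRT rejection rate %.4f; Wald rejection rate %s\n",
              g$n_converged, g$n_replicates, g$lrt_rejection_rate,
              ifelse(is.na(g$wald_rejection_rate), "NA",
                     sprintf("%.4f", g$wald_rejection_rate))))
  invisible(x)
}

#' Parameter-recovery summary of a simulation study
#'
#' Bias and RMSE of the alt-model estimates relative to the generating
#' parameters, over converged replicates, together with the Monte-Carlo
#' standard error of the bias (SD across replicates / sqrt of replicates).
#'
#' @param study An `arirt_study` whose alt structure matches the generating
#'   model's.
#' @param truth An [arirt_model()] with the generating parameter values
#'   (defaults to the study's generating model).
#' @return A tibble with columns `term`, `truth`, `mean_estimate`, `bias`,
#'   `rmse`, `mc_se`.
#' @export
recovery_summary <- function(study, truth = NULL) {
  if (is.null(truth)) truth <- study$generating_model
  reps <- study$replicates
  ok <- reps$converged_null & reps$converged_alt
  if (!any(ok)) abort_input("No converged replicates to summarize.")
  est <- do.call(rbind, reps$estimates_alt[ok])
  truth_vec <- c(truth$bank$slope, truth$bank$threshold, truth$lag_coefficients)
  if (length(truth_vec) != ncol(est)) {
    abort_input("`truth` has %d parameters but the fitted spec has %d.",
                length(truth_vec), ncol(est))
  }
  err <- sweep(est, 2, truth_vec)
  tibble::tibble(
    term = colnames(est),
    truth = truth_vec,
    mean_estimate = colMeans(est),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2)),
    mc_se = apply(est, 2, sd) / sqrt(sum(ok))
  )
}
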