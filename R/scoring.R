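#' EAP person-ability estimates with posterior standard deviations
#'
#' Expected a posteriori (EAP) scoring: for each person the posterior over
#' the latent grid is proportional to `prior weight x conditional likelihood
#' of the observed responses`, and the score is the posterior mean. The
#' posterior standard deviation is reported as the estimate's standard
#' error. For auto-regressive models each person's own observed responses
#' supply the lag terms. A person with no observed responses receives the
#' prior mean 0 and prior SD 1, with a warning.
#'
#' @param fit An `arirt_fit`, or an [arirt_model()].
#' @param data Persons x items responses; defaults to the data the model was
#'   fitted to.
#' @param grid A [latent_grid()]; defaults to the fit's grid.
#' @return A tibble with columns `person`, `theta`, `se`.
#' @export
eap_scores <- function(fit, data = NULL, grid = NULL) {
  if (inherits(fit, "arirt_fit")) {
    model <- fit$model
    if (is.null(data)) data <- fit$data
    if (is.null(grid)) grid <- fit$grid
  } else if (inherits(fit, "arirt_model")) {
    model <- fit
    if (is.null(data)) abort_input("`data` is required when scoring from a model.")
    if (is.null(grid)) grid <- latent_grid()
  } else {
    abort_input("`fit` must be an arirt_fit or arirt_model.")
  }
  X <- as_response_matrix(data)
  if (ncol(X) != n_items_of(model)) {
    abort_input("Data has %d items but the model has %d.",
                ncol(X), n_items_of(model))
  }
  Z <- lag_design(X, model$lags)
  n <- nrow(X)
  p <- ncol(X)
  Q <- length(grid$nodes)
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0
  base <- matrix(-model$bank$threshold, n, p, byrow = TRUE)
  for (cc in seq_along(Z)) base <- base + model$lag_coefficients[cc] * Z[[cc]]
  logdens <- matrix(0, n, Q)
  for (q in seq_len(Q)) {
    eta <- base + matrix(model$bank$slope * grid$nodes[q], n, p, byrow = TRUE)
    logdens[, q] <- rowSums((Xz * plogis(eta, log.p = TRUE) +
                             (1 - Xz) * plogis(-eta, log.p = TRUE)) * obs)
  }
  W <- exp(logdens) * matrix(grid$weights, n, Q, byrow = TRUE)
  norm <- rowSums(W)
  W <- W / norm
  theta_hat <- as.vector(W %*% grid$nodes)
  second <- as.vector(W %*% grid$nodes^2)
  post_sd <- sqrt(pmax(second - theta_hat^2, 0))

  empty <- rowSums(obs) == 0L
  if (any(empty)) {
    warning(sprintf("%d person(s) have no observed responses; returning the prior (0, 1).",
                    sum(empty)), call. = FALSE)
    theta_hat[empty] <- 0
    post_sd[empty] <- 1
  }
  tibble::tibble(person = seq_len(n), theta = theta_hat, se = post_sd)
}

#' Relative efficiency of person estimates between two models
#'
#' The per-person ratio of measurement variances, `(se_a / se_b)^2`. Values
#' above 1 mean model `b` claims smaller standard errors (more information)
#' than model `a` for that person.
#'
#' @param se_a,se_b Positive standard-error vectors of equal length.
#' @return A tibble with columns `person` and `ratio`; the mean ratio is
#'   `mean(result$ratio)`.
#' @export
relative_efficiency <- function(se_a, se_b) {
  if (length(se_a) != length(se_b)) abort_input("SE vectors differ in length.")
  if (any(se_a <= 0) || any(se_b <= 0)) abort_input("Standard errors must be positive.")
  tibble::tibble(person = seq_along(se_a), ratio = (se_a / se_b)^2)
}

#' Mean bias and RMSD between two person-score vectors
#'
#' @param theta_a,theta_b Equal-length score vectors (same persons).
#' @return A one-row tibble with `mean_bias = mean(a - b)` and
#'   `rmsd = sqrt(mean((a - b)^2))`.
#' @export
compare_scores <- function(theta_a, theta_b) {
  if (length(theta_a) != length(theta_b)) abort_input("Score vectors differ in length.")
  d <- theta_a - theta_b
  tibble::tibble(mean_bias = mean(d), rmsd = sqrt(mean(d^2)))
}

#' Between-model person-score comparison with BCa bootstrap intervals
#'
#' Computes the mean bias and RMSD of the EAP estimates and the mean
#' relative efficiency of their standard errors between two fitted models,
#' with bias-corrected and accelerated (BCa) bootstrap confidence intervals.
#' The resampling unit is the person.
#'
#' @param scores_a,scores_b Score tibbles from [eap_scores()] for the same
#'   persons (model `a` is conventionally the richer model, so ratios above
#'   1 mean model `b` is over-optimistic about precision).
#' @param n_resamples Bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with columns `statistic`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
score_comparison <- function(scores_a, scores_b, n_resamples = 5000L,
                             level = 0.95, seed = 1L) {
  if (nrow(scores_a) != nrow(scores_b)) abort_input("Score tables differ in rows.")
  d <- scores_a$theta - scores_b$theta
  re <- (scores_a$se / scores_b$se)^2
  stats <- list(
    mean_bias = list(x = d, f = mean),
    rmsd = list(x = d, f = function(v) sqrt(mean(v^2))),
    mean_relative_efficiency = list(x = re, f = mean)
  )
  purrr::imap_dfr(stats, function(s, name) {
    ci <- bca_interval(s$x, s$f, n_resamples = n_resamples, level = level,
                       seed = seed)
    tibble::tibble(statistic = name, estimate = s$f(s$x),
                   conf.low = ci[1], conf.high = ci[2])
  })
}
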