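# Full-information marginal maximum likelihood by quasi-Newton ascent with
# analytic gradients. The latent distribution is fixed at N(0,1) for
# identification; slopes are unconstrained in sign.

unpack_params <- function(par, p, n_coef) {
  list(slopes = par[seq_len(p)],
       thresholds = par[p + seq_len(p)],
       beta = if (n_coef) par[2L * p + seq_len(n_coef)] else numeric())
}

param_labels <- function(p, structure) {
  c(sprintf("slope[%d]", seq_len(p)),
    sprintf("threshold[%d]", seq_len(p)),
    lag_coef_labels(structure))
}

#' Fit an auto-regressive 2PL model by marginal maximum likelihood
#'
#' Maximizes the marginal log-likelihood (see [marginal_loglik()]) over item
#' slopes, thresholds, and lag coefficients by BFGS with analytic gradients,
#' restarting until the log-likelihood is stationary. Standard errors come
#' from the inverse observed information (central finite differences of the
#' analytic gradient).
#'
#' Start values are slopes 1, thresholds `-qlogis(pass rate)`, lag
#' coefficients 0 (close to the null of no sequential dependency), unless
#' `start` is supplied. Items with no observed 0 or no observed 1 trigger a
#' warning and their parameters are flagged unstable; non-convergence is
#' reported in the result, not raised as an error.
#'
#' @param data Persons x items binary responses (0/1/NA), matrix or data
#'   frame; column order is the administration order that defines lags.
#' @param lags A [lag_structure()] describing the sequential-dependency
#'   terms; defaults to none (plain 2PL). Alternatively give `order` and
#'   `lag_mode` and the structure is built for you.
#' @param order,lag_mode Convenience shortcut used when `lags` is `NULL`.
#' @param quadrature_points Gauss-Hermite points for the latent integral
#'   (default 61).
#' @param max_iterations BFGS iteration cap (default 10000).
#' @param reltol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param gradient_tolerance Scaled gradient-norm threshold for declaring
#'   convergence (default 1e-4, scaled by `max(1, |loglik|)`; steep items
#'   leave small score components in flat directions at a numerically
#'   converged optimum, so tighter thresholds mislabel true optima).
#' @param start Optional [arirt_model()] providing start values.
#' @param standard_errors Compute observed-information standard errors
#'   (default TRUE; skipping them saves time in large simulations).
#' @return An object of class `arirt_fit` with the fitted [arirt_model()]
#'   (`$model`), named estimates and standard errors, the log-likelihood,
#'   parameter/person counts, convergence diagnostics, the quadrature grid,
#'   and the response matrix used.
#' @seealso [tidy()], [glance()], [eap_scores()], [lr_test()]
#' @examples
#' bank <- item_bank(c(1.2, 1.5, 0.9, 1.1), c(-0.5, 0, 0.4, 0.8))
#' truth <- arirt_model(bank, lag_structure(4, 1, "fixed"), 0.6)
#' x <- simulate_responses(truth, n_persons = 300, seed = 1)
#' fit <- fit_arirt(x, order = 1, lag_mode = "fixed", quadrature_points = 21)
#' glance(fit)
#' @export
fit_arirt <- function(data, lags = NULL, order = 0L, lag_mode = NULL,
                      quadrature_points = 61L, max_iterations = 10000L,
                      reltol = 1e-8, gradient_tolerance = 1e-4,
                      start = NULL, standard_errors = TRUE) {
  X <- as_response_matrix(data)
  p <- ncol(X)
  if (is.null(lags)) {
    if (is.null(lag_mode)) lag_mode <- if (order > 0L) "fixed" else "none"
    lags <- lag_structure(p, order, lag_mode)
  }
  if (lags$n_items != p) {
    abort_input("Lag structure is for %d items but the data has %d.",
                lags$n_items, p)
  }
  if (reltol <= 0 || gradient_tolerance <= 0) {
    abort_input("Tolerances must be positive.")
  }

  pass <- colMeans(X, na.rm = TRUE)
  constant <- pass %in% c(0, 1) | is.nan(pass)
  if (any(constant)) {
    warning(sprintf("Item(s) %s have no observed variation; their parameters are unstable.",
                    paste(which(constant), collapse = ", ")), call. = FALSE)
  }

  grid <- latent_grid(quadrature_points)
  pat <- collapse_patterns(X)
  Z <- lag_design(pat$X, lags)

  if (is.null(start)) {
    pass_c <- pmin(pmax(pass, 1 / (2 * nrow(X))), 1 - 1 / (2 * nrow(X)))
    par <- c(rep(1, p), -qlogis(pass_c), rep(0, lags$n_coef))
  } else {
    if (!inherits(start, "arirt_model")) abort_input("`start` must be an arirt_model.")
    par <- c(start$bank$slope, start$bank$threshold, start$lag_coefficients)
  }

  # fn and gr share one evaluation, cached on the parameter vector
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    u <- unpack_params(par, p, lags$n_coef)
    val <- ll_core(u$slopes, u$thresholds, u$beta, pat$X, pat$counts, Z, grid,
                   gradient = TRUE)
    cache$par <- par
    cache$val <- val
    val
  }
  fn <- function(par) -evaluate(par)$loglik
  gr <- function(par) -evaluate(par)$gradient

  ll_start <- -fn(par)
  total_iter <- 0L
  opt_code <- 0L
  ll_prev <- -Inf
  for (pass_i in 1:6) {
    opt <- optim(par, fn, gr, method = "BFGS",
                 control = list(maxit = max_iterations, reltol = reltol))
    par <- opt$par
    total_iter <- total_iter + opt$counts[["function"]]
    opt_code <- opt$convergence
    ll_now <- -opt$value
    if (is.finite(ll_prev) && ll_now - ll_prev < 1e-7) break
    ll_prev <- ll_now
  }
  ll_hat <- -opt$value
  grad_hat <- -gr(par)
  converged <- opt_code == 0L &&
    max(abs(grad_hat)) <= gradient_tolerance * max(1, abs(ll_hat))

  u <- unpack_params(par, p, lags$n_coef)
  model <- arirt_model(item_bank(u$slopes, u$thresholds), lags, u$beta)
  labels <- param_labels(p, lags)
  estimates <- setNames(par, labels)

  se <- rep(NA_real_, length(par))
  if (standard_errors) {
    se <- observed_information_se(par, p, lags$n_coef, pat, Z, grid)
  }
  se <- setNames(se, labels)
  if (any(constant)) se[c(which(constant), p + which(constant))] <- NA_real_

  structure(
    list(model = model, estimates = estimates, std_errors = se,
         log_likelihood = ll_hat, log_likelihood_start = ll_start,
         n_parameters = length(par), n_persons = nrow(X), n_items = p,
         converged = converged, n_iterations = total_iter,
         max_abs_gradient = max(abs(grad_hat)),
         grid = grid, data = X,
         options = list(quadrature_points = quadrature_points,
                        max_iterations = max_iterations, reltol = reltol,
                        gradient_tolerance = gradient_tolerance)),
    class = "arirt_fit"
  )
}

# Observed information via central finite differences of the analytic
# gradient; non-positive-definite information yields NA SEs with a warning.
observed_information_se <- function(par, p, n_coef, pat, Z, grid) {
  k <- length(par)
  grad_at <- function(pp) {
    u <- unpack_params(pp, p, n_coef)
    ll_core(u$slopes, u$thresholds, u$beta, pat$X, pat$counts, Z, grid,
            gradient = TRUE)$gradient
  }
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- 1e-4 * max(1, abs(par[i]))
    e <- numeric(k); e[i] <- h
    H[, i] <- (grad_at(par + e) - grad_at(par - e)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  info <- -H
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch)) {
    warning("Observed information is not positive definite; standard errors set to NA.",
            call. = FALSE)
    return(rep(NA_real_, k))
  }
  sqrt(diag(chol2inv(ch)))
}

#' Standard errors from the observed information matrix
#'
#' Recomputes observed-information standard errors for a model at (or near)
#' a local maximum of the marginal likelihood, using central finite
#' differences of the analytic score.
#'
#' @param model An [arirt_model()] holding the parameter values.
#' @param data Persons x items responses the model was fitted to.
#' @param grid A [latent_grid()].
#' @return Named vector of standard errors (NA with a warning when the
#'   information matrix is not positive definite).
#' @export
standard_errors <- function(model, data, grid = latent_grid()) {
  X <- as_response_matrix(data)
  pat <- collapse_patterns(X)
  Z <- lag_design(pat$X, model$lags)
  p <- n_items_of(model)
  par <- c(model$bank$slope, model$bank$threshold, model$lag_coefficients)
  se <- observed_information_se(par, p, model$lags$n_coef, pat, Z, grid)
  setNames(se, param_labels(p, model$lags))
}
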