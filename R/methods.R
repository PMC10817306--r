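#' @export
print.arirt_fit <- function(x, ...) {
  cat(sprintf("<arirt_fit> %d persons x %d items, lag mode \"%s\" (order %d)\n",
              x$n_persons, x$n_items, x$model$lags$mode, x$model$lags$order))
  cat(sprintf("log-likelihood %.3f on %d parameters; %s after %d evaluations\n",
              x$log_likelihood, x$n_parameters,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  if (x$model$lags$n_coef > 0) {
    lab <- lag_coef_labels(x$model$lags)
    est <- x$model$lag_coefficients
    se <- x$std_errors[lab]
    cat("lag effects:\n")
    for (i in seq_along(lab)) {
      cat(sprintf("  %s = %.3f (SE %.3f, OR %.3f)\n",
                  lab[i], est[i], se[i], exp(est[i])))
    }
  }
  invisible(x)
}

#' Tidy the parameter estimates of a fitted model
#'
#' One row per free parameter with its estimate, standard error, Wald z
#' statistic, and two-sided normal p-value, in broom's column conventions.
#'
#' @param x An `arirt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `parameter` (slope / threshold /
#'   lag), `item` (NA for shared lag coefficients), `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy arirt_fit
#' @export
tidy.arirt_fit <- function(x, ...) {
  term <- names(x$estimates)
  parameter <- dplyr::case_when(
    grepl("^slope", term) ~ "slope",
    grepl("^threshold", term) ~ "threshold",
    TRUE ~ "lag"
  )
  item <- rep(NA_integer_, length(term))
  item[parameter == "slope"] <- seq_len(x$n_items)
  item[parameter == "threshold"] <- seq_len(x$n_items)
  jm <- regmatches(term, regexpr("j=\\d+", term))
  item[parameter == "lag"][grepl("j=", term[parameter == "lag"])] <-
    as.integer(sub("j=", "", jm))
  z <- unname(x$estimates / x$std_errors)
  tibble::tibble(
    term = term, parameter = parameter, item = item,
    estimate = unname(x$estimates), std.error = unname(x$std_errors),
    statistic = z, p.value = 2 * pnorm(-abs(z))
  )
}

#' One-row summary of a fitted model
#'
#' @param x An `arirt_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `BIC`, `df` (free parameters),
#'   `nobs` (persons), `converged`, and `n_iterations`.
#' @method glance arirt_fit
#' @export
glance.arirt_fit <- function(x, ...) {
  ic <- information_criteria(x$log_likelihood, x$n_parameters, x$n_persons)
  tibble::tibble(
    logLik = x$log_likelihood, AIC = ic$AIC, BIC = ic$BIC,
    df = x$n_parameters, nobs = x$n_persons,
    converged = x$converged, n_iterations = x$n_iterations
  )
}

#' @export
logLik.arirt_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_persons, class = "logLik")
}

#' @export
coef.arirt_fit <- function(object, ...) object$estimates

#' Serialize a fitted model to JSON
#'
#' Writes estimates, standard errors, the lag structure, log-likelihood,
#' counts, and the convergence block to a JSON file that [read_fit_json()]
#' can restore (as a model plus metadata, not a refittable object).
#'
#' @param fit An `arirt_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    estimates = as.list(fit$estimates),
    std_errors = as.list(fit$std_errors),
    lag_structure = list(n_items = fit$model$lags$n_items,
                         order = fit$model$lags$order,
                         mode = fit$model$lags$mode,
                         terms = fit$model$lags$terms),
    log_likelihood = fit$log_likelihood,
    n_parameters = fit$n_parameters,
    n_persons = fit$n_persons,
    n_items = fit$n_items,
    convergence = list(converged = fit$converged,
                       n_iterations = fit$n_iterations,
                       max_abs_gradient = fit$max_abs_gradient),
    options = fit$options
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized fit back as a model plus metadata
#'
#' @param path A JSON file written by [write_fit_json()].
#' @return A list with elements `model` (an [arirt_model()]), `std_errors`,
#'   `log_likelihood`, `n_parameters`, `n_persons`, and `convergence`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- obj$lag_structure
  lags <- if (ls$mode == "sparse") {
    lag_structure(ls$n_items, ls$order, ls$mode,
                  terms = tibble::as_tibble(ls$terms))
  } else {
    lag_structure(ls$n_items, ls$order, ls$mode)
  }
  est <- unlist(obj$estimates)
  p <- obj$n_items
  model <- arirt_model(item_bank(est[seq_len(p)], est[p + seq_len(p)]),
                       lags,
                       if (lags$n_coef) est[2 * p + seq_len(lags$n_coef)] else numeric())
  list(model = model, std_errors = unlist(obj$std_errors),
       log_likelihood = obj$log_likelihood, n_parameters = obj$n_parameters,
       n_persons = obj$n_persons, convergence = obj$convergence)
}
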