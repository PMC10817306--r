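# Shared toy models and an independent dense-grid integration oracle.

toy_bank <- function() item_bank(c(1.2, 0.8, 1.5), c(-0.3, 0.2, 0.5))

toy_ar1 <- function(beta = 0.5) {
  arirt_model(toy_bank(), lag_structure(3, 1, "fixed"), beta)
}

# Independent oracle: marginal log-likelihood by dense trapezoid integration
# of each person's conditional product against the N(0,1) density.
trapz_loglik <- function(model, X, n_grid = 10001, range = 8) {
  th <- seq(-range, range, length.out = n_grid)
  dens <- dnorm(th)
  bank <- model$bank
  terms <- model$lags$terms
  sum(apply(X, 1, function(x) {
    like <- rep(1, length(th))
    for (j in seq_len(ncol(X))) {
      if (is.na(x[j])) next
      eta <- -bank$threshold[j] + bank$slope[j] * th
      tj <- terms[terms$item == j, , drop = FALSE]
      for (r in seq_len(nrow(tj))) {
        xp <- x[j - tj$lag[r]]
        if (!is.na(xp)) eta <- eta + model$lag_coefficients[tj$coef[r]] * xp
      }
      pr <- plogis(eta)
      like <- like * (if (x[j] == 1) pr else 1 - pr)
    }
    log(pracma::trapz(th, like * dens))
  }))
}

# Oracle EAP: posterior mean and sd for one response vector on a dense grid.
trapz_eap <- function(model, x, n_grid = 10001, range = 8) {
  th <- seq(-range, range, length.out = n_grid)
  dens <- dnorm(th)
  bank <- model$bank
  terms <- model$lags$terms
  like <- rep(1, length(th))
  for (j in seq_along(x)) {
    if (is.na(x[j])) next
    eta <- -bank$threshold[j] + bank$slope[j] * th
    tj <- terms[terms$item == j, , drop = FALSE]
    for (r in seq_len(nrow(tj))) {
      xp <- x[j - tj$lag[r]]
      if (!is.na(xp)) eta <- eta + model$lag_coefficients[tj$coef[r]] * xp
    }
    pr <- plogis(eta)
    like <- like * (if (x[j] == 1) pr else 1 - pr)
  }
  post <- like * dens
  norm <- pracma::trapz(th, post)
  m <- pracma::trapz(th, th * post) / norm
  v <- pracma::trapz(th, th^2 * post) / norm - m^2
  c(mean = m, sd = sqrt(v))
}
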