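test_that("the latent grid matches the standard normal", {
  for (n in c(21, 41, 61)) {
    g <- latent_grid(n)
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
    expect_true(all(diff(g$nodes) > 0))
    expect_equal(sum(g$weights * g$nodes), 0, tolerance = 1e-10)
    expect_equal(sum(g$weights * g$nodes^2), 1, tolerance = 1e-10)
  }
  g <- latent_grid(61)
  expect_equal(sum(g$weights * plogis(g$nodes)), 0.5, tolerance = 1e-10)
  expect_error(latent_grid(2), ">= 3")
})

test_that("marginal log-likelihood matches closed forms and a dense-grid oracle", {
  # all-zero parameters: every response has probability 1/2, theta drops out
  m0 <- arirt_model(item_bank(rep(0, 3), rep(0, 3)))
  X0 <- matrix(c(0, 1, 1, 0, 1, 0), 2, 3)
  expect_equal(marginal_loglik(m0, X0), 6 * log(0.5), tolerance = 1e-12)

  # AR1 toy with missing responses vs independent trapezoid integration
  m <- toy_ar1(0.5)
  X <- as.matrix(simulate_responses(m, 50, seed = 9))
  X[cbind(c(1, 5, 7), c(1, 2, 3))] <- NA
  expect_equal(marginal_loglik(m, X, latent_grid(61)), trapz_loglik(m, X),
               tolerance = 1e-6)
})

test_that("pattern probabilities sum to one over all patterns", {
  set.seed(2)
  bank <- item_bank(runif(4, 0.7, 2), rnorm(4))
  lg <- lag_structure(4, 2, "variable")
  m <- arirt_model(bank, lg, rnorm(lg$n_coef, 0, 0.6))
  pats <- as.matrix(expand.grid(rep(list(0:1), 4)))
  total <- sum(apply(pats, 1, function(r) pattern_probability(m, r)))
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("fitting recovers toy generating parameters", {
  truth <- arirt_model(item_bank(c(1.3, 0.9, 1.6, 1.1), c(-0.6, 0, 0.5, 0.9)),
                       lag_structure(4, 1, "fixed"), 0.6)
  x <- simulate_responses(truth, 3000, seed = 42)
  fit <- fit_arirt(x, order = 1, quadrature_points = 31)
  expect_true(fit$converged)
  expect_equal(fit$n_parameters, 9L)
  expect_true(all(fit$std_errors > 0))
  # every parameter lies within 3 standard errors of its generating value
  truth_vec <- c(truth$bank$slope, truth$bank$threshold, truth$lag_coefficients)
  expect_true(all(abs(unname(fit$estimates) - truth_vec) <
                    3 * unname(fit$std_errors)))
})

test_that("the achieved optimum is stationary and quadrature-stable", {
  truth <- arirt_model(toy_bank(), lag_structure(3, 1, "fixed"), 0.5)
  x <- simulate_responses(truth, 400, seed = 8)
  fit <- fit_arirt(x, order = 1, quadrature_points = 41)
  # refitting from the fitted values barely moves the log-likelihood
  refit <- fit_arirt(x, order = 1, quadrature_points = 41, start = fit$model)
  expect_lt(abs(refit$log_likelihood - fit$log_likelihood), 1e-6)
  # log-likelihood improved over the start values
  expect_gte(fit$log_likelihood, fit$log_likelihood_start)

  # quadrature refinement at the optimum of a 12-item fit: 61 points are
  # enough that doubling the grid leaves the value unchanged to 1e-6
  set.seed(30)
  bank12 <- item_bank(runif(12, 0.8, 2.0), seq(-1.5, 1.5, length.out = 12))
  truth12 <- arirt_model(bank12, lag_structure(12, 1, "fixed"), 0.572)
  x12 <- simulate_responses(truth12, 499, seed = 21)
  f12 <- fit_arirt(x12, order = 1, quadrature_points = 61,
                   standard_errors = FALSE)
  ll61 <- marginal_loglik(f12$model, x12, latent_grid(61))
  ll121 <- marginal_loglik(f12$model, x12, latent_grid(121))
  expect_lt(abs(ll61 - ll121), 1e-6)
})

test_that("a 2PL fit and an AR1 model with zero lag are likelihood-equivalent", {
  truth <- spm_parameters("2pl")
  x <- simulate_responses(truth, 499, seed = 11)
  f0 <- fit_arirt(x, quadrature_points = 21, standard_errors = FALSE)
  frozen <- arirt_model(f0$model$bank, lag_structure(12, 1, "fixed"), 0)
  expect_equal(marginal_loglik(frozen, x, f0$grid), f0$log_likelihood,
               tolerance = 1e-6)
  # and the freely fitted AR1 can only improve on it
  f1 <- fit_arirt(x, order = 1, quadrature_points = 21,
                  standard_errors = FALSE)
  expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-8)
})

test_that("standard errors match the Bernoulli closed form and shrink with N", {
  # single item with zero slope: tau is a pure Bernoulli intercept, so
  # SE(tau) = sqrt(1 / (N * phat * (1 - phat)))
  set.seed(5)
  x1 <- matrix(rbinom(400, 1, 0.3), ncol = 1)
  phat <- mean(x1)
  m1 <- arirt_model(item_bank(0, -qlogis(phat)))
  se <- standard_errors(m1, x1, latent_grid(41))
  expect_equal(unname(se["threshold[1]"]),
               sqrt(1 / (400 * phat * (1 - phat))), tolerance = 1e-4)

  # SEs shrink with N, approaching the asymptotic 1/sqrt(N) rate
  truth <- arirt_model(item_bank(c(1.1, 0.9, 1.4), c(-0.5, 0.2, 0.6)))
  se_by_n <- sapply(c(250, 1000, 4000), function(n) {
    x <- simulate_responses(truth, n, seed = 77)
    mean(fit_arirt(x, quadrature_points = 21)$std_errors)
  })
  expect_true(all(diff(se_by_n) < 0))
  expect_equal(se_by_n[2] / se_by_n[3], 2, tolerance = 0.2)
})

test_that("exchangeable duplicate items receive equal standard errors", {
  truth <- arirt_model(item_bank(c(1.2, 1.2, 0.9), c(0.3, 0.3, -0.4)))
  x <- as.matrix(simulate_responses(truth, 300, seed = 13))
  x_sym <- rbind(x, x[, c(2, 1, 3)])  # items 1 and 2 exactly exchangeable
  fit <- fit_arirt(x_sym, quadrature_points = 31)
  expect_true(all(is.finite(fit$std_errors)))
  expect_equal(unname(fit$std_errors["slope[1]"]),
               unname(fit$std_errors["slope[2]"]), tolerance = 1e-4)
  expect_equal(unname(fit$std_errors["threshold[1]"]),
               unname(fit$std_errors["threshold[2]"]), tolerance = 1e-4)
})

test_that("degenerate inputs are reported, not hidden", {
  x <- cbind(rep(1, 40), rbinom(40, 1, 0.5))
  expect_warning(fit <- fit_arirt(x, quadrature_points = 11,
                                  standard_errors = FALSE),
                 "no observed variation")
  expect_true(is.na(fit$std_errors[["slope[1]"]]))
  expect_error(marginal_loglik(arirt_model(item_bank(Inf, 0)),
                               matrix(c(0, 1), 2, 1)), "finite")
})

test_that("quadrature error at the asymptotic optimum is negligible from 31 points", {
  # fit the EXACT pattern distribution of the steep reference AR1 model (the
  # N -> infinity limit): any deviation from truth is numerical, not sampling
  truth <- spm_parameters("ar1_2pl")
  truth_vec <- c(truth$bank$slope, truth$bank$threshold,
                 truth$lag_coefficients)
  pats <- as.matrix(expand.grid(rep(list(0:1), 12)))
  g_dense <- latent_grid(201)
  Z <- arirt:::lag_design(pats, truth$lags)
  base <- matrix(-truth$bank$threshold, nrow(pats), 12, byrow = TRUE) +
    truth$lag_coefficients[1] * Z[[1]]
  logdens <- sapply(g_dense$nodes, function(t) {
    eta <- base + matrix(truth$bank$slope * t, nrow(pats), 12, byrow = TRUE)
    rowSums(pats * plogis(eta, log.p = TRUE) +
            (1 - pats) * plogis(-eta, log.p = TRUE))
  })
  probs <- as.vector(exp(logdens) %*% g_dense$weights)
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  # spot-check the vectorized pattern probabilities against the public API
  for (i in c(1, 2000, 4096)) {
    expect_equal(probs[i], pattern_probability(truth, pats[i, ], g_dense),
                 tolerance = 1e-12)
  }
  asymptotic_fit <- function(Q) {
    grid <- latent_grid(Q)
    fn <- function(pp) {
      u <- arirt:::unpack_params(pp, 12, 1)
      -arirt:::ll_core(u$slopes, u$thresholds, u$beta, pats, probs, Z, grid)$loglik
    }
    gr <- function(pp) {
      u <- arirt:::unpack_params(pp, 12, 1)
      -arirt:::ll_core(u$slopes, u$thresholds, u$beta, pats, probs, Z, grid,
                       gradient = TRUE)$gradient
    }
    o <- optim(truth_vec, fn, gr, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-10))
    for (i in 1:3) o <- optim(o$par, fn, gr, method = "BFGS",
                              control = list(maxit = 10000, reltol = 1e-10))
    o$par
  }

  dev31 <- asymptotic_fit(31) - truth_vec
  expect_lt(max(abs(dev31)), 0.02)

  dev21 <- asymptotic_fit(21) - truth_vec
  # 21 points misstate the steepest slope by more than 0.1 ...
  expect_gt(abs(dev21[5]), 0.1)
  # ... but leave the lag coefficient essentially exact, so 21-point studies
  # of the lag test are sound
  expect_lt(abs(dev21[25]), 1e-3)
})
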