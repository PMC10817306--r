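#' Simulate binary responses from an auto-regressive 2PL model
#'
#' Draws each person's ability from N(0, 1) (unless `theta` is supplied) and
#' generates item responses sequentially in administration order: item `j`
#' is Bernoulli with the conditional probability given the responses already
#' generated for items `1..j-1`. Fully reproducible given `seed`.
#'
#' @param model An [arirt_model()] (the generating parameters).
#' @param n_persons Number of persons to simulate.
#' @param seed Optional integer seed.
#' @param theta Optional ability vector of length `n_persons` (overrides the
#'   N(0, 1) draw).
#' @return A tibble with columns `item_1 .. item_p`; the generating
#'   abilities are attached as attribute `"theta"`.
#' @examples
#' m <- arirt_model(item_bank(c(1, 1), c(0, 0)), lag_structure(2, 1, "fixed"), 1)
#' simulate_responses(m, 5, seed = 1)
#' @export
simulate_responses <- function(model, n_persons, seed = NULL, theta = NULL) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 1L) abort_input("`n_persons` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  p <- n_items_of(model)
  if (is.null(theta)) {
    theta <- rnorm(n_persons)
  } else if (length(theta) != n_persons) {
    abort_input("`theta` must have length `n_persons`.")
  }
  X <- matrix(0L, n_persons, p)
  terms <- model$lags$terms
  for (j in seq_len(p)) {
    eta <- -model$bank$threshold[j] + model$bank$slope[j] * theta
    tj <- terms[terms$item == j, , drop = FALSE]
    for (r in seq_len(nrow(tj))) {
      eta <- eta + model$lag_coefficients[tj$coef[r]] * X[, j - tj$lag[r]]
    }
    X[, j] <- rbinom(n_persons, 1L, plogis(eta))
  }
  out <- tibble::as_tibble(as.data.frame(X),
                           .name_repair = ~ sprintf("item_%d", seq_len(p)))
  attr(out, "theta") <- theta
  out
}

#' Model-implied marginal pass rate of each item
#'
#' Integrates the conditional response probabilities over the N(0, 1)
#' latent distribution and over the implied distribution of the lagged
#' responses, by forward recursion over joint histories at each quadrature
#' node. Useful as a closed-form check on [simulate_responses()].
#'
#' @param model An [arirt_model()].
#' @param grid A [latent_grid()].
#' @return Numeric vector of length `n_items` of marginal P(X_j = 1).
#' @export
implied_pass_rates <- function(model, grid = latent_grid()) {
  p <- n_items_of(model)
  k <- max(model$lags$order, 0L)
  rates <- numeric(p)
  for (q in seq_along(grid$nodes)) {
    theta <- grid$nodes[q]
    # joint distribution over the last min(j, k) responses, updated forward
    hist_states <- matrix(numeric(0), 1, 0)
    hist_prob <- 1
    for (j in seq_len(p)) {
      pr <- vapply(seq_along(hist_prob), function(s) {
        history <- rep(NA_real_, j - 1L)
        depth <- ncol(hist_states)
        if (depth > 0) history[(j - depth):(j - 1L)] <- hist_states[s, ]
        response_probability(model, j, theta, history)
      }, numeric(1))
      rates[j] <- rates[j] + grid$weights[q] * sum(hist_prob * pr)
      if (k > 0) {
        new_states <- rbind(cbind(hist_states, 0), cbind(hist_states, 1))
        new_prob <- c(hist_prob * (1 - pr), hist_prob * pr)
        if (ncol(new_states) > k) {
          key <- apply(new_states[, -1, drop = FALSE], 1, paste, collapse = "")
          agg <- rowsum(new_prob, key)
          states <- unique(new_states[, -1, drop = FALSE])
          skey <- apply(states, 1, paste, collapse = "")
          hist_states <- states[match(rownames(agg), skey), , drop = FALSE]
          hist_prob <- as.vector(agg)
        } else {
          hist_states <- new_states
          hist_prob <- new_prob
        }
      }
    }
  }
  rates
}
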