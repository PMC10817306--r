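#' Linear predictor of an item given ability and response history
#'
#' Evaluates `eta = -threshold[j] + slope[j] * theta + sum of lag terms`,
#' where each active lag term `(j, m)` contributes
#' `beta * history[j - m]`. Lag terms whose predictor response is missing
#' (`NA`) are dropped for that evaluation.
#'
#' @param model An [arirt_model()].
#' @param item Item index `j` (1-based, administration order).
#' @param theta Ability value(s); vectorized.
#' @param history Responses to items `1..j-1` (0/1/NA). May be omitted for
#'   items with no active lag terms.
#' @return Numeric vector of linear predictors, same length as `theta`.
#' @examples
#' m <- arirt_model(item_bank(c(1, 1), c(0, 0)),
#'                  lag_structure(2, 1, "fixed"), 0.572)
#' linear_predictor(m, 2, theta = 0, history = 1) # 0.572
#' @export
linear_predictor <- function(model, item, theta, history = NULL) {
  p <- n_items_of(model)
  item <- as.integer(item)
  if (length(item) != 1L || is.na(item) || item < 1L || item > p) {
    abort_input("`item` must be a single index in 1..%d.", p)
  }
  terms <- model$lags$terms[model$lags$terms$item == item, , drop = FALSE]
  if (is.null(history)) history <- rep(NA_real_, item - 1L)
  if (length(history) != item - 1L) {
    abort_input("`history` must have length %d for item %d.", item - 1L, item)
  }
  offset <- 0
  if (nrow(terms)) {
    x_prev <- history[item - terms$lag]
    keep <- !is.na(x_prev)
    if (any(keep)) {
      offset <- sum(model$lag_coefficients[terms$coef[keep]] * x_prev[keep])
    }
  }
  -model$bank$threshold[item] + model$bank$slope[item] * theta + offset
}

#' Conditional response probability of an item
#'
#' The logistic transform of [linear_predictor()]: the probability of a
#' correct response to item `j` given ability `theta` and the observed
#' responses to the preceding items.
#'
#' @inheritParams linear_predictor
#' @return Probabilities in (0, 1), same length as `theta`.
#' @examples
#' m <- arirt_model(item_bank(1, 0))
#' response_probability(m, 1, theta = 0) # 0.5
#' @export
response_probability <- function(model, item, theta, history = NULL) {
  plogis(linear_predictor(model, item, theta, history))
}

#' Conditional item information
#'
#' Fisher information of an item at ability `theta`,
#' `slope^2 * P * (1 - P)` with `P` the conditional response probability.
#' Because the lag terms do not interact with `theta`, conditioning on the
#' previous response(s) shifts the information curve horizontally but leaves
#' its shape (and its maximum `slope^2 / 4`) unchanged.
#'
#' @inheritParams linear_predictor
#' @return Non-negative information values, same length as `theta`.
#' @export
item_information <- function(model, item, theta, history = NULL) {
  p <- response_probability(model, item, theta, history)
  model$bank$slope[item]^2 * p * (1 - p)
}

#' Tabulate conditional response and information functions
#'
#' Builds the long-format table behind conditional item response function
#' (IRF) and item information plots: one row per item, ability point, and
#' prior-response condition. Items without active lag terms (always item 1)
#' have the single condition `"(none)"`; an item with `t` active lag terms
#' has `2^t` conditions, one per combination of lagged responses.
#'
#' @param model An [arirt_model()].
#' @param theta Ability grid; the default covers more than 99.99 percent of
#'   the standard-normal latent mass.
#' @return A tibble with columns `item`, `theta`, `condition` (label such as
#'   `"x[j-1]=1"`), `probability`, and `information`.
#' @export
irf_table <- function(model, theta = seq(-4, 4, length.out = 161)) {
  if (!is.numeric(theta) || !length(theta) || any(!is.finite(theta))) {
    abort_input("`theta` must be a non-empty finite numeric grid.")
  }
  p <- n_items_of(model)
  purrr::map_dfr(seq_len(p), function(j) {
    terms <- model$lags$terms[model$lags$terms$item == j, , drop = FALSE]
    n_t <- nrow(terms)
    conds <- if (n_t == 0L) {
      list(list(label = "(none)", history = NULL))
    } else {
      combos <- expand.grid(rep(list(c(0L, 1L)), n_t))
      purrr::map(seq_len(nrow(combos)), function(r) {
        vals <- as.integer(combos[r, ])
        history <- rep(NA_real_, j - 1L)
        history[j - terms$lag] <- vals
        list(label = paste(sprintf("x[j-%d]=%d", terms$lag, vals),
                           collapse = ", "),
             history = history)
      })
    }
    purrr::map_dfr(conds, function(cond) {
      pr <- response_probability(model, j, theta, cond$history)
      tibble::tibble(item = j, theta = theta, condition = cond$label,
                     probability = pr,
                     information = model$bank$slope[j]^2 * pr * (1 - pr))
    })
  })
}
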