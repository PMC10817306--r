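#' Construct an item bank in slope-intercept form
#'
#' An item bank holds the per-item slope (discrimination, logit per unit of
#' the latent trait) and threshold (a negated intercept on the logit scale)
#' of a 2PL-type model, in the slope-intercept parameterization
#' `P(X = 1 | theta) = plogis(-threshold + slope * theta)`.
#'
#' @param slope,threshold Numeric vectors of equal length, one entry per item
#'   in administration order. Alternatively `slope` may be a data frame with
#'   columns `slope` and `threshold` (and optionally `item`).
#' @return A tibble of class `item_bank` with columns `item`, `slope`,
#'   `threshold`.
#' @examples
#' item_bank(slope = c(1, 2), threshold = c(0, 1))
#' @export
item_bank <- function(slope, threshold = NULL) {
  if (is.data.frame(slope)) {
    df <- slope
    if (!all(c("slope", "threshold") %in% names(df))) {
      abort_input("Item bank data frame needs columns `slope` and `threshold`.")
    }
    slope <- df$slope
    threshold <- df$threshold
  }
  slope <- as.numeric(slope)
  threshold <- as.numeric(threshold)
  if (length(slope) != length(threshold)) {
    abort_input("`slope` and `threshold` must have the same length.")
  }
  if (length(slope) < 1L) abort_input("An item bank needs at least one item.")
  if (!all(is.finite(slope)) || !all(is.finite(threshold))) {
    abort_input("Item parameters must all be finite.")
  }
  out <- tibble::tibble(item = seq_along(slope), slope = slope,
                        threshold = threshold)
  class(out) <- c("item_bank", class(out))
  out
}

#' Convert between slope-intercept and discrimination-difficulty forms
#'
#' The slope-intercept form `plogis(-threshold + slope * theta)` and the
#' classical IRT form `plogis(discrimination * (theta - difficulty))`
#' describe the same item response function with `discrimination = slope`
#' and `difficulty = threshold / slope`. The conversion is exact and
#' round-trips, but requires non-zero slopes in the difficulty direction.
#'
#' @param bank An [item_bank()] (for `to = "difficulty"`) or a data frame
#'   with columns `discrimination` and `difficulty` (for `to = "intercept"`).
#' @param to Target parameterization: `"difficulty"` returns columns
#'   `item`, `discrimination`, `difficulty`; `"intercept"` returns an
#'   [item_bank()].
#' @return A tibble in the requested parameterization.
#' @examples
#' convert_parameters(item_bank(2, 1), to = "difficulty") # difficulty 0.5
#' @export
convert_parameters <- function(bank, to = c("difficulty", "intercept")) {
  to <- match.arg(to)
  if (to == "difficulty") {
    if (!all(c("slope", "threshold") %in% names(bank))) {
      abort_input("Expected columns `slope` and `threshold`.")
    }
    if (any(bank$slope == 0)) {
      abort_input("Cannot express item %d in difficulty form: slope is zero.",
                  which(bank$slope == 0)[1])
    }
    tibble::tibble(item = seq_len(nrow(bank)),
                   discrimination = bank$slope,
                   difficulty = bank$threshold / bank$slope)
  } else {
    if (!all(c("discrimination", "difficulty") %in% names(bank))) {
      abort_input("Expected columns `discrimination` and `difficulty`.")
    }
    item_bank(slope = bank$discrimination,
              threshold = bank$difficulty * bank$discrimination)
  }
}

#' Assemble an auto-regressive 2PL model
#'
#' Binds an [item_bank()], a [lag_structure()], and the lag coefficients into
#' a complete model whose linear predictor for item `j` is
#' `-threshold[j] + slope[j] * theta + sum of beta * x[j - m]` over the active
#' lag terms of item `j`. With an empty lag structure this is the plain 2PL.
#'
#' @param bank An [item_bank()].
#' @param lags A [lag_structure()]; defaults to no lags.
#' @param lag_coefficients Numeric vector, one entry per distinct coefficient
#'   of `lags` (logit scale). Positive values make success on a lagged item
#'   raise the success probability of the current item.
#' @return An object of class `arirt_model`.
#' @examples
#' bank <- item_bank(slope = c(1, 1.5, 2), threshold = c(-1, 0, 1))
#' arirt_model(bank, lag_structure(3, 1, "fixed"), lag_coefficients = 0.572)
#' @export
arirt_model <- function(bank, lags = NULL, lag_coefficients = numeric()) {
  if (!inherits(bank, "item_bank")) bank <- item_bank(bank)
  if (is.null(lags)) lags <- lag_structure(nrow(bank), 0L, "none")
  if (!inherits(lags, "lag_structure")) abort_input("`lags` must be a lag_structure.")
  if (lags$n_items != nrow(bank)) {
    abort_input("Lag structure is for %d items but the bank has %d.",
                lags$n_items, nrow(bank))
  }
  lag_coefficients <- as.numeric(lag_coefficients)
  if (length(lag_coefficients) != lags$n_coef) {
    abort_input("Expected %d lag coefficient(s), got %d.",
                lags$n_coef, length(lag_coefficients))
  }
  if (!all(is.finite(lag_coefficients)) && length(lag_coefficients)) {
    abort_input("Lag coefficients must be finite.")
  }
  structure(
    list(bank = bank, lags = lags, lag_coefficients = lag_coefficients),
    class = "arirt_model"
  )
}

#' @export
print.arirt_model <- function(x, ...) {
  cat(sprintf("<arirt_model> %d items, lag mode \"%s\" (order %d, %d coefficient(s))\n",
              nrow(x$bank), x$lags$mode, x$lags$order, x$lags$n_coef))
  if (x$lags$n_coef > 0) {
    cat("lag coefficients:",
        paste(sprintf("%s=%.3f", lag_coef_labels(x$lags), x$lag_coefficients),
              collapse = ", "), "\n")
  }
  print(tibble::as_tibble(x$bank), n = 5)
  invisible(x)
}

n_items_of <- function(model) nrow(model$bank)

# total number of free parameters of a model/spec
n_parameters_of <- function(model) 2L * nrow(model$bank) + model$lags$n_coef
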