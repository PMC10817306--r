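#' Define the auto-regressive lag structure of a model
#'
#' A lag structure records which preceding item responses enter the linear
#' predictor of each item, and how the corresponding coefficients are shared.
#' An active term `(j, m)` means that the response to item `j - m` predicts
#' the response to item `j`; terms only exist for `j - m >= 1`, so the first
#' item never receives a lag effect and no phantom predecessor is invented.
#'
#' Coefficient sharing depends on `mode`:
#' * `"none"`: no lag terms (the plain 2PL); `order` is forced to 0.
#' * `"fixed"`: one coefficient per lag order `m = 1..order`, shared by all
#'   items (the AR1-2PL has a single coefficient).
#' * `"variable"`: every active term has its own coefficient, giving
#'   `sum(pmin(seq_len(n_items) - 1, order))` free parameters.
#' * `"sparse"`: only the user-supplied `terms` are active, one coefficient
#'   each.
#'
#' @param n_items Number of items `p` in administration order.
#' @param order Maximum lag `k` (non-negative integer; at most `n_items - 1`).
#' @param mode Coefficient-sharing mode, see Details.
#' @param terms For `mode = "sparse"`, a data frame with columns `item` and
#'   `lag` listing the active terms.
#' @return An object of class `lag_structure`: a list with elements
#'   `n_items`, `order`, `mode`, `terms` (a tibble with columns `item`,
#'   `lag`, `coef` giving the coefficient index of each active term), and
#'   `n_coef` (the number of distinct coefficients).
#' @examples
#' lag_structure(12, 1, "fixed")     # the AR1-2PL structure: 1 coefficient
#' lag_structure(12, 1, "variable")  # item-specific lags: 11 coefficients
#' @export
lag_structure <- function(n_items, order = 0L,
                          mode = c("none", "fixed", "variable", "sparse"),
                          terms = NULL) {
  mode <- match.arg(mode)
  n_items <- as.integer(n_items)
  order <- as.integer(order)
  if (is.na(n_items) || n_items < 1L) abort_input("`n_items` must be a positive integer.")
  if (is.na(order) || order < 0L) abort_input("`order` must be a non-negative integer.")
  if (mode == "none") {
    order <- 0L
  } else if (mode != "sparse" && order == 0L) {
    abort_input("`order` must be >= 1 for mode \"%s\".", mode)
  }
  if (order > n_items - 1L) {
    abort_input("Lag order %d exceeds the %d preceding item(s) available.",
                order, n_items - 1L)
  }

  if (mode == "sparse") {
    if (is.null(terms) || !all(c("item", "lag") %in% names(terms))) {
      abort_input("Sparse mode requires `terms` with columns `item` and `lag`.")
    }
    terms <- tibble::tibble(item = as.integer(terms$item),
                            lag = as.integer(terms$lag))
    bad <- terms$lag < 1L | terms$item - terms$lag < 1L | terms$item > n_items
    if (any(bad)) {
      abort_input("Sparse term (item=%d, lag=%d) references a non-existent preceding item.",
                  terms$item[which(bad)[1]], terms$lag[which(bad)[1]])
    }
    if (anyDuplicated(terms)) abort_input("Duplicate sparse lag terms supplied.")
    terms <- dplyr::arrange(terms, .data$item, .data$lag)
    terms$coef <- seq_len(nrow(terms))
    order <- if (nrow(terms)) max(terms$lag) else 0L
  } else if (mode == "none") {
    terms <- tibble::tibble(item = integer(), lag = integer(), coef = integer())
  } else {
    terms <- tidyr::expand_grid(item = seq_len(n_items), lag = seq_len(order))
    terms <- dplyr::filter(terms, .data$item - .data$lag >= 1L)
    terms$coef <- if (mode == "fixed") terms$lag else seq_len(nrow(terms))
  }

  n_coef <- switch(mode,
    none = 0L,
    fixed = order,
    variable = nrow(terms),
    sparse = nrow(terms)
  )
  structure(
    list(n_items = n_items, order = order, mode = mode,
         terms = terms, n_coef = as.integer(n_coef)),
    class = "lag_structure"
  )
}

#' Count the free lag parameters of an auto-regressive structure
#'
#' For a test of `p` items and maximum lag `k`, a fixed-lag model estimates
#' `k` coefficients, while a variable-lag model estimates
#' `sum over j of min(j - 1, k)` (early items have fewer predecessors).
#' A sparse structure estimates one coefficient per supplied term.
#'
#' @inheritParams lag_structure
#' @return A non-negative integer count.
#' @examples
#' lag_param_count(12, 1, "fixed")    # 1
#' lag_param_count(12, 1, "variable") # 11
#' lag_param_count(12, 2, "variable") # 21
#' @export
lag_param_count <- function(n_items, order,
                            mode = c("none", "fixed", "variable", "sparse"),
                            terms = NULL) {
  mode <- match.arg(mode)
  if (n_items < 1L) abort_input("`n_items` must be >= 1.")
  if (order < 0L) abort_input("`order` must be >= 0.")
  switch(mode,
    none = 0L,
    fixed = as.integer(order),
    variable = as.integer(sum(pmin(seq_len(n_items) - 1L, order))),
    sparse = {
      if (is.null(terms)) abort_input("Sparse mode requires `terms`.")
      nrow(terms)
    }
  )
}

#' @export
print.lag_structure <- function(x, ...) {
  cat(sprintf("<lag_structure> %s, %d item(s), order %d, %d coefficient(s)\n",
              x$mode, x$n_items, x$order, x$n_coef))
  invisible(x)
}

# labels for lag coefficients, used in tidy() and serialization
lag_coef_labels <- function(structure) {
  if (structure$n_coef == 0L) return(character())
  if (structure$mode == "fixed") {
    sprintf("lag[m=%d]", seq_len(structure$order))
  } else {
    tm <- structure$terms[order(structure$terms$coef), ]
    tm <- tm[!duplicated(tm$coef), ]
    sprintf("lag[j=%d,m=%d]", tm$item, tm$lag)
  }
}
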