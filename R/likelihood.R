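# Marginal likelihood machinery.
#
# The AR likelihood conditions each item on the person's OBSERVED previous
# responses, so the per-person likelihood stays a product over items and the
# marginal likelihood is a single integral over theta. Identical response
# rows (including their missingness pattern) therefore have identical
# likelihood contributions and are collapsed to unique patterns with counts.

# Coerce a persons x items data frame / matrix to an integer 0/1/NA matrix.
as_response_matrix <- function(data) {
  if (is.data.frame(data)) {
    id_like <- vapply(data, function(col) is.character(col) || is.factor(col),
                      logical(1))
    data <- as.matrix(data[!id_like])
  }
  if (!is.matrix(data)) abort_input("`data` must be a matrix or data frame.")
  storage.mode(data) <- "double"
  ok <- is.na(data) | data == 0 | data == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort_input("Response at row %d, column %d is %s; expected 0, 1, or NA.",
                bad[1], bad[2], format(data[bad[1], bad[2]]))
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    abort_input("Response matrix must have at least one person and one item.")
  }
  unname(data)
}

# Collapse to unique response patterns; returns X (patterns x items),
# counts, and the pattern index of each original row.
collapse_patterns <- function(X) {
  key <- apply(X, 1L, function(r) paste(ifelse(is.na(r), "m", r), collapse = ""))
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  list(X = X[keep, , drop = FALSE],
       counts = as.vector(tabulate(idx, max(idx))),
       index = idx)
}

# Per-coefficient lag design matrices: Z[[c]][i, j] is the sum of lagged
# responses feeding coefficient c at item j for pattern i (missing lagged
# responses are dropped, i.e. contribute 0).
lag_design <- function(X, structure) {
  n <- nrow(X)
  p <- ncol(X)
  if (structure$n_coef == 0L) return(list())
  Z <- replicate(structure$n_coef, matrix(0, n, p), simplify = FALSE)
  for (r in seq_len(nrow(structure$terms))) {
    j <- structure$terms$item[r]
    m <- structure$terms$lag[r]
    cc <- structure$terms$coef[r]
    x_prev <- X[, j - m]
    x_prev[is.na(x_prev)] <- 0
    Z[[cc]][, j] <- Z[[cc]][, j] + x_prev
  }
  Z
}

# Core marginal log-likelihood (and analytic gradient) over collapsed
# patterns. Parameters arrive unpacked; `counts` weights each pattern.
# Vectorized over quadrature nodes: all n x p x Q evaluations live in one
# n x (p*Q) matrix (column block q holds items 1..p at node q), and per-node
# aggregation is a single matrix product with a 0/1 block-sum matrix.
ll_core <- function(slopes, thresholds, beta, X, counts, Z, grid,
                    gradient = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  Q <- length(grid$nodes)
  obs <- !is.na(X)
  Xz <- X
  Xz[!obs] <- 0

  base <- matrix(-thresholds, n, p, byrow = TRUE)
  for (cc in seq_along(Z)) base <- base + beta[cc] * Z[[cc]]

  jdx <- rep(seq_len(p), Q)                       # item of each column
  E <- base[, jdx, drop = FALSE] +
    matrix(rep(slopes, Q) * rep(grid$nodes, each = p), n, p * Q, byrow = TRUE)
  # log(1 - P) = -(max(eta,0) + log1p(exp(-|eta|))), numerically stable;
  # log P = eta + log(1 - P)
  lp0 <- -(pmax(E, 0) + log1p(exp(-abs(E))))
  S <- (lp0 + Xz[, jdx, drop = FALSE] * E) * obs[, jdx, drop = FALSE]
  block_q <- matrix(0, p * Q, Q)                  # sums items within a node
  block_q[cbind(seq_len(p * Q), rep(seq_len(Q), each = p))] <- 1
  logdens <- S %*% block_q

  M <- apply(logdens, 1L, max)
  li <- M + log(as.vector(exp(logdens - M) %*% grid$weights))
  total <- sum(counts * li)

  if (!gradient) return(list(loglik = total))

  A <- exp(logdens - li) * matrix(grid$weights, n, Q, byrow = TRUE)
  A <- A * counts                                  # posterior weight x count
  P <- exp(E + lp0)
  G <- A[, rep(seq_len(Q), each = p), drop = FALSE] *
    (Xz[, jdx, drop = FALSE] - P) * obs[, jdx, drop = FALSE]
  gcol <- colSums(G)
  dim(gcol) <- c(p, Q)
  g_thr <- -rowSums(gcol)
  g_slope <- as.vector(gcol %*% grid$nodes)
  g_beta <- numeric(length(beta))
  if (length(beta)) {
    block_j <- matrix(0, p * Q, p)                # sums nodes within an item
    block_j[cbind(seq_len(p * Q), jdx)] <- 1
    H <- G %*% block_j
    for (cc in seq_along(Z)) g_beta[cc] <- sum(H * Z[[cc]])
  }
  list(loglik = total,
       gradient = c(g_slope, g_thr, g_beta))
}

#' Marginal log-likelihood of a model for a response matrix
#'
#' Computes `sum over persons of log integral over theta of the product of
#' conditional item probabilities`, with the integral taken against the
#' standard-normal latent distribution on a Gauss-Hermite grid. For
#' auto-regressive models the conditioning history of each item is the
#' person's own observed responses, so the likelihood still factorizes over
#' items given theta. Missing responses contribute no factor; missing lagged
#' predictors drop their lag term.
#'
#' @param model An [arirt_model()].
#' @param data Persons x items responses (0/1/NA), matrix or data frame.
#' @param grid A [latent_grid()]; defaults to 61 points.
#' @return The scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(model, data, grid = latent_grid()) {
  X <- as_response_matrix(data)
  if (ncol(X) != n_items_of(model)) {
    abort_input("Data has %d items but the model has %d.",
                ncol(X), n_items_of(model))
  }
  if (!all(is.finite(model$bank$slope)) || !all(is.finite(model$bank$threshold)) ||
      (length(model$lag_coefficients) && !all(is.finite(model$lag_coefficients)))) {
    abort_input("Model parameters must be finite.")
  }
  pat <- collapse_patterns(X)
  Z <- lag_design(pat$X, model$lags)
  ll_core(model$bank$slope, model$bank$threshold, model$lag_coefficients,
          pat$X, pat$counts, Z, grid)$loglik
}

#' Marginal probability of a complete response pattern
#'
#' Integrates the conditional product of item probabilities for one complete
#' 0/1 pattern over the standard-normal latent distribution. Summing over
#' all `2^p` patterns yields 1, which serves as a total-probability check on
#' the likelihood machinery.
#'
#' @param model An [arirt_model()].
#' @param pattern A complete 0/1 response vector of length `n_items`.
#' @param grid A [latent_grid()].
#' @return The marginal pattern probability in (0, 1).
#' @export
pattern_probability <- function(model, pattern, grid = latent_grid()) {
  pattern <- as.numeric(pattern)
  if (length(pattern) != n_items_of(model) || any(!pattern %in% c(0, 1))) {
    abort_input("`pattern` must be a complete 0/1 vector of length %d.",
                n_items_of(model))
  }
  exp(marginal_loglik(model, matrix(pattern, nrow = 1), grid))
}
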