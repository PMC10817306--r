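#' Gauss-Hermite quadrature grid for a standard-normal latent trait
#'
#' Nodes and weights for integrating over the latent trait, obtained by
#' rescaling physicists' Gauss-Hermite quadrature to the N(0, 1) density
#' (`theta = sqrt(2) * x`, `w = w / sqrt(pi)`). The weights are renormalized
#' to sum to exactly 1. The latent distribution is fixed at N(0, 1) for
#' identification, so the grid carries no free parameters.
#'
#' @param n_points Number of quadrature points (at least 3; default 61).
#' @return An object of class `latent_grid`: a list with increasing `nodes`
#'   and positive `weights` summing to 1.
#' @examples
#' g <- latent_grid(21)
#' sum(g$weights * g$nodes^2) # ~1, the N(0,1) variance
#' @export
latent_grid <- function(n_points = 61L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L) {
    abort_input("`n_points` must be an integer >= 3.")
  }
  gh <- pracma::gaussHermite(n_points)
  nodes <- sqrt(2) * gh$x
  weights <- gh$w / sqrt(pi)
  weights <- weights / sum(weights)
  ord <- order(nodes)
  structure(list(nodes = nodes[ord], weights = weights[ord]),
            class = "latent_grid")
}

#' @export
print.latent_grid <- function(x, ...) {
  cat(sprintf("<latent_grid> %d Gauss-Hermite points on [%.3f, %.3f] for N(0,1)\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}
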