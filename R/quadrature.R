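#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int f(t) e^{-t^2} dt \approx \sum_q w_q f(t_q)},
#' computed by the Golub-Welsch algorithm (eigen-decomposition of the
#' symmetric Jacobi matrix of the Hermite recurrence).
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` (increasing) and `weights` (positive, summing
#'   to \eqn{\sqrt\pi}).
#' @examples
#' gh <- gauss_hermite(21)
#' sum(gh$weights) # sqrt(pi)
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  jac <- matrix(0, n, n)
  off <- sqrt(i / 2)
  jac[cbind(i, i + 1L)] <- off
  jac[cbind(i + 1L, i)] <- off
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = e$vectors[1L, ord]^2 * sqrt(pi))
}

#' Quadrature rule against a normal density
#'
#' Change of variables of [gauss_hermite()] so that
#' \eqn{\int f(x)\,N(x;\mu,\sigma^2)\,dx \approx \sum_q w_q f(x_q)} with the
#' weights normalized to sum to 1.
#'
#' @param n number of nodes; default 21 (the package-wide default for
#'   marginal maximum likelihood).
#' @param mean,sd mean and standard deviation of the normal density.
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @export
normal_quadrature <- function(n = 21, mean = 0, sd = 1) {
  stopifnot(sd > 0)
  gh <- gauss_hermite(n)
  list(nodes = mean + sd * sqrt(2) * gh$nodes,
       weights = gh$weights / sqrt(pi))
}
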