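#' Concrete parameter values for a latent structure model
#'
#' For trait models (LTA/MLTA) a parameter set holds the mixing proportions
#' `pi` (length K), the J x K threshold matrix `tau` (logit units), the
#' J x K loading matrix `lambda`, and the class factor means `mu` and
#' variances `sigma2` (length K). For LCA it holds `pi` and the J x K
#' matrix `prob` of class-conditional affirmative probabilities.
#'
#' Entries tied by the owning `model_spec` must be bit-equal; fixed entries
#' must hold their fixed value. [validate_parameter_set()] enforces this.
#'
#' @param spec the owning [model_spec].
#' @param pi mixing proportions, length K, summing to 1.
#' @param tau J x K threshold matrix (recycled from a length-J vector for
#'   class-invariant thresholds).
#' @param lambda J x K loading matrix (default all 1).
#' @param mu class factor means (default all 0).
#' @param sigma2 class factor variances (default all 1).
#' @param prob J x K class-conditional probabilities (LCA only).
#' @return a `parameter_set`.
#' @export
parameter_set <- function(spec, pi, tau = NULL, lambda = NULL, mu = NULL,
                          sigma2 = NULL, prob = NULL) {
  validate_model_spec(spec)
  K <- spec$K; J <- spec$J
  pi <- as.numeric(pi)
  if (spec$family == "LCA") {
    prob <- matrix(as.numeric(prob), J, K)
    ps <- structure(list(spec = spec, pi = pi, prob = prob),
                    class = "parameter_set")
    return(validate_parameter_set(ps))
  }
  tau <- matrix(as.numeric(tau), J, K)
  lambda <- if (is.null(lambda)) matrix(1, J, K) else
    matrix(as.numeric(lambda), J, K)
  mu <- if (is.null(mu)) numeric(K) else as.numeric(mu)
  sigma2 <- if (is.null(sigma2)) rep(1, K) else as.numeric(sigma2)
  ps <- structure(list(spec = spec, pi = pi, tau = tau, lambda = lambda,
                       mu = mu, sigma2 = sigma2),
                  class = "parameter_set")
  validate_parameter_set(ps)
}

#' Validate a parameter set against its specification
#'
#' Checks dimensions, simplex/positivity constraints and the exact
#' (bit-equal) satisfaction of every equality and fixing constraint of the
#' owning spec.
#'
#' @param ps a `parameter_set`.
#' @return `ps`, invisibly, or an error.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  spec <- ps$spec; K <- spec$K; J <- spec$J
  if (length(ps$pi) != K) stop("pi must have length K")
  if (any(ps$pi <= 0) || any(ps$pi >= 1 + 1e-12))
    stop("each mixing proportion must lie in (0, 1)")
  if (abs(sum(ps$pi) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (spec$family == "LCA") {
    if (!all(dim(ps$prob) == c(J, K))) stop("prob must be J x K")
    if (any(ps$prob < 0 | ps$prob > 1)) stop("prob entries must be in [0,1]")
    return(invisible(ps))
  }
  if (!all(dim(ps$tau) == c(J, K))) stop("tau must be J x K")
  if (!all(dim(ps$lambda) == c(J, K))) stop("lambda must be J x K")
  if (length(ps$mu) != K || length(ps$sigma2) != K)
    stop("mu and sigma2 must have length K")
  if (any(ps$sigma2 <= 0)) stop("class variances must be positive")
  shared <- setdiff(seq_len(J), spec$variant_items)
  for (j in shared)
    if (length(unique(ps$tau[j, ])) != 1L)
      stop("item ", j, " threshold must be identical across classes")
  if (spec$loadings == "fixed1" && !all(ps$lambda == 1))
    stop("loadings must be fixed at 1")
  if (spec$loadings == "shared" && length(unique(as.vector(ps$lambda))) != 1L)
    stop("shared-loading constraint violated")
  if (spec$means == "fixed0" && !all(ps$mu == 0))
    stop("means must be fixed at 0")
  if (spec$means == "free_class1" && K > 1L && ps$mu[K] != 0)
    stop("the anchor class (class K) must have mean fixed at 0")
  if (spec$variances == "fixed1" && !all(ps$sigma2 == 1))
    stop("variances must be fixed at 1")
  if (spec$variances == "free_class1" && K > 1L && ps$sigma2[K] != 1)
    stop("the anchor class (class K) must have variance fixed at 1")
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, digits = 3, ...) {
  spec <- x$spec
  cat(sprintf("<parameter_set> %s, K = %d, J = %d\n", spec$family, spec$K,
              spec$J))
  cat("  pi:", paste(round(x$pi, digits), collapse = " "), "\n")
  if (spec$family == "LCA") {
    cat("  class-conditional probabilities:\n")
    print(round(x$prob, digits))
  } else {
    cat("  thresholds (tau):\n"); print(round(x$tau, digits))
    cat("  mu:", paste(round(x$mu, digits), collapse = " "),
        "| sigma2:", paste(round(x$sigma2, digits), collapse = " "), "\n")
  }
  invisible(x)
}

# ---- free-parameter packing for the M-step optimizer ------------------------
# Structural parameters (everything except pi) are packed into a single
# numeric vector theta; variances enter as log(sigma2). The map records, for
# every (item, class) cell of tau/lambda and every class mean/variance, the
# theta position (0 = fixed; shared cells share a position).

make_parmap <- function(spec) {
  K <- spec$K; J <- spec$J
  pos <- 0L
  nxt <- function() { pos <<- pos + 1L; pos }
  tau_pos <- matrix(0L, J, K)
  for (j in seq_len(J)) {
    if (j %in% spec$variant_items && K > 1L) {
      for (c in seq_len(K)) tau_pos[j, c] <- nxt()
    } else {
      p <- nxt(); tau_pos[j, ] <- p
    }
  }
  lambda_pos <- matrix(0L, J, K)
  if (spec$loadings == "shared") lambda_pos[, ] <- nxt()
  if (spec$loadings == "free")
    for (c in seq_len(K)) for (j in seq_len(J)) lambda_pos[j, c] <- nxt()
  mu_pos <- integer(K)
  if (spec$means == "free_class1")
    for (c in seq_len(K - 1L)) mu_pos[c] <- nxt()
  lsig_pos <- integer(K)
  if (spec$variances == "free_class1")
    for (c in seq_len(K - 1L)) lsig_pos[c] <- nxt()
  if (spec$variances == "free_per_class")
    for (c in seq_len(K)) lsig_pos[c] <- nxt()
  list(tau = tau_pos, lambda = lambda_pos, mu = mu_pos, lsig = lsig_pos,
       n_theta = pos)
}

pack_theta <- function(ps, map = make_parmap(ps$spec)) {
  theta <- numeric(map$n_theta)
  theta[map$tau[map$tau > 0L]] <- ps$tau[map$tau > 0L]
  theta[map$lambda[map$lambda > 0L]] <- ps$lambda[map$lambda > 0L]
  if (any(map$mu > 0L)) theta[map$mu[map$mu > 0L]] <- ps$mu[map$mu > 0L]
  if (any(map$lsig > 0L))
    theta[map$lsig[map$lsig > 0L]] <- log(ps$sigma2[map$lsig > 0L])
  theta
}

unpack_theta <- function(theta, spec, pi, map = make_parmap(spec)) {
  K <- spec$K; J <- spec$J
  tau <- matrix(theta[map$tau], J, K)
  lambda <- matrix(1, J, K)
  lambda[map$lambda > 0L] <- theta[map$lambda[map$lambda > 0L]]
  mu <- numeric(K)
  mu[map$mu > 0L] <- theta[map$mu[map$mu > 0L]]
  sigma2 <- rep(1, K)
  sigma2[map$lsig > 0L] <- exp(theta[map$lsig[map$lsig > 0L]])
  structure(list(spec = spec, pi = pi, tau = tau, lambda = lambda,
                 mu = mu, sigma2 = sigma2), class = "parameter_set")
}
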