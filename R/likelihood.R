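#' Item operation characteristic (2PL/Rasch response) function
#'
#' Probability of an affirmative answer given the latent trait value F:
#' \eqn{P(y = 1 | F) = 1 / (1 + \exp(\tau - \lambda F))}. The threshold
#' \eqn{\tau} is the trait value at which the probability is 0.5 when
#' \eqn{\lambda = 1}; \eqn{\lambda} is the discrimination.
#'
#' @param f latent trait value(s).
#' @param tau threshold (logit units).
#' @param lambda loading/discrimination (default 1).
#' @return probability, vectorized over inputs.
#' @export
item_response_prob <- function(f, tau, lambda = 1) {
  stopifnot(all(is.finite(f)), all(is.finite(tau)), all(is.finite(lambda)))
  stats::plogis(lambda * f - tau)
}

# ---- response matrix utilities ---------------------------------------------

as_response_matrix <- function(data) {
  if (is.list(data) && !is.null(data$responses)) data <- data$responses
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) stop("data must be a matrix or data.frame")
  storage.mode(data) <- "integer"
  if (anyNA(data)) stop("response matrix must not contain missing values")
  if (!all(data %in% c(0L, 1L))) stop("responses must be coded 0/1")
  if (nrow(data) < 1L) stop("response matrix must have at least one row")
  if (is.null(colnames(data)))
    colnames(data) <- paste0("item", seq_len(ncol(data)))
  data
}

# encode each row as 1 + sum_j y_j 2^(j-1)
pattern_id <- function(y) as.integer(y %*% 2^(seq_len(ncol(y)) - 1)) + 1L

# collapse to unique patterns with multiplicities
compress_patterns <- function(y) {
  id <- pattern_id(y)
  tab <- table(id)
  uid <- as.integer(names(tab))
  first <- match(uid, id)
  list(y = y[first, , drop = FALSE], counts = as.numeric(tab),
       id = uid, row_index = match(id, uid))
}

all_patterns <- function(J) {
  stopifnot(J <= 20)
  m <- as.matrix(expand.grid(rep(list(0:1), J), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- list(NULL, paste0("item", seq_len(J)))
  storage.mode(m) <- "integer"
  m[order(pattern_id(m)), , drop = FALSE]
}

# ---- class-conditional pattern probabilities -------------------------------

# item log-probabilities at quadrature nodes for one class: J x Q matrices
class_item_logprobs <- function(ps, class, rule) {
  eta <- outer(ps$lambda[, class], rule$nodes) - ps$tau[, class]
  list(lp = stats::plogis(eta, log.p = TRUE),
       l1p = stats::plogis(-eta, log.p = TRUE),
       p = stats::plogis(eta))
}

# probability of each pattern row under one class (vector over patterns)
class_pattern_prob_vec <- function(y, ps, class, nq = 21) {
  spec <- ps$spec
  if (spec$family == "LCA") {
    p <- pmin(pmax(ps$prob[, class], 1e-12), 1 - 1e-12)
    return(as.numeric(exp(y %*% log(p) + (1 - y) %*% log1p(-p))))
  }
  if (ps$sigma2[class] < 1e-6)
    stop("class variance below floor; degenerate trait distribution")
  rule <- normal_quadrature(nq, ps$mu[class], sqrt(ps$sigma2[class]))
  il <- class_item_logprobs(ps, class, rule)
  a <- y %*% il$lp + (1 - y) %*% il$l1p      # patterns x nodes
  as.numeric(exp(a) %*% rule$weights)
}

#' Class-conditional probability of a response pattern
#'
#' Marginal probability of the 0/1 pattern `y` under latent class `class`,
#' integrating the item response functions over that class's normal trait
#' distribution with Gauss-Hermite quadrature (exact product of Bernoullis
#' for LCA).
#'
#' @param y 0/1 vector of length J (or a matrix of patterns, one per row).
#' @param class class index.
#' @param params a [parameter_set].
#' @param nq number of quadrature nodes (default 21).
#' @return probability (vector if `y` is a matrix).
#' @export
class_conditional_pattern_prob <- function(y, class, params, nq = 21) {
  validate_parameter_set(params)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  class_pattern_prob_vec(y, params, class, nq)
}

# patterns x K matrix of class-conditional probabilities
class_prob_matrix <- function(y, ps, nq = 21) {
  m <- vapply(seq_len(ps$spec$K),
              function(c) class_pattern_prob_vec(y, ps, c, nq),
              numeric(nrow(y)))
  matrix(m, nrow(y), ps$spec$K)
}

#' Mixture observed-data log-likelihood
#'
#' \eqn{\sum_i \log \sum_c \pi_c P(y_i | c)}, computed once per unique
#' response pattern with multiplicities.
#'
#' @param data 0/1 response matrix (n x J) or the list returned by
#'   [load_responses()].
#' @param params a [parameter_set].
#' @param nq quadrature nodes.
#' @return log-likelihood (scalar).
#' @export
mixture_loglik <- function(data, params, nq = 21) {
  y <- as_response_matrix(data)
  validate_parameter_set(params)
  cp <- compress_patterns(y)
  pm <- class_prob_matrix(cp$y, params, nq)
  mix <- as.numeric(pm %*% params$pi)
  if (any(mix <= 0)) {
    bad <- which(mix <= 0)[1L]
    stop("pattern ", paste(cp$y[bad, ], collapse = ""),
         " has zero probability under all classes")
  }
  sum(cp$counts * log(mix))
}

#' Standardized factor loadings under the logit link
#'
#' For item j in class c with loading \eqn{\lambda_{jc}} and class variance
#' \eqn{\sigma^2_c}, the standardized loading is
#' \eqn{\lambda\sigma / \sqrt{\lambda^2\sigma^2 + \pi^2/3}}, the correlation
#' between the latent trait and the underlying logistic response propensity.
#'
#' @param params a trait-model [parameter_set].
#' @return J x K matrix.
#' @export
standardize_loadings <- function(params) {
  validate_parameter_set(params)
  if (params$spec$family == "LCA")
    stop("standardized loadings are defined for trait models only")
  ls <- sweep(params$lambda, 2, sqrt(params$sigma2), `*`)
  ls / sqrt(ls^2 + pi^2 / 3)
}
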