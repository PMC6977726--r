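#' Posterior class probabilities and most-likely-class assignment
#'
#' Bayes posterior \eqn{p_{ic} = \pi_c P(y_i|c) / \sum_{c'} \pi_{c'}
#' P(y_i|c')}, computed once per unique response pattern. Ties in the MAP
#' assignment are broken toward the lower class index (the food-security
#' side for canonical two-class fits), a deliberately conservative rule.
#'
#' @param data 0/1 response matrix.
#' @param fit an `mlta_fit`, or any list with elements `spec` and `params`
#'   (e.g. a truth stub built from [table2_parameters()] via [as_fit()]).
#' @param nq quadrature nodes.
#' @return list of class `mlta_posterior`: `prob` (n x K, rows sum to 1),
#'   `map` (integer MAP class per respondent), `labels` (class labels).
#' @export
posterior_probabilities <- function(data, fit, nq = NULL) {
  y <- as_response_matrix(data)
  ps <- fit$params
  nq <- nq %||% fit$nq %||% 21
  cp <- compress_patterns(y)
  pm <- class_prob_matrix(cp$y, ps, nq)
  num <- sweep(pm, 2, ps$pi, `*`)
  tot <- rowSums(num)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0)[1L]
    stop("pattern ", paste(cp$y[bad, ], collapse = ""),
         " has zero probability under every class")
  }
  post_u <- num / tot
  map_u <- max.col(post_u, ties.method = "first")
  prob <- post_u[cp$row_index, , drop = FALSE]
  rownames(prob) <- rownames(y)
  structure(list(prob = prob, map = map_u[cp$row_index],
                 labels = fit$class_labels %||%
                   paste0("class", seq_len(ncol(prob)))),
            class = "mlta_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a fit-like object from known parameters
#'
#' Wraps a [model_spec] and [parameter_set] (e.g. the printed generating
#' estimates) so that classification functions expecting a fitted model can
#' be used with fixed parameter values.
#'
#' @param spec a `model_spec`.
#' @param params a `parameter_set`.
#' @param nq quadrature nodes.
#' @return an `mlta_fit`-like object (no log-likelihood).
#' @export
as_fit <- function(spec, params, nq = 21) {
  validate_parameter_set(params)
  fit <- structure(list(spec = spec, params = params, loglik = NA_real_,
                        n = NA_integer_,
                        p_free = count_free_parameters(spec),
                        converged = NA, nq = nq),
                   class = "mlta_fit")
  canonicalize_fit(fit)
}

resolve_class <- function(class, labels, K) {
  if (is.character(class)) {
    idx <- match(class, labels)
    if (is.na(idx)) stop("unknown class label: ", class)
    return(idx)
  }
  stopifnot(class >= 1, class <= K)
  as.integer(class)
}

#' Posterior-probability-based prevalence of a class
#'
#' Mean posterior probability of the class over respondents -- not the
#' share of MAP assignments (the two coincide only for a perfectly
#' separated classification).
#'
#' @param post an `mlta_posterior`.
#' @param class class index or label (e.g. `"food_insecurity"`).
#' @return proportion in [0, 1].
#' @export
prevalence_posterior <- function(post, class) {
  stopifnot(inherits(post, "mlta_posterior"))
  c_idx <- resolve_class(class, post$labels, ncol(post$prob))
  mean(post$prob[, c_idx])
}

#' Share of respondents MAP-assigned to a class
#' @inheritParams prevalence_posterior
#' @return proportion in [0, 1].
#' @export
prevalence_map <- function(post, class) {
  stopifnot(inherits(post, "mlta_posterior"))
  c_idx <- resolve_class(class, post$labels, ncol(post$prob))
  mean(post$map == c_idx)
}

#' Average posterior probability within each MAP class
#'
#' For each class c, the mean of \eqn{p_{ic}} over respondents whose MAP
#' class is c -- the diagonal of the average-latent-class-probability
#' matrix commonly reported for mixture models. A class with no MAP
#' members yields NA and is flagged in the `empty` attribute.
#'
#' @param post an `mlta_posterior`.
#' @return named numeric vector (one entry per class).
#' @export
average_class_probabilities <- function(post) {
  stopifnot(inherits(post, "mlta_posterior"))
  k <- ncol(post$prob)
  if (k < 2L) stop("average class probabilities require K >= 2")
  out <- vapply(seq_len(k), function(c) {
    idx <- post$map == c
    if (!any(idx)) return(NA_real_)
    mean(post$prob[idx, c])
  }, numeric(1))
  names(out) <- post$labels
  structure(out, empty = unname(which(is.na(out))))
}

#' Enumerate the model-implied distribution over all response patterns
#'
#' Computes, for every one of the 2^J patterns, the model-implied mixture
#' probability, the per-class posterior probabilities and the MAP class.
#' Per-item model-implied marginals follow by summation.
#'
#' @param fit an `mlta_fit` (or [as_fit()] stub).
#' @param nq quadrature nodes.
#' @return list: `patterns` (2^J x J 0/1 matrix), `prob` (mixture
#'   probabilities, summing to 1), `posterior` (2^J x K), `map`,
#'   `item_marginals` (length J), `labels`.
#' @export
enumerate_pattern_probs <- function(fit, nq = NULL) {
  ps <- fit$params
  nq <- nq %||% fit$nq %||% 21
  pats <- all_patterns(ps$spec$J)
  pm <- class_prob_matrix(pats, ps, nq)
  prob <- as.numeric(pm %*% ps$pi)
  num <- sweep(pm, 2, ps$pi, `*`)
  posterior <- num / rowSums(num)
  map <- max.col(posterior, ties.method = "first")
  list(patterns = pats, prob = prob, posterior = posterior, map = map,
       item_marginals = as.numeric(crossprod(pats, prob)),
       labels = fit$class_labels %||% paste0("class", seq_len(ncol(pm))))
}

#' Model-implied average posterior probability per MAP class
#'
#' Population version of [average_class_probabilities()]: over all 2^J
#' patterns, restricted to patterns MAP-assigned to each class, the
#' pattern-probability-weighted mean of that class's posterior.
#'
#' @param fit an `mlta_fit` (or [as_fit()] stub).
#' @param nq quadrature nodes.
#' @return named numeric vector, one entry per class.
#' @export
model_average_class_probabilities <- function(fit, nq = NULL) {
  enum <- enumerate_pattern_probs(fit, nq)
  k <- ncol(enum$posterior)
  out <- vapply(seq_len(k), function(c) {
    idx <- enum$map == c
    if (!any(idx)) return(NA_real_)
    sum(enum$prob[idx] * enum$posterior[idx, c]) / sum(enum$prob[idx])
  }, numeric(1))
  names(out) <- enum$labels
  out
}

#' Response-pattern goodness of fit
#'
#' Observed versus model-expected counts for every response pattern, with
#' per-pattern chi-square contributions (obs - exp)^2 / exp, sorted by
#' observed count descending. Patterns never observed appear with observed
#' count 0. No omnibus p-value is attached: with 2^J sparse cells the
#' chi-square asymptotics are unreliable, so only the contributions are
#' reported.
#'
#' @param data 0/1 response matrix.
#' @param fit an `mlta_fit`.
#' @param nq quadrature nodes.
#' @return data.frame: `pattern`, `observed`, `expected`, `chisq`.
#' @export
pattern_fit <- function(data, fit, nq = NULL) {
  y <- as_response_matrix(data)
  enum <- enumerate_pattern_probs(fit, nq)
  n <- nrow(y)
  obs <- tabulate(pattern_id(y), nbins = nrow(enum$patterns))
  expected <- n * enum$prob
  chisq <- (obs - expected)^2 / expected
  out <- data.frame(
    pattern = apply(enum$patterns, 1, paste, collapse = ""),
    observed = obs, expected = expected, chisq = chisq,
    stringsAsFactors = FALSE)
  out[order(-out$observed, out$pattern), ]
}
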