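#' JSON serialization of specs, parameter sets and fits
#'
#' `spec_to_list`/`params_to_list` produce plain lists suitable for
#' `jsonlite::write_json`; `spec_from_list`/`params_from_list` invert
#' them. [write_fit_json()]/[read_fit_json()] round-trip a fitted model
#' (spec, estimates, log-likelihood and indices).
#'
#' @name serialization
NULL

spec_to_list <- function(spec) {
  list(family = spec$family, K = spec$K, J = spec$J,
       variant_items = spec$variant_items, loadings = spec$loadings,
       means = spec$means, variances = spec$variances)
}

spec_from_list <- function(x) {
  new_model_spec(x$family, x$K, x$J,
                 variant_items = unlist(x$variant_items) %||% integer(),
                 loadings = x$loadings %||% "fixed1",
                 means = x$means %||% "fixed0",
                 variances = x$variances %||% "fixed1")
}

params_to_list <- function(ps) {
  base <- list(pi = ps$pi)
  if (ps$spec$family == "LCA") c(base, list(prob = ps$prob))
  else c(base, list(tau = ps$tau, lambda = ps$lambda, mu = ps$mu,
                    sigma2 = ps$sigma2))
}

params_from_list <- function(x, spec) {
  to_mat <- function(m) {
    m <- if (is.list(m)) do.call(rbind, lapply(m, unlist)) else as.matrix(m)
    matrix(as.numeric(m), spec$J, spec$K)
  }
  if (spec$family == "LCA")
    parameter_set(spec, pi = unlist(x$pi), prob = to_mat(x$prob))
  else
    parameter_set(spec, pi = unlist(x$pi), tau = to_mat(x$tau),
                  lambda = to_mat(x$lambda), mu = unlist(x$mu),
                  sigma2 = unlist(x$sigma2))
}

#' @rdname serialization
#' @param fit an `mlta_fit`.
#' @param path output/input file path.
#' @export
write_fit_json <- function(fit, path) {
  ic <- if (is.finite(fit$loglik %||% NA_real_) && !is.na(fit$n))
    information_criteria(fit) else NULL
  obj <- list(spec = spec_to_list(fit$spec),
              params = params_to_list(fit$params),
              loglik = fit$loglik, n = fit$n, p_free = fit$p_free,
              converged = fit$converged, n_starts = fit$n_starts,
              best_start_seed = fit$best_start_seed,
              class_labels = fit$class_labels,
              class_mean_scores = fit$class_mean_scores,
              indices = ic[c("AIC", "BIC", "ABIC")], nq = fit$nq %||% 21)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname serialization
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- spec_from_list(as.list(x$spec))
  params <- params_from_list(as.list(x$params), spec)
  fit <- structure(
    list(spec = spec, params = params,
         loglik = x$loglik %||% NA_real_, n = x$n %||% NA_integer_,
         p_free = x$p_free %||% count_free_parameters(spec),
         converged = x$converged %||% NA,
         n_starts = x$n_starts %||% NA_integer_,
         best_start_seed = x$best_start_seed %||% NA_integer_,
         nq = x$nq %||% 21),
    class = "mlta_fit")
  canonicalize_fit(fit)
}
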