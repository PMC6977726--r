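#' Generating parameters of the published two-class mixture IRT model
#'
#' The two-class, one-factor mixture IRT population used throughout the
#' package's synthetic-data checks: class weights 0.824 (food security)
#' and 0.176 (food insecurity); all loadings fixed at 1; food-security
#' class trait distribution N(-3.435, 2.352), food-insecurity class
#' anchored at N(0, 1); thresholds class-variant for item 1
#' (-3.433 / -0.862) and item 3 (-1.417 / -0.427) and shared for the
#' remaining items (0.864, 0.807, 1.892, 1.311, 2.607, 1.601, 4.452 for
#' items 2, 4, 5, 6, 7, 8, 9).
#'
#' @return list with `spec` (the matching [mlta_model] 2 specification)
#'   and `params` (a [parameter_set]).
#' @export
table2_parameters <- function() {
  spec <- mlta_model(2)
  tau <- matrix(0, 9, 2)
  tau[1, ] <- c(-3.433, -0.862)
  tau[3, ] <- c(-1.417, -0.427)
  shared <- c(item2 = 0.864, item4 = 0.807, item5 = 1.892, item6 = 1.311,
              item7 = 2.607, item8 = 1.601, item9 = 4.452)
  tau[c(2, 4, 5, 6, 7, 8, 9), 1] <- shared
  tau[c(2, 4, 5, 6, 7, 8, 9), 2] <- shared
  params <- parameter_set(spec, pi = c(0.824, 0.176), tau = tau,
                          lambda = matrix(1, 9, 2),
                          mu = c(-3.435, 0), sigma2 = c(2.352, 1))
  list(spec = spec, params = params)
}

#' Synthetic-data configuration
#'
#' @param spec a [model_spec].
#' @param params a matching [parameter_set].
#' @param n number of respondents.
#' @param seed RNG seed (Mersenne-Twister via `set.seed`; the single
#'   documented generator so replicates are portable).
#' @param export_truth keep the true class labels and trait values in the
#'   result (they are never placed inside the response matrix itself).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(spec, params, n, seed = 1L,
                             export_truth = TRUE) {
  validate_parameter_set(params)
  stopifnot(n >= 1)
  structure(list(spec = spec, params = params, n = as.integer(n),
                 seed = as.integer(seed),
                 export_truth = isTRUE(export_truth)),
            class = "synthetic_config")
}

#' Generate item responses from a mixture latent trait model
#'
#' Per respondent: class ~ Categorical(pi); trait F ~ N(mu_c, sigma2_c);
#' item j ~ Bernoulli(1 / (1 + exp(tau_jc - lambda_jc F))) independently
#' given F. Bit-reproducible given the seed.
#'
#' @param config a [synthetic_config()] (LCA parameter sets are routed to
#'   [generate_lca()]).
#' @return list: `responses` (n x J 0/1 integer matrix with item column
#'   names), `class` (true class index per respondent, if exported),
#'   `trait` (true F per respondent, if exported).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ps <- config$params
  if (ps$spec$family == "LCA") {
    out <- generate_lca(ps, config$n, config$seed)
    if (!config$export_truth) out$class <- NULL
    return(out)
  }
  set.seed(config$seed)
  n <- config$n; J <- ps$spec$J; K <- ps$spec$K
  cls <- sample.int(K, n, replace = TRUE, prob = ps$pi)
  f <- stats::rnorm(n, ps$mu[cls], sqrt(ps$sigma2[cls]))
  eta <- f * t(ps$lambda)[cls, , drop = FALSE] - t(ps$tau)[cls, , drop = FALSE]
  y <- matrix(as.integer(stats::runif(n * J) < stats::plogis(eta)), n, J)
  colnames(y) <- paste0("item", seq_len(J))
  rownames(y) <- seq_len(n)
  out <- list(responses = y)
  if (config$export_truth) { out$class <- cls; out$trait <- f }
  out
}

#' Generate item responses from a latent class model
#'
#' Class ~ Categorical(pi), then independent Bernoulli items with the
#' class-conditional probabilities.
#'
#' @param params an LCA [parameter_set].
#' @param n number of respondents.
#' @param seed RNG seed.
#' @return list: `responses` (n x J 0/1 matrix), `class` (true labels).
#' @export
generate_lca <- function(params, n, seed = 1L) {
  validate_parameter_set(params)
  stopifnot(params$spec$family == "LCA", n >= 1)
  set.seed(seed)
  J <- params$spec$J; K <- params$spec$K
  cls <- sample.int(K, n, replace = TRUE, prob = params$pi)
  p <- t(params$prob)[cls, , drop = FALSE]
  y <- matrix(as.integer(stats::runif(n * J) < p), n, J)
  colnames(y) <- paste0("item", seq_len(J))
  rownames(y) <- seq_len(n)
  list(responses = y, class = cls)
}

# generate from any fitted parameter set (used by the parametric bootstrap)
simulate_from <- function(params, n, seed = 1L) {
  if (params$spec$family == "LCA")
    generate_lca(params, n, seed)$responses
  else
    generate(synthetic_config(params$spec, params, n, seed,
                              export_truth = FALSE))$responses
}
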