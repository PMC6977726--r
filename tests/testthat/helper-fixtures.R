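# Shared fixtures and independent oracles used across the suite.

# small fit configuration keeping desk-scale runtime; tests that need the
# full 90-start policy say so explicitly
quick_ctrl <- list(short_maxit = 25, n_refine = 3)

# dense-grid trapezoid integration of the class-conditional pattern
# probability: the independent oracle for the quadrature code path
dense_pattern_prob <- function(y, class, params, lower = -10, upper = 10,
                               npts = 1e5) {
  f <- seq(lower, upper, length.out = npts)
  p <- vapply(seq_along(y), function(j)
    item_response_prob(f, params$tau[j, class], params$lambda[j, class]),
    numeric(npts))
  lik <- exp(rowSums(log(p) * rep(y, each = npts) +
                       log1p(-p) * rep(1 - y, each = npts)))
  dens <- stats::dnorm(f, params$mu[class], sqrt(params$sigma2[class]))
  h <- f[2] - f[1]
  g <- lik * dens
  h * (sum(g) - (g[1] + g[npts]) / 2)
}

# dense-grid posterior mean of the trait given a pattern (mixture-weighted)
dense_eap <- function(y, params, lower = -12, upper = 8, npts = 1e5) {
  f <- seq(lower, upper, length.out = npts)
  h <- f[2] - f[1]
  K <- params$spec$K
  joint <- matrix(0, npts, K)
  for (c in seq_len(K)) {
    p <- vapply(seq_along(y), function(j)
      item_response_prob(f, params$tau[j, c], params$lambda[j, c]),
      numeric(npts))
    lik <- exp(rowSums(log(p) * rep(y, each = npts) +
                         log1p(-p) * rep(1 - y, each = npts)))
    joint[, c] <- params$pi[c] * lik *
      stats::dnorm(f, params$mu[c], sqrt(params$sigma2[c]))
  }
  tot <- rowSums(joint)
  sum(f * tot * h) / sum(tot * h)
}

# well-separated 2-class LCA used in several recovery/power checks
separated_lca <- function() {
  spec <- lca_spec(2)
  list(spec = spec,
       params = parameter_set(spec, pi = c(0.6, 0.4),
                              prob = cbind(rep(0.08, 9), rep(0.9, 9))))
}

# write a 3-level answer CSV (a lot / sometimes / never) for load_responses
write_answer_csv <- function(path, answers, ids = seq_len(nrow(answers))) {
  df <- data.frame(id = ids, answers, check.names = FALSE)
  names(df) <- c("id", paste0("item", seq_len(ncol(answers))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
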