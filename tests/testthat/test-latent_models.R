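test_that("item_response_prob has the defining threshold property", {
  expect_equal(item_response_prob(2.607, tau = 2.607, lambda = 1), 0.5)
  expect_equal(item_response_prob(-1.3 / 0.7, tau = -1.3, lambda = 0.7), 0.5)
  # zero loading: flat in F (the LCA limit)
  expect_equal(item_response_prob(c(-5, 0, 5), tau = 1.2, lambda = 0),
               rep(plogis(-1.2), 3))
  expect_equal(item_response_prob(0, tau = -0.862), 0.7031, tolerance = 5e-5)
  # strictly increasing in F for positive loading
  f <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(item_response_prob(f, tau = 0.5, lambda = 1.3)) > 0))
})

test_that("count_free_parameters reproduces every laddered parameterization", {
  expect_equal(sapply(1:4, function(k) count_free_parameters(lca_spec(k))),
               c(9L, 19L, 29L, 39L))
  expect_equal(count_free_parameters(lta_spec()), 10L)
  expect_equal(sapply(1:6, function(m) count_free_parameters(mlta_model(m))),
               c(12L, 14L, 18L, 19L, 21L, 36L))
  expect_equal(count_free_parameters(mlta_model(2, K = 3)), 19L)
  # unidentified constraint patterns are refused
  expect_error(mlta_spec(2, 9, means = "free_class1",
                         variances = "free_per_class"), "unidentified")
  expect_error(mlta_spec(2, 9, loadings = "free",
                         variances = "free_class1"), "unidentified")
})

test_that("quadrature pattern probabilities agree with dense integration", {
  # 3-item toy model against a 1e5-point trapezoid rule
  spec <- mlta_spec(K = 1, J = 3)
  ps <- parameter_set(spec, pi = 1, tau = c(-1, 0, 1))
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (r in seq_len(nrow(pats))) {
    q <- class_conditional_pattern_prob(pats[r, ], 1, ps)
    expect_lt(abs(q - dense_pattern_prob(pats[r, ], 1, ps)), 1e-6)
  }
  # randomized small instances, fixed seed; a denser 61-node rule is used
  # so the check isolates the integration machinery from the question of
  # 21-node adequacy (a documented default, exercised above)
  set.seed(17)
  for (case in 1:5) {
    spec2 <- mlta_spec(K = 1, J = 3, loadings = "shared",
                       variances = "free_per_class")
    ps2 <- parameter_set(spec2, pi = 1, tau = runif(3, -2, 2),
                         lambda = matrix(runif(1, 0.5, 2), 3, 1),
                         sigma2 = runif(1, 0.5, 2))
    y <- sample(0:1, 3, replace = TRUE)
    expect_lt(abs(class_conditional_pattern_prob(y, 1, ps2, nq = 61) -
                    dense_pattern_prob(y, 1, ps2)), 1e-6)
  }
})

test_that("pattern probabilities normalize over all 512 patterns", {
  t2 <- table2_parameters()
  for (c in 1:2) {
    pr <- class_conditional_pattern_prob(mixlta:::all_patterns(9), c,
                                         t2$params)
    expect_equal(sum(pr), 1, tolerance = 1e-8)
    expect_true(all(pr >= 0 & pr <= 1))
  }
  # single item, zero loading reduces to a Bernoulli
  spec1 <- mlta_spec(K = 1, J = 1, loadings = "shared")
  ps1 <- parameter_set(spec1, pi = 1, tau = 0.7, lambda = 0)
  expect_equal(class_conditional_pattern_prob(1L, 1, ps1), plogis(-0.7),
               tolerance = 1e-12)
})

test_that("mixture_loglik matches closed forms and is additive", {
  # K = 1, zero loadings: independent-Bernoulli closed form
  spec <- mlta_spec(K = 1, J = 3, loadings = "shared")
  tau <- c(-0.5, 0.3, 1.1)
  ps <- parameter_set(spec, pi = 1, tau = tau, lambda = 0)
  set.seed(4)
  y <- matrix(sample(0:1, 60, replace = TRUE), 20, 3)
  p <- plogis(-tau)
  closed <- sum(y %*% log(p) + (1 - y) %*% log1p(-p))
  expect_equal(mixture_loglik(y, ps), closed, tolerance = 1e-10)
  # duplicating the data doubles the log-likelihood exactly
  expect_equal(mixture_loglik(rbind(y, y), ps), 2 * mixture_loglik(y, ps))
  # toy 2-respondent 2-item LCA, hand-enumerated
  lspec <- lca_spec(2, J = 2)
  lps <- parameter_set(lspec, pi = c(0.3, 0.7),
                       prob = cbind(c(0.2, 0.4), c(0.8, 0.6)))
  yy <- rbind(c(1L, 0L), c(0L, 1L))
  # P(1,0) = .3(.2*.6) + .7(.8*.4) = 0.26 ; P(0,1) = .3(.8*.4) + .7(.2*.6)
  expect_equal(mixture_loglik(yy, lps), log(0.26) + log(0.18),
               tolerance = 1e-12)
})

test_that("standardized loadings reproduce the printed algebra and limits", {
  t2 <- table2_parameters()
  sl <- standardize_loadings(t2$params)
  expect_equal(round(sl[1, 1], 3), 0.646)
  expect_equal(round(sl[1, 2], 3), 0.483)
  expect_true(all(abs(sl - sl[rep(1, 9), ]) < 1e-12)) # same within class
  spec <- mlta_spec(K = 1, J = 2, loadings = "free",
                    variances = "fixed1")
  ps0 <- parameter_set(spec, pi = 1, tau = c(0, 0),
                       lambda = c(0, 50))
  sl0 <- standardize_loadings(ps0)
  expect_equal(sl0[1, 1], 0)
  expect_gt(sl0[2, 1], 0.999)
})

test_that("fit_model recovers a single-class Rasch LTA", {
  spec <- lta_spec()
  tau <- c(-1.5, -0.5, 0, 0.5, 1, 1.5, 2, 2.5, 3)
  ps <- parameter_set(spec, pi = 1, tau = tau, sigma2 = 1.8)
  sim <- generate(synthetic_config(spec, ps, 5000, seed = 3))
  fit <- fit_model(sim$responses, spec, n_starts = 5, seed = 2,
                   control = quick_ctrl)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$tau[, 1] - tau)), 0.15)
  expect_lt(abs(fit$params$sigma2[1] - 1.8), 0.3)
  expect_true(all(diff(fit$loglik_trace) > -1e-6)) # EM monotone
})

test_that("fit_model recovers a well-separated 2-class LCA", {
  g <- separated_lca()
  sim <- generate_lca(g$params, 5000, seed = 7)
  fit <- fit_model(sim$responses, g$spec, n_starts = 8, seed = 5,
                   control = quick_ctrl)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$prob - g$params$prob)), 0.03)
  expect_lt(abs(fit$params$pi[1] - 0.6), 0.03)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # canonical order: class 1 is the low-scoring (food security) side
  expect_lt(fit$class_mean_scores[1], fit$class_mean_scores[2])
})

test_that("nested specs order the fitted log-likelihood", {
  t2 <- table2_parameters()
  sim <- generate(synthetic_config(t2$spec, t2$params, 800, seed = 21))
  f1 <- fit_model(sim$responses, mlta_model(1), n_starts = 8, seed = 9,
                  control = quick_ctrl)
  warm <- parameter_set(mlta_model(2), pi = f1$params$pi,
                        tau = f1$params$tau, lambda = f1$params$lambda,
                        mu = f1$params$mu, sigma2 = f1$params$sigma2)
  f2 <- fit_model(sim$responses, mlta_model(2), n_starts = 8, seed = 9,
                  control = modifyList(quick_ctrl, list(init = list(warm))))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_equal(f2$p_free, f1$p_free + 2L)
  # the fitted parameter set satisfies the constraint pattern exactly
  expect_silent(validate_parameter_set(f2$params))
  shared <- setdiff(1:9, c(1L, 3L))
  expect_identical(f2$params$tau[shared, 1], f2$params$tau[shared, 2])
})

test_that("fitting is invariant to respondent order", {
  g <- separated_lca()
  sim <- generate_lca(g$params, 400, seed = 12)
  y <- sim$responses
  set.seed(2)
  perm <- sample(nrow(y))
  f_a <- fit_model(y, g$spec, n_starts = 4, seed = 77, control = quick_ctrl)
  f_b <- fit_model(y[perm, ], g$spec, n_starts = 4, seed = 77,
                   control = quick_ctrl)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-12)
  expect_equal(f_a$params$prob, f_b$params$prob, tolerance = 1e-12)
})

test_that("parameter sets violating their spec are refused", {
  spec <- mlta_model(2)
  t2 <- table2_parameters()
  bad_tau <- t2$params$tau
  bad_tau[2, 2] <- bad_tau[2, 1] + 0.01   # item 2 must be shared
  expect_error(parameter_set(spec, pi = c(0.8, 0.2), tau = bad_tau,
                             mu = c(-3, 0), sigma2 = c(2, 1)),
               "identical across classes")
  expect_error(parameter_set(spec, pi = c(0.5, 0.6), tau = t2$params$tau,
                             mu = c(-3, 0), sigma2 = c(2, 1)), "sum to 1")
  expect_error(parameter_set(spec, pi = c(0.8, 0.2), tau = t2$params$tau,
                             mu = c(-3, 0.5), sigma2 = c(2, 1)), "anchor")
  expect_error(parameter_set(spec, pi = c(0.8, 0.2), tau = t2$params$tau,
                             mu = c(-3, 0), sigma2 = c(-1, 1)), "positive")
})
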