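toy_lca_fit <- function() {
  spec <- lca_spec(2, J = 2)
  ps <- parameter_set(spec, pi = c(0.3, 0.7),
                      prob = cbind(c(0.2, 0.4), c(0.8, 0.6)))
  as_fit(spec, ps)
}

test_that("posterior probabilities follow Bayes and normalize to 1e-10", {
  fit <- toy_lca_fit()
  y <- rbind(c(1L, 0L), c(0L, 1L))
  post <- posterior_probabilities(y, fit)
  # hand Bayes for (1,0): 0.3*(0.2*0.6) / 0.26 (class with items rarer)
  lab_low <- which(fit$class_labels == "food_security")
  expect_equal(post$prob[1, lab_low], 0.036 / 0.26, tolerance = 1e-12)
  expect_true(all(abs(rowSums(post$prob) - 1) < 1e-10))

  # K = 1: all posteriors are 1
  s1 <- mlta_spec(K = 1, J = 3)
  p1 <- parameter_set(s1, pi = 1, tau = c(-1, 0, 1))
  post1 <- posterior_probabilities(matrix(c(1L, 0L, 1L), 1), as_fit(s1, p1))
  expect_equal(as.numeric(post1$prob), 1)

  # larger normalization check under the two-class generator
  t2 <- table2_parameters()
  sim <- generate(synthetic_config(t2$spec, t2$params, 500, seed = 3))
  p2 <- posterior_probabilities(sim$responses, as_fit(t2$spec, t2$params))
  expect_true(all(abs(rowSums(p2$prob) - 1) < 1e-10))
})

test_that("mirrored two-class models swap posteriors for mirrored patterns", {
  spec <- lca_spec(2, J = 3)
  ps <- parameter_set(spec, pi = c(0.5, 0.5),
                      prob = cbind(c(0.2, 0.3, 0.4), c(0.8, 0.7, 0.6)))
  fit <- as_fit(spec, ps)
  y <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))   # pattern and its complement
  post <- posterior_probabilities(y, fit)
  expect_equal(post$prob[1, ], rev(post$prob[2, ]), tolerance = 1e-12)
  # exact tie breaks toward the lower class index
  spec_t <- lca_spec(2, J = 2)
  ps_t <- parameter_set(spec_t, pi = c(0.5, 0.5),
                        prob = cbind(c(0.3, 0.7), c(0.7, 0.3)))
  post_t <- posterior_probabilities(rbind(c(1L, 1L)), as_fit(spec_t, ps_t))
  expect_equal(as.numeric(post_t$prob), c(0.5, 0.5))
  expect_equal(post_t$map, 1L)
})

test_that("posterior prevalence matches the generator and exceeds MAP share", {
  t2 <- table2_parameters()
  fit <- as_fit(t2$spec, t2$params)
  sim <- generate(synthetic_config(t2$spec, t2$params, 20000, seed = 44))
  post <- posterior_probabilities(sim$responses, fit)
  prev <- prevalence_posterior(post, "food_insecurity")
  expect_lt(abs(prev - 0.176), 0.012)
  # the less certain minority class shrinks under MAP assignment
  expect_lt(prevalence_map(post, "food_insecurity"), prev)
  # degenerate posteriors: the two definitions coincide
  dg <- structure(list(prob = cbind(c(1, 0, 1), c(0, 1, 0)),
                       map = c(1L, 2L, 1L), labels = c("a", "b")),
                  class = "mlta_posterior")
  expect_equal(prevalence_posterior(dg, "b"), prevalence_map(dg, "b"))
})

test_that("average class probabilities: toy, degenerate, and model-implied", {
  toy <- structure(list(prob = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                        map = c(1L, 2L), labels = c("c1", "c2")),
                   class = "mlta_posterior")
  expect_equal(as.numeric(average_class_probabilities(toy)), c(0.9, 0.8))
  dg <- structure(list(prob = cbind(c(1, 0), c(0, 1)), map = c(1L, 2L),
                       labels = c("c1", "c2")), class = "mlta_posterior")
  expect_equal(as.numeric(average_class_probabilities(dg)), c(1, 1))
  # empty MAP class is flagged, not an error
  em <- structure(list(prob = rbind(c(0.6, 0.4), c(0.7, 0.3)),
                       map = c(1L, 1L), labels = c("c1", "c2")),
                  class = "mlta_posterior")
  out <- average_class_probabilities(em)
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "empty"), 2L)
  # model-implied diagonal under the printed generating model: 0.89 / 0.79
  t2 <- table2_parameters()
  acp <- model_average_class_probabilities(as_fit(t2$spec, t2$params))
  expect_equal(round(unname(acp["food_security"]), 2), 0.89)
  expect_equal(round(unname(acp["food_insecurity"]), 2), 0.79)
})

test_that("enumerate_pattern_probs is a coherent distribution with the
           printed margins", {
  t2 <- table2_parameters()
  fit <- as_fit(t2$spec, t2$params)
  enum <- enumerate_pattern_probs(fit)
  expect_equal(sum(enum$prob), 1, tolerance = 1e-10)
  expect_equal(nrow(enum$patterns), 512L)
  # margins via pattern summation equal the quadrature single-item path
  marg_q <- as.numeric(mixlta:::class_item_marginals(t2$params) %*%
                         t2$params$pi)
  expect_equal(enum$item_marginals, marg_q, tolerance = 1e-10)
  expect_equal(round(100 * enum$item_marginals[1], 1), 53.0)
  expect_equal(round(100 * enum$item_marginals[2], 1), 8.7)
})

test_that("pattern_fit accounts for every pattern and its mass", {
  t2 <- table2_parameters()
  fit <- as_fit(t2$spec, t2$params)
  sim <- generate(synthetic_config(t2$spec, t2$params, 20000, seed = 55))
  pf <- pattern_fit(sim$responses, fit)
  expect_equal(nrow(pf), 512L)
  expect_equal(sum(pf$expected), 20000, tolerance = 1e-6)
  expect_equal(sum(pf$observed), 20000)
  # unobserved patterns still appear, with positive expectation
  expect_true(any(pf$observed == 0))
  expect_true(all(pf$expected > 0))
  # calibration under the true model: total chi-square ~ cell count
  expect_lt(sum(pf$chisq), 2 * 512)
  expect_true(all(diff(pf$observed) <= 0))  # sorted by observed desc
})
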