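# exhaustive-search oracle over all single splits of all features: returns
# the (feature, cut, decrease) triple with first-wins tie-breaking
best_split_oracle <- function(x, y) {
  y <- as.integer(as.factor(y))
  gini <- function(v) { n <- length(v); if (!n) return(0)
    1 - sum((tabulate(v, 2) / n)^2) }
  parent <- length(y) * gini(y)
  best <- NULL; best_dec <- 0
  for (f in seq_len(ncol(x))) {
    uv <- sort(unique(x[, f]))
    if (length(uv) < 2) next
    for (cut in (uv[-1] + uv[-length(uv)]) / 2) {
      l <- x[, f] <= cut
      dec <- parent - sum(l) * gini(y[l]) - sum(!l) * gini(y[!l])
      if (dec > best_dec + 1e-12) { best_dec <- dec
        best <- list(feature = f, cut = cut, dec = dec) }
    }
  }
  best
}

# evaluate an extracted rule set on a feature row
rule_matches <- function(rule, row) {
  if (rule == "(all)") return(TRUE)
  all(vapply(strsplit(rule, " & ", fixed = TRUE)[[1]], function(cond) {
    p <- strsplit(cond, " ", fixed = TRUE)[[1]]
    v <- row[[p[1]]]; cut <- as.numeric(p[3])
    switch(p[2], "<=" = v <= cut, ">=" = v >= cut, ">" = v > cut,
           "==" = v == cut, stop("bad op ", p[2]))
  }, logical(1)))
}

test_that("a score-separable labelling yields one split between 3 and 4", {
  set.seed(9)
  y <- matrix(sample(0:1, 50 * 9, replace = TRUE), 50, 9)
  feats <- score_features(y)
  labels <- ifelse(feats$score >= 4, "insecure", "secure")
  tree <- fit_tree(feats, labels, tree_control(minsplit = 2))
  expect_false(tree$root$leaf)
  expect_equal(tree$features[tree$root$feature], "score")
  expect_gt(tree$root$cut, 3); expect_lt(tree$root$cut, 4)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)
  expect_equal(tree_accuracy(tree, feats, labels), 1)
  rules <- extract_rules(tree)
  expect_setequal(rules$rule, c("score <= 3", "score >= 4"))
  expect_equal(rules$class[rules$rule == "score >= 4"], "insecure")
})

test_that("degenerate labellings give leaves, not errors", {
  y <- matrix(sample(0:1, 90, replace = TRUE), 10, 9)
  feats <- score_features(y)
  tree <- fit_tree(feats, rep("same", 10))
  expect_true(tree$root$leaf)
  # single leaf on balanced binary labels: accuracy 0.5
  lab <- rep(c("a", "b"), 5)
  stump <- fit_tree(feats[, 1, drop = FALSE], lab,
                    tree_control(minsplit = 100))
  expect_true(stump$root$leaf)
  expect_equal(tree_accuracy(stump, feats[, 1, drop = FALSE], lab), 0.5)
})

test_that("the greedy first split agrees with the exhaustive oracle", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(3:6, 1)
    x <- cbind(a = sample(0:4, n, replace = TRUE),
               b = sample(0:1, n, replace = TRUE))
    y <- sample(c("p", "q"), n, replace = TRUE)
    tree <- fit_tree(x, y, tree_control(cp = 0, minsplit = 2))
    oracle <- best_split_oracle(x, y)
    if (is.null(oracle) || length(unique(y)) == 1L) {
      expect_true(tree$root$leaf)
    } else {
      expect_false(tree$root$leaf)
      expect_equal(tree$root$feature, oracle$feature)
      expect_equal(tree$root$cut, oracle$cut)
    }
  }
})

test_that("extracted rules reproduce tree predictions exactly", {
  t2 <- table2_parameters()
  sim <- generate(synthetic_config(t2$spec, t2$params, 600, seed = 10))
  fit <- as_fit(t2$spec, t2$params)
  post <- posterior_probabilities(sim$responses, fit)
  feats <- score_features(sim$responses)
  labels <- factor(post$labels[post$map], levels = unique(post$labels))
  tree <- fit_tree(feats, labels, tree_control_full())
  rules <- extract_rules(tree)
  expect_equal(sum(rules$n), nrow(feats))
  pred <- as.character(predict(tree, feats))
  for (i in seq_len(nrow(feats))) {
    hit <- which(vapply(rules$rule, rule_matches, logical(1),
                        row = feats[i, ]))
    expect_length(hit, 1L)
    expect_equal(rules$class[hit], pred[i])
  }
})

test_that("full growth reaches 100% accuracy on pattern-determined labels", {
  t2 <- table2_parameters()
  sim <- generate(synthetic_config(t2$spec, t2$params, 2132, seed = 31))
  post <- posterior_probabilities(sim$responses, as_fit(t2$spec, t2$params))
  feats <- score_features(sim$responses)
  labels <- factor(post$labels[post$map], levels = unique(post$labels))
  tree <- fit_tree(feats, labels, tree_control_full())
  expect_equal(tree_accuracy(tree, feats, labels), 1)
  # every split strictly reduces weighted Gini impurity
  gini <- function(counts) 1 - sum((counts / sum(counts))^2)
  check <- function(node) {
    if (node$leaf) return(invisible())
    wg <- function(nd) sum(nd$counts) * gini(nd$counts)
    expect_lt(wg(node$left) + wg(node$right), wg(node))
    check(node$left); check(node$right)
  }
  check(tree$root)
})

test_that("the population MAP rule is the published cut-off structure", {
  t2 <- table2_parameters()
  enum <- enumerate_pattern_probs(as_fit(t2$spec, t2$params))
  score <- rowSums(enum$patterns)
  insecure <- enum$map == 2L
  expect_true(all(insecure[score >= 4]))
  expect_true(all(!insecure[score <= 1]))
  # scores 2-3: secure iff item 1 affirmed and (score 2 or item 3 affirmed)
  mid <- score %in% 2:3
  secure_rule <- enum$patterns[, 1] == 1 &
    (score == 2 | enum$patterns[, 3] == 1)
  expect_equal(!insecure[mid], secure_rule[mid])
})
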