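#' Control settings for the classification tree
#'
#' Defaults mirror the common CART defaults (complexity penalty 0.01,
#' minimum split size 20). The full-growth preset (`cp = 0`,
#' `minsplit = 2`) grows until nodes are pure and is the configuration
#' under which a tree over the raw score and all items reproduces a
#' pattern-determined labelling exactly.
#'
#' @param cp complexity penalty: a split is kept only when its impurity
#'   improvement, scaled by the root impurity, exceeds `cp`.
#' @param minsplit minimum node size eligible for splitting.
#' @param maxdepth maximum tree depth.
#' @return list of class `tree_control`.
#' @export
tree_control <- function(cp = 0.01, minsplit = 20, maxdepth = 30) {
  stopifnot(cp >= 0, minsplit >= 2, maxdepth >= 1)
  structure(list(cp = cp, minsplit = minsplit, maxdepth = maxdepth),
            class = "tree_control")
}

#' @rdname tree_control
#' @export
tree_control_full <- function() tree_control(cp = 0, minsplit = 2)

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

#' Fit a binary CART classification tree
#'
#' Greedy recursive binary partitioning minimizing Gini impurity.
#' Deterministic given the data and control: features are scanned in
#' column order and candidate thresholds (midpoints of adjacent observed
#' values) in increasing order, with strictly-better-wins tie-breaking, so
#' the first best split encountered is kept. Single-class labels yield a
#' single-leaf tree.
#'
#' @param features data.frame or matrix of numeric features (for the
#'   cut-off analysis: the raw score plus the nine 0/1 items, in that
#'   order; see [score_features()]).
#' @param labels binary class labels (factor or vector with 2 levels; a
#'   single level gives a leaf).
#' @param control a [tree_control()].
#' @return object of class `cart_tree` with the root node, feature names,
#'   class levels and control.
#' @export
fit_tree <- function(features, labels, control = tree_control()) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  labels <- as.factor(labels)
  levels_ <- levels(labels)
  if (length(levels_) > 2L) stop("only binary labels are supported")
  yi <- as.integer(labels)
  n <- nrow(x)
  stopifnot(length(yi) == n, n >= 1)
  root_counts <- tabulate(yi, nbins = max(2L, length(levels_)))
  root_gini <- gini_impurity(root_counts)

  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], nbins = length(levels_))
    node_gini <- gini_impurity(counts)
    leaf <- function() list(leaf = TRUE, class = which.max(counts),
                            n = length(idx), counts = counts)
    if (node_gini == 0 || length(idx) < control$minsplit ||
        depth >= control$maxdepth || root_gini == 0)
      return(leaf())
    best <- NULL
    best_score <- 0
    for (f in seq_len(ncol(x))) {
      v <- x[idx, f]
      uv <- sort(unique(v))
      if (length(uv) < 2L) next
      cuts <- (uv[-1] + uv[-length(uv)]) / 2
      for (cut in cuts) {
        left <- v <= cut
        nl <- sum(left); nr <- length(idx) - nl
        if (nl == 0L || nr == 0L) next
        cl <- tabulate(yi[idx][left], nbins = length(levels_))
        cr <- counts - cl
        dec <- length(idx) * node_gini -
          nl * gini_impurity(cl) - nr * gini_impurity(cr)
        if (dec > best_score + 1e-12) {
          best_score <- dec
          best <- list(feature = f, cut = cut, left = left)
        }
      }
    }
    if (is.null(best) || best_score / (n * root_gini) <= control$cp)
      return(leaf())
    list(leaf = FALSE, feature = best$feature, cut = best$cut,
         n = length(idx), counts = counts,
         left = grow(idx[best$left], depth + 1L),
         right = grow(idx[!best$left], depth + 1L))
  }

  structure(list(root = grow(seq_len(n), 0L), features = colnames(x),
                 levels = levels_, control = control, n = n),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "index"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata))
  x <- x[, object$features, drop = FALSE]
  route <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$feature] <= node$cut) node$left else node$right
    node$class
  }
  idx <- vapply(seq_len(nrow(x)), function(i) route(object$root, x[i, ]),
                integer(1))
  if (type == "index") idx else factor(object$levels[idx],
                                       levels = object$levels)
}

#' Training accuracy of a classification tree
#'
#' @param tree a `cart_tree`.
#' @param features feature table used for prediction.
#' @param labels reference labels (same coding used at fit time).
#' @return proportion of respondents predicted into their reference class.
#' @export
tree_accuracy <- function(tree, features, labels) {
  pred <- predict(tree, features, type = "class")
  mean(as.character(pred) == as.character(as.factor(labels)))
}

#' Extract decision rules from a fitted tree
#'
#' Root-to-leaf path conjunctions with redundant conditions on the same
#' feature merged (for each feature only the tightest lower and upper
#' bound survives). Conditions on integer-valued features such as the raw
#' score are printed in integer form (`score >= 4` rather than
#' `score > 3.5`); 0/1 items print as equality tests.
#'
#' @param tree a `cart_tree`.
#' @return data.frame of class `rule_set`: `rule` (conjunction text),
#'   `class` (predicted label), `n` (training coverage).
#' @export
extract_rules <- function(tree) {
  paths <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      paths[[length(paths) + 1L]] <<-
        list(conds = conds, class = tree$levels[node$class], n = node$n)
      return(invisible())
    }
    fname <- tree$features[node$feature]
    walk(node$left, c(conds, list(list(f = fname, op = "<=", v = node$cut))))
    walk(node$right, c(conds, list(list(f = fname, op = ">", v = node$cut))))
  }
  walk(tree$root, list())

  fmt_path <- function(conds) {
    if (!length(conds)) return("(all)")
    ub <- list(); lb <- list()
    for (cd in conds) {
      if (cd$op == "<=") {
        if (is.null(ub[[cd$f]]) || cd$v < ub[[cd$f]]) ub[[cd$f]] <- cd$v
      } else {
        if (is.null(lb[[cd$f]]) || cd$v > lb[[cd$f]]) lb[[cd$f]] <- cd$v
      }
    }
    txt <- character(0)
    for (f in unique(c(names(lb), names(ub)))) {
      lo <- lb[[f]]; hi <- ub[[f]]
      # binary feature bounded on one side only -> equality form
      if (!is.null(hi) && is.null(lo) && hi > 0 && hi < 1) {
        txt <- c(txt, sprintf("%s == 0", f)); next
      }
      if (!is.null(lo) && is.null(hi) && lo > 0 && lo < 1) {
        txt <- c(txt, sprintf("%s == 1", f)); next
      }
      # cuts fall at midpoints, so integer features tighten to integers
      lo_int <- if (!is.null(lo) && abs(lo - round(lo)) > 1e-9)
        ceiling(lo) else NULL
      hi_int <- if (!is.null(hi) && abs(hi - round(hi)) > 1e-9)
        floor(hi) else NULL
      if (!is.null(lo_int) && !is.null(hi_int) && lo_int == hi_int) {
        txt <- c(txt, sprintf("%s == %d", f, lo_int)); next
      }
      if (!is.null(hi))
        txt <- c(txt, if (!is.null(hi_int)) sprintf("%s <= %d", f, hi_int)
                 else sprintf("%s <= %g", f, hi))
      if (!is.null(lo))
        txt <- c(txt, if (!is.null(lo_int)) sprintf("%s >= %d", f, lo_int)
                 else sprintf("%s > %g", f, lo))
    }
    paste(txt, collapse = " & ")
  }

  out <- data.frame(
    rule = vapply(paths, function(p) fmt_path(p$conds), character(1)),
    class = vapply(paths, `[[`, character(1), "class"),
    n = vapply(paths, function(p) as.integer(p$n), integer(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("rule_set", class(out))
  out
}

#' @export
print.cart_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s-> %s (n = %d)\n", pad, x$levels[node$class], node$n))
      return(invisible())
    }
    f <- x$features[node$feature]
    cat(sprintf("%sif %s <= %g:\n", pad, f, node$cut))
    rec(node$left, indent + 1L)
    cat(sprintf("%selse (%s > %g):\n", pad, f, node$cut))
    rec(node$right, indent + 1L)
  }
  cat(sprintf("<cart_tree> n = %d, classes: %s\n", x$n,
              paste(x$levels, collapse = ", ")))
  rec(x$root, 0L)
  invisible(x)
}

#' Feature table for the cut-off tree
#'
#' Raw score followed by the nine item indicators, the feature set over
#' which scale cut-offs are derived.
#'
#' @param data 0/1 response matrix.
#' @return data.frame with columns `score`, `item1`, ..., `itemJ`.
#' @export
score_features <- function(data) {
  y <- as_response_matrix(data)
  out <- data.frame(score = raw_score(y), y)
  names(out) <- c("score", colnames(y))
  out
}
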