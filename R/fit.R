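#' Fit a latent structure model by marginal maximum likelihood
#'
#' Maximizes the mixture observed-data log-likelihood by EM. The E-step
#' computes posterior class responsibilities per unique response pattern;
#' the M-step updates the mixing proportions in closed form and the
#' structural parameters (thresholds, loadings, class means/variances) by
#' bounded quasi-Newton (L-BFGS-B with analytic gradients) on the
#' Gauss-Hermite quadrature approximation of the expected complete-data
#' log-likelihood. LCA uses closed-form M-steps throughout. The EM update
#' never decreases the observed-data log-likelihood (generalized EM).
#'
#' Random starts follow a two-stage strategy: every start runs a short EM,
#' and the most promising candidates are refined to full tolerance; the
#' best refined solution is returned. Start values perturb the thresholds
#' around the logits of the marginal item proportions, draw mixing
#' proportions from a flat Dirichlet, class-1 means from N(0, 2) and
#' variances from LogNormal(0, 0.25); the RNG stream for start i is seeded
#' with `seed + i`.
#'
#' @param data 0/1 response matrix (or [load_responses()] result).
#' @param spec a [model_spec].
#' @param n_starts number of random starts (default 90).
#' @param seed base seed for the start streams.
#' @param tol relative log-likelihood convergence tolerance.
#' @param control list overriding internals: `nq` quadrature nodes (21),
#'   `maxit` EM iterations (2000), `mstep_maxit` inner L-BFGS-B iterations
#'   (10), `short_maxit`/`short_tol` for stage-1 starts (30, 1e-5),
#'   `n_refine` candidates refined to convergence (5), `init` an optional
#'   list of [parameter_set] warm starts prepended to the random starts.
#' @return an object of class `mlta_fit`: spec, params, loglik, n, p_free,
#'   converged, n_starts, best_start_seed, standardized_loadings (trait
#'   models), loglik_trace of the winning run, class_labels and
#'   class_mean_scores (model-implied mean raw score per class), and
#'   boundary flags.
#' @export
fit_model <- function(data, spec, n_starts = 90, seed = 1L, tol = 1e-7,
                      control = list()) {
  validate_model_spec(spec)
  y <- as_response_matrix(data)
  if (ncol(y) != spec$J) stop("data has ", ncol(y), " items but spec J = ",
                              spec$J)
  ctrl <- modifyList(list(nq = 21, maxit = 2000, mstep_maxit = 10,
                          short_maxit = 30, short_tol = 1e-5, n_refine = 5,
                          init = NULL), control)
  p_free <- count_free_parameters(spec)
  if (nrow(y) < p_free)
    stop("n = ", nrow(y), " respondents is below the free-parameter count ",
         p_free)
  cp <- compress_patterns(y)
  n <- sum(cp$counts)
  pbar <- as.numeric(crossprod(cp$y, cp$counts)) / n

  starts <- list()
  for (ini in ctrl$init)
    starts[[length(starts) + 1L]] <- list(params = ini, seed = NA_integer_)
  for (i in seq_len(n_starts)) {
    s <- as.integer((seed + i) %% .Machine$integer.max)
    starts[[length(starts) + 1L]] <-
      list(params = random_start(spec, pbar, s), seed = s)
  }
  if (!length(starts)) stop("no starting values (n_starts = 0, no init)")

  stage1 <- lapply(starts, function(st) {
    r <- tryCatch(
      em_fit(cp$y, cp$counts, spec, st$params, nq = ctrl$nq,
             maxit = ctrl$short_maxit, tol = ctrl$short_tol,
             mstep_maxit = ctrl$mstep_maxit),
      error = function(e) list(loglik = -Inf, error = conditionMessage(e)))
    r$seed <- st$seed
    r
  })
  lls <- vapply(stage1, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) {
    msgs <- unique(unlist(lapply(stage1, `[[`, "error")))
    stop("no start converged; diagnostics: ", paste(msgs, collapse = "; "))
  }
  keep <- order(lls, decreasing = TRUE)[seq_len(min(ctrl$n_refine,
                                                    sum(is.finite(lls))))]
  refined <- lapply(keep, function(k) {
    r <- tryCatch(
      em_fit(cp$y, cp$counts, spec, stage1[[k]]$params, nq = ctrl$nq,
             maxit = ctrl$maxit, tol = tol,
             mstep_maxit = ctrl$mstep_maxit),
      error = function(e) list(loglik = -Inf, error = conditionMessage(e)))
    r$seed <- stage1[[k]]$seed
    r
  })
  rll <- vapply(refined, `[[`, numeric(1), "loglik")
  if (all(!is.finite(rll))) stop("no refined start converged")
  best <- refined[[which.max(rll)]]

  fit <- structure(
    list(spec = spec, params = best$params, loglik = best$loglik, n = n,
         p_free = p_free, converged = isTRUE(best$converged),
         n_starts = length(starts), best_start_seed = best$seed,
         loglik_trace = best$trace, boundary = isTRUE(best$boundary),
         n_patterns = nrow(cp$y), nq = ctrl$nq),
    class = "mlta_fit")
  canonicalize_fit(fit)
}

#' @export
print.mlta_fit <- function(x, ...) {
  cat(sprintf("<mlta_fit> %s, K = %d, J = %d\n", x$spec$family, x$spec$K,
              x$spec$J))
  cat(sprintf("  n = %d, logLik = %.3f, free parameters = %d, %s\n",
              x$n, x$loglik, x$p_free,
              if (x$converged) "converged" else "NOT converged"))
  cat("  pi:", paste(round(x$params$pi, 3), collapse = " "),
      "| labels:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.mlta_fit <- function(object, ...) {
  structure(object$loglik, df = object$p_free, nobs = object$n,
            class = "logLik")
}

# ---- internals --------------------------------------------------------------

# model-implied marginal affirmative probability per item and class (J x K)
class_item_marginals <- function(ps, nq = 21) {
  spec <- ps$spec
  if (spec$family == "LCA") return(ps$prob)
  m <- vapply(seq_len(spec$K), function(c) {
    rule <- normal_quadrature(nq, ps$mu[c], sqrt(ps$sigma2[c]))
    il <- class_item_logprobs(ps, c, rule)
    as.numeric(il$p %*% rule$weights)
  }, numeric(spec$J))
  matrix(m, spec$J, spec$K)
}

# Attach semantic class labels (and physically reorder classes when the
# constraint pattern permits) so that the class with the lowest
# model-implied mean raw score comes first ("food security" for K = 2).
canonicalize_fit <- function(fit) {
  ps <- fit$params
  spec <- fit$spec
  marg <- class_item_marginals(ps, fit$nq)
  mean_scores <- colSums(marg)
  K <- spec$K
  ord <- order(mean_scores)
  if (K > 1L && is_label_symmetric(spec) && !identical(ord, seq_len(K))) {
    ps$pi <- ps$pi[ord]
    if (spec$family == "LCA") ps$prob <- ps$prob[, ord, drop = FALSE]
    else {
      ps$tau <- ps$tau[, ord, drop = FALSE]
      ps$lambda <- ps$lambda[, ord, drop = FALSE]
      ps$mu <- ps$mu[ord]
      ps$sigma2 <- ps$sigma2[ord]
    }
    mean_scores <- mean_scores[ord]
    fit$params <- validate_parameter_set(ps)
  }
  labels <- paste0("class", seq_len(K))
  if (K == 2L) {
    rk <- rank(mean_scores, ties.method = "first")
    labels <- c("food_security", "food_insecurity")[rk]
  }
  fit$class_labels <- labels
  fit$class_mean_scores <- mean_scores
  if (spec$family != "LCA")
    fit$standardized_loadings <- standardize_loadings(fit$params)
  fit
}

random_start <- function(spec, pbar, seed) {
  set.seed(seed)
  K <- spec$K; J <- spec$J
  pclip <- pmin(pmax(pbar, 0.02), 0.98)
  g <- stats::rexp(K) + 0.1
  pi <- g / sum(g)
  pi <- pmax(pi, 0.05); pi <- pi / sum(pi)
  if (spec$family == "LCA") {
    prob <- stats::plogis(stats::qlogis(pclip) +
                            matrix(stats::rnorm(J * K), J, K))
    return(parameter_set(spec, pi = pi, prob = prob))
  }
  tau <- matrix(-stats::qlogis(pclip), J, K) +
    matrix(stats::rnorm(J * K), J, K)
  shared <- setdiff(seq_len(J), spec$variant_items)
  tau[shared, ] <- tau[shared, 1L]
  lambda <- switch(spec$loadings,
    fixed1 = matrix(1, J, K),
    shared = matrix(exp(stats::rnorm(1, 0, 0.3)), J, K),
    free   = matrix(exp(stats::rnorm(J * K, 0, 0.3)), J, K))
  mu <- numeric(K)
  if (spec$means == "free_class1")
    mu[seq_len(K - 1L)] <- stats::rnorm(K - 1L, 0, sqrt(2))
  sigma2 <- rep(1, K)
  if (spec$variances == "free_class1")
    sigma2[seq_len(K - 1L)] <- stats::rlnorm(K - 1L, 0, 0.25)
  if (spec$variances == "free_per_class")
    sigma2 <- stats::rlnorm(K, 0, 0.25)
  parameter_set(spec, pi = pi, tau = tau, lambda = lambda, mu = mu,
                sigma2 = sigma2)
}

PI_FLOOR <- 1e-4
SIG_FLOOR <- 1e-4

em_fit <- function(yu, counts, spec, init, nq, maxit, tol, mstep_maxit) {
  ps <- init
  n <- sum(counts)
  trait <- spec$family != "LCA"
  map <- if (trait) make_parmap(spec) else NULL
  bounds <- if (trait) theta_bounds(map) else NULL
  trace <- numeric(0)
  converged <- FALSE
  boundary <- FALSE
  pm <- class_prob_matrix(yu, ps, nq)
  ll <- -Inf
  for (it in seq_len(maxit)) {
    mix <- as.numeric(pm %*% ps$pi)
    if (any(mix <= 0) || any(!is.finite(mix)))
      stop("zero-probability pattern encountered during EM")
    ll_new <- sum(counts * log(mix))
    trace <- c(trace, ll_new)
    if (it > 1L && ll_new - ll < tol * max(1, abs(ll_new))) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
    z <- sweep(pm, 2, ps$pi, `*`) / mix
    w <- counts * z                                   # patterns x K
    pi_new <- colSums(w) / n
    if (any(pi_new < PI_FLOOR)) {
      boundary <- TRUE
      pi_new <- pmax(pi_new, PI_FLOOR)
      pi_new <- pi_new / sum(pi_new)
    }
    ps$pi <- pi_new
    if (!trait) {
      pr <- crossprod(yu, w)                          # J x K
      pr <- sweep(pr, 2, colSums(w), `/`)
      ps$prob <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
    } else {
      theta0 <- pack_theta(ps, map)
      env <- q_environment(yu, w, spec, map, nq)
      opt <- stats::optim(theta0, fn = env$negq, gr = env$neggrad,
                          method = "L-BFGS-B",
                          lower = bounds$lower, upper = bounds$upper,
                          control = list(maxit = mstep_maxit))
      if (opt$value <= env$negq(theta0) + 1e-10)
        ps <- unpack_theta(opt$par, spec, ps$pi, map)
      if (any(ps$sigma2 <= SIG_FLOOR * 1.0001)) boundary <- TRUE
    }
    pm <- class_prob_matrix(yu, ps, nq)
  }
  list(params = ps, loglik = ll, trace = trace, converged = converged,
       boundary = boundary, iterations = length(trace))
}

theta_bounds <- function(map) {
  lower <- rep(-30, map$n_theta)
  upper <- rep(30, map$n_theta)
  lam <- unique(map$lambda[map$lambda > 0L])
  lower[lam] <- -15; upper[lam] <- 15
  lsig <- unique(map$lsig[map$lsig > 0L])
  lower[lsig] <- log(SIG_FLOOR); upper[lsig] <- log(1e4)
  list(lower = lower, upper = upper)
}

# Expected complete-data log-likelihood (structural part) and its analytic
# gradient, as closures over the fixed responsibilities w = counts * z.
q_environment <- function(yu, w, spec, map, nq) {
  K <- spec$K; J <- spec$J
  gh <- gauss_hermite(nq)
  wq <- gh$weights / sqrt(pi)
  last_theta <- NULL
  last <- NULL

  evaluate <- function(theta) {
    if (!is.null(last_theta) && identical(theta, last_theta)) return(last)
    ps <- unpack_theta(theta, spec, rep(1 / K, K), map)
    q_val <- 0
    grad <- numeric(map$n_theta)
    for (c in seq_len(K)) {
      sd_c <- sqrt(ps$sigma2[c])
      f_q <- ps$mu[c] + sd_c * sqrt(2) * gh$nodes
      eta <- outer(ps$lambda[, c], f_q) - ps$tau[, c]
      lp <- stats::plogis(eta, log.p = TRUE)
      l1p <- stats::plogis(-eta, log.p = TRUE)
      p <- stats::plogis(eta)
      a <- yu %*% lp + (1 - yu) %*% l1p
      lmat <- exp(a)
      pv <- pmax(as.numeric(lmat %*% wq), 1e-300)
      q_val <- q_val + sum(w[, c] * log(pv))
      coef <- w[, c] / pv
      g <- sweep(lmat * coef, 2, wq, `*`)             # patterns x nodes
      gq <- colSums(g)
      s_jq <- t(crossprod(g, yu))                     # J x Q
      d <- s_jq - sweep(p, 2, gq, `*`)                # J x Q
      d_tau <- -rowSums(d)
      for (j in seq_len(J)) {
        grad[map$tau[j, c]] <- grad[map$tau[j, c]] + d_tau[j]
        if (map$lambda[j, c] > 0L)
          grad[map$lambda[j, c]] <- grad[map$lambda[j, c]] +
            sum(d[j, ] * f_q)
      }
      if (map$mu[c] > 0L)
        grad[map$mu[c]] <- grad[map$mu[c]] +
          sum(ps$lambda[, c] * rowSums(d))
      if (map$lsig[c] > 0L)
        grad[map$lsig[c]] <- grad[map$lsig[c]] +
          sum((d %*% (f_q - ps$mu[c])) * ps$lambda[, c]) / 2
    }
    last_theta <<- theta
    last <<- list(value = q_val, grad = grad)
    last
  }
  list(negq = function(theta) -evaluate(theta)$value,
       neggrad = function(theta) -evaluate(theta)$grad)
}

#' Observed-information standard errors (diagnostic)
#'
#' Numerical-Hessian standard errors of the free parameters at the fitted
#' maximum, on the estimation scale (log variances; multinomial logits for
#' the mixing proportions, last class as reference). These are plain
#' observed-information SEs, not robust/sandwich SEs.
#'
#' @param fit an `mlta_fit`.
#' @param data the response matrix the model was fitted to.
#' @return named vector of standard errors.
#' @export
observed_information_se <- function(fit, data) {
  y <- as_response_matrix(data)
  spec <- fit$spec
  cp <- compress_patterns(y)
  K <- spec$K
  if (spec$family == "LCA")
    stop("diagnostic SEs are implemented for trait models only")
  map <- make_parmap(spec)
  pack <- function(ps) {
    alpha <- if (K > 1L) log(ps$pi[-K] / ps$pi[K]) else numeric(0)
    c(alpha, pack_theta(ps, map))
  }
  unpack <- function(v) {
    if (K > 1L) {
      ea <- exp(c(v[seq_len(K - 1L)], 0))
      pi <- ea / sum(ea)
      theta <- v[-seq_len(K - 1L)]
    } else {
      pi <- 1; theta <- v
    }
    unpack_theta(theta, spec, pi, map)
  }
  negll <- function(v) {
    ps <- unpack(v)
    pm <- class_prob_matrix(cp$y, ps, fit$nq)
    -sum(cp$counts * log(pmax(as.numeric(pm %*% ps$pi), 1e-300)))
  }
  v0 <- pack(fit$params)
  h <- stats::optimHess(v0, negll)
  se <- sqrt(diag(solve(h)))
  names(se) <- c(if (K > 1L) paste0("alpha", seq_len(K - 1L)),
                 theta_names(map, spec))
  se
}

theta_names <- function(map, spec) {
  nm <- character(map$n_theta)
  for (j in seq_len(spec$J)) for (c in seq_len(spec$K)) {
    if (map$tau[j, c] > 0L && !nzchar(nm[map$tau[j, c]]))
      nm[map$tau[j, c]] <- if (j %in% spec$variant_items)
        sprintf("tau%d.c%d", j, c) else sprintf("tau%d", j)
    if (map$lambda[j, c] > 0L && !nzchar(nm[map$lambda[j, c]]))
      nm[map$lambda[j, c]] <- if (spec$loadings == "shared") "lambda"
        else sprintf("lambda%d.c%d", j, c)
  }
  for (c in seq_len(spec$K)) {
    if (map$mu[c] > 0L) nm[map$mu[c]] <- sprintf("mu%d", c)
    if (map$lsig[c] > 0L) nm[map$lsig[c]] <- sprintf("log_sigma2_%d", c)
  }
  nm
}
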