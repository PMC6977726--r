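#' Expected a-posteriori (EAP) latent trait scores
#'
#' Mixture-weighted posterior mean of the latent trait:
#' \eqn{E[F | y_i] = \sum_c p_{ic} E[F | y_i, c]}, with the class-conditional
#' posterior mean evaluated by Gauss-Hermite quadrature against that
#' class's trait distribution.
#'
#' @param data 0/1 response matrix.
#' @param fit a trait-model `mlta_fit` (or [as_fit()] stub).
#' @param nq quadrature nodes.
#' @return numeric vector of per-respondent EAP scores.
#' @export
eap_factor_scores <- function(data, fit, nq = NULL) {
  y <- as_response_matrix(data)
  ps <- fit$params
  if (ps$spec$family == "LCA")
    stop("EAP factor scores require a latent trait model (LTA/MLTA)")
  nq <- nq %||% fit$nq %||% 21
  cp <- compress_patterns(y)
  K <- ps$spec$K
  cond_mean <- matrix(0, nrow(cp$y), K)
  pm <- matrix(0, nrow(cp$y), K)
  for (c in seq_len(K)) {
    rule <- normal_quadrature(nq, ps$mu[c], sqrt(ps$sigma2[c]))
    il <- class_item_logprobs(ps, c, rule)
    lmat <- exp(cp$y %*% il$lp + (1 - cp$y) %*% il$l1p)
    pv <- as.numeric(lmat %*% rule$weights)
    pm[, c] <- pv
    cond_mean[, c] <- as.numeric(lmat %*% (rule$weights * rule$nodes)) / pv
  }
  num <- sweep(pm, 2, ps$pi, `*`)
  z <- num / rowSums(num)
  eap_u <- rowSums(z * cond_mean)
  eap_u[cp$row_index]
}

#' Differential item functioning by logistic regression
#'
#' For each item, regresses the 0/1 response on the class indicator plus
#' the latent factor score and reports the Wald test of the class
#' coefficient. An item shows DIF when class membership remains associated
#' with the response after conditioning on the trait. Quasi-separation is
#' flagged, not raised.
#'
#' @param data 0/1 response matrix.
#' @param map_labels per-respondent class assignment (integer or factor;
#'   typically the MAP classes of the invariant-thresholds model).
#' @param scores per-respondent factor scores from the same model.
#' @param alpha significance level for the DIF flag (default 0.05).
#' @param bonferroni divide alpha by the number of items (default FALSE,
#'   matching the conventional per-item 0.05 usage).
#' @return data.frame: `item`, `beta` (class coefficient), `se`, `p_value`,
#'   `dif` flag, `separation` flag.
#' @export
dif_test <- function(data, map_labels, scores, alpha = 0.05,
                     bonferroni = FALSE) {
  y <- as_response_matrix(data)
  cls <- as.integer(as.factor(map_labels))
  if (length(unique(cls)) < 2L)
    stop("class indicator is constant; DIF is undefined for a single class")
  stopifnot(length(cls) == nrow(y), length(scores) == nrow(y))
  thr <- if (bonferroni) alpha / ncol(y) else alpha
  rows <- lapply(seq_len(ncol(y)), function(j) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y[, j] ~ factor(cls) + scores, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    cls_row <- grep("^factor\\(cls\\)", rownames(co))[1L]
    beta <- co[cls_row, 1L]; se <- co[cls_row, 2L]; p <- co[cls_row, 4L]
    if (!sep && (abs(beta) > 15 || se > 50)) sep <- TRUE
    data.frame(item = j, beta = beta, se = se, p_value = p,
               dif = is.finite(p) && p < thr, separation = sep)
  })
  do.call(rbind, rows)
}

#' Per-item threshold-invariance sensitivity scan
#'
#' Starting from the invariant-thresholds base model, refits one model per
#' item with that item's threshold freed across classes and reports the
#' likelihood ratio statistic (2 * delta-LL, 1 df) and chi-square p-value.
#' Each variant adds exactly one free parameter. Variants are warm-started
#' from the base solution in addition to fresh random starts.
#'
#' @param data 0/1 response matrix.
#' @param base either a base-model `mlta_fit` or a [model_spec] with no
#'   class-variant thresholds (fitted here if a spec is given).
#' @param n_starts,seed,control fitting configuration (see [fit_model()]).
#' @param alpha flag level (default 0.05).
#' @return data.frame: `item`, `loglik_base`, `loglik_variant`, `lr`,
#'   `df`, `p_value`, `flag`, `converged`, `note`.
#' @export
threshold_invariance_scan <- function(data, base, n_starts = 10, seed = 1L,
                                      control = list(), alpha = 0.05) {
  y <- as_response_matrix(data)
  if (inherits(base, "model_spec")) {
    if (length(base$variant_items))
      stop("base spec must have class-invariant thresholds")
    base <- fit_model(y, base, n_starts = max(n_starts, 10), seed = seed,
                      control = control)
  }
  spec0 <- base$spec
  if (length(spec0$variant_items))
    stop("base fit must have class-invariant thresholds")
  rows <- lapply(seq_len(spec0$J), function(j) {
    spec_j <- mlta_spec(spec0$K, spec0$J, variant_items = j,
                        loadings = spec0$loadings, means = spec0$means,
                        variances = spec0$variances)
    ctrl_j <- modifyList(control, list(init = list(
      parameter_set(spec_j, pi = base$params$pi, tau = base$params$tau,
                    lambda = base$params$lambda, mu = base$params$mu,
                    sigma2 = base$params$sigma2))))
    fit_j <- tryCatch(
      fit_model(y, spec_j, n_starts = n_starts, seed = seed + j,
                control = ctrl_j),
      error = function(e) e)
    if (inherits(fit_j, "error"))
      return(data.frame(item = j, loglik_base = base$loglik,
                        loglik_variant = NA_real_, lr = NA_real_, df = 1L,
                        p_value = NA_real_, flag = NA,
                        converged = FALSE,
                        note = conditionMessage(fit_j),
                        stringsAsFactors = FALSE))
    lr <- 2 * (fit_j$loglik - base$loglik)
    if (lr < -1e-4)
      warning("variant for item ", j, " fitted below the base model (lr = ",
              signif(lr, 3), "); increase starts")
    lr_clamped <- max(lr, 0)
    p <- stats::pchisq(lr_clamped, df = 1, lower.tail = FALSE)
    data.frame(item = j, loglik_base = base$loglik,
               loglik_variant = fit_j$loglik, lr = lr, df = 1L,
               p_value = p, flag = p < alpha, converged = fit_j$converged,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
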