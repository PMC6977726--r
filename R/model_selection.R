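#' Information criteria for a fitted model
#'
#' AIC = -2LL + 2p; BIC = -2LL + p log(n); sample-size-adjusted BIC
#' (ABIC) = -2LL + p log((n + 2)/24), with p the free-parameter count and
#' n the respondent count.
#'
#' @param fit an `mlta_fit` (or any list with `loglik`, `p_free`, `n`).
#' @return list with `AIC`, `BIC`, `ABIC`, `loglik`, `p_free`, `n`.
#' @export
information_criteria <- function(fit) {
  stopifnot(is.finite(fit$loglik), fit$n >= 1)
  m2ll <- -2 * fit$loglik
  p <- fit$p_free
  n <- fit$n
  list(AIC = m2ll + 2 * p,
       BIC = m2ll + p * log(n),
       ABIC = m2ll + p * log((n + 2) / 24),
       loglik = fit$loglik, p_free = p, n = n)
}

#' Relative entropy of a posterior classification
#'
#' \eqn{1 - \sum_i \sum_c (-p_{ic} \log p_{ic}) / (n \log K)}: 1 for a
#' perfectly separated classification, 0 for uniformly uncertain rows.
#' Undefined (error) for K = 1, matching the convention of leaving the
#' entropy blank for single-class models.
#'
#' @param post n x K posterior probability matrix (rows sum to 1), or a
#'   [posterior_probabilities()] result.
#' @return scalar in [0, 1].
#' @export
entropy <- function(post) {
  if (is.list(post) && !is.null(post$prob)) post <- post$prob
  stopifnot(is.matrix(post))
  k <- ncol(post)
  if (k < 2L) stop("entropy is undefined for a single class (K = 1)")
  if (any(abs(rowSums(post) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  n <- nrow(post)
  plogp <- ifelse(post > 0, post * log(post), 0)
  1 - sum(-plogp) / (n * log(k))
}

#' Bootstrapped likelihood ratio test for the number of classes
#'
#' Parametric bootstrap comparison of a k-class model against a nested
#' (k-1)-class model: both are fitted to the observed data; B datasets of
#' the same size are generated from the fitted null (k-1) model, both
#' models are refitted to each, and the p-value is
#' (1 + #\{LR_b >= LR_obs\}) / (B + 1).
#'
#' @param data 0/1 response matrix.
#' @param spec_k alternative [model_spec].
#' @param spec_km1 null [model_spec], nested in `spec_k`.
#' @param B bootstrap replicates (default 99).
#' @param seed RNG seed governing replicate generation and refits.
#' @param n_starts random starts per bootstrap fit (default 10, fewer than
#'   a final analysis fit, to keep the bootstrap tractable).
#' @param control passed to [fit_model()].
#' @return list with `lr_obs`, `lr_boot`, `B`, `p_value`,
#'   `replicate_converged`; errors if more than 10\% of replicates fail.
#' @export
blrt <- function(data, spec_k, spec_km1, B = 99, seed = 1L, n_starts = 10,
                 control = list()) {
  y <- as_response_matrix(data)
  if (count_free_parameters(spec_km1) > count_free_parameters(spec_k))
    stop("spec_km1 must be nested in (no larger than) spec_k")
  fit_k <- fit_model(y, spec_k, n_starts = n_starts, seed = seed,
                     control = control)
  fit_0 <- fit_model(y, spec_km1, n_starts = n_starts, seed = seed,
                     control = control)
  lr_obs <- 2 * (fit_k$loglik - fit_0$loglik)
  n <- nrow(y)
  lr_boot <- rep(NA_real_, B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    sb <- as.integer((seed + 1000L + b) %% .Machine$integer.max)
    yb <- simulate_from(fit_0$params, n, seed = sb)
    res <- tryCatch({
      fk <- fit_model(yb, spec_k, n_starts = n_starts, seed = sb,
                      control = control)
      f0 <- fit_model(yb, spec_km1, n_starts = n_starts, seed = sb,
                      control = control)
      2 * (fk$loglik - f0$loglik)
    }, error = function(e) NA_real_)
    lr_boot[b] <- res
    ok[b] <- is.finite(res)
  }
  if (mean(!ok) > 0.10)
    stop("more than 10% of bootstrap replicates failed to converge (",
         sum(!ok), "/", B, ")")
  lrb <- lr_boot[ok]
  p <- (1 + sum(lrb >= lr_obs)) / (sum(ok) + 1)
  list(lr_obs = lr_obs, lr_boot = lr_boot, B = B, p_value = p,
       replicate_converged = ok, fit_k = fit_k, fit_km1 = fit_0)
}

#' Fit and tabulate a ladder of candidate models
#'
#' Fits every specification in `specs` with a shared seed policy and
#' tabulates free parameters, log-likelihood, AIC/BIC/ABIC and relative
#' entropy (blank for K = 1), flagging the best model per criterion.
#' Fit failures are annotated in the row and the ladder continues.
#'
#' @param data 0/1 response matrix.
#' @param specs named list of [model_spec]s (names become row labels).
#' @param n_starts,seed,tol,control passed to [fit_model()].
#' @return list with `table` (data.frame), `fits` (list of `mlta_fit`),
#'   and `best` (named list of best row label per criterion).
#' @export
model_ladder <- function(data, specs, n_starts = 20, seed = 1L, tol = 1e-7,
                         control = list()) {
  y <- as_response_matrix(data)
  if (!length(specs)) stop("at least one model spec is required")
  if (is.null(names(specs)))
    names(specs) <- paste0("model", seq_along(specs))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  rows <- lapply(names(specs), function(nm) {
    fit <- tryCatch(fit_model(y, specs[[nm]], n_starts = n_starts,
                              seed = seed, tol = tol, control = control),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(model = nm, p_free = count_free_parameters(specs[[nm]]),
                        loglik = NA_real_, AIC = NA_real_, BIC = NA_real_,
                        ABIC = NA_real_, entropy = NA_real_,
                        note = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    fits[[nm]] <<- fit
    ic <- information_criteria(fit)
    ent <- if (specs[[nm]]$K >= 2L)
      entropy(posterior_probabilities(y, fit)$prob) else NA_real_
    data.frame(model = nm, p_free = fit$p_free, loglik = fit$loglik,
               AIC = ic$AIC, BIC = ic$BIC, ABIC = ic$ABIC, entropy = ent,
               note = if (fit$converged) "" else "not converged",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- list()
  for (crit in c("AIC", "BIC", "ABIC"))
    if (any(is.finite(tab[[crit]])))
      best[[crit]] <- tab$model[which.min(tab[[crit]])]
  if (any(is.finite(tab$entropy)))
    best$entropy <- tab$model[which.max(tab$entropy)]
  list(table = tab, fits = fits, best = best)
}
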