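#' Model specifications for latent structure models on binary items
#'
#' A `model_spec` declares the family (LCA, LTA or MLTA), the number of
#' latent classes K, the number of items J, and the equality/fixing
#' constraint pattern on the parameter blocks:
#'
#' * `loadings`: `"fixed1"` (all discriminations fixed at 1, the Rasch
#'   convention), `"shared"` (one free loading common to all items and
#'   classes) or `"free"` (one loading per item per class);
#' * `variant_items`: the set of items whose threshold is allowed to differ
#'   between classes (all other items share one threshold across classes);
#' * `means`: `"fixed0"` (all class factor means fixed at 0) or
#'   `"free_class1"` (free for class 1 -- and, when K > 2, for every
#'   non-anchor class -- with the last class anchored at 0);
#' * `variances`: `"fixed1"`, `"free_class1"` (free for the non-anchor
#'   classes, last class fixed at 1) or `"free_per_class"`.
#'
#' LCA carries no latent trait: its class-conditional model is a product of
#' Bernoullis with free per-item per-class probabilities. LTA is the single
#' class (K = 1) Rasch model: loadings fixed at 1, mean fixed at 0, free
#' factor variance.
#'
#' @name model_spec
NULL

new_model_spec <- function(family, K, J, variant_items = integer(),
                           loadings = "fixed1", means = "fixed0",
                           variances = "fixed1") {
  spec <- structure(
    list(family = family, K = as.integer(K), J = as.integer(J),
         variant_items = sort(unique(as.integer(variant_items))),
         loadings = loadings, means = means, variances = variances),
    class = "model_spec")
  validate_model_spec(spec)
  spec
}

validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$family %in% c("LCA", "LTA", "MLTA"))
    stop("unknown model family: ", spec$family)
  if (spec$K < 1L) stop("K must be >= 1")
  if (spec$J < 1L) stop("J must be >= 1")
  if (spec$family == "LTA" && spec$K != 1L)
    stop("LTA implies a single class (K = 1)")
  if (spec$family == "LCA") return(invisible(spec))
  if (length(spec$variant_items) &&
      (min(spec$variant_items) < 1L || max(spec$variant_items) > spec$J))
    stop("variant_items outside 1..J")
  if (!spec$loadings %in% c("fixed1", "shared", "free"))
    stop("unknown loadings constraint: ", spec$loadings)
  if (!spec$means %in% c("fixed0", "free_class1"))
    stop("unknown means constraint: ", spec$means)
  if (!spec$variances %in% c("fixed1", "free_class1", "free_per_class"))
    stop("unknown variances constraint: ", spec$variances)
  # identification: a free mean or variance needs an anchored reference class
  if (spec$K > 1L) {
    if (spec$means == "free_class1" && spec$variances == "free_per_class")
      stop("unidentified constraint pattern: free class-1 mean with all ",
           "variances free leaves no anchored class")
    if (spec$loadings == "free" && spec$variances != "fixed1")
      stop("unidentified constraint pattern: free loadings require ",
           "variances fixed at 1")
    if (spec$loadings == "free" && spec$means != "fixed0")
      stop("unidentified constraint pattern: free loadings require ",
           "means fixed at 0")
  }
  if (spec$K == 1L && spec$means == "free_class1")
    stop("a single-class model cannot free its mean (scale unidentified)")
  invisible(spec)
}

#' Latent class analysis specification
#' @param K number of classes (>= 1).
#' @param J number of items (default 9).
#' @return a `model_spec`.
#' @export
lca_spec <- function(K, J = 9) new_model_spec("LCA", K, J)

#' Rasch latent trait (1-factor, 1-class) specification
#'
#' Loadings fixed at 1, factor mean fixed at 0, free factor variance:
#' J + 1 free parameters.
#' @param J number of items (default 9).
#' @return a `model_spec`.
#' @export
lta_spec <- function(J = 9)
  new_model_spec("LTA", 1L, J, variances = "free_per_class")

#' Mixture latent trait specification
#'
#' General constructor; see [model_spec] for the constraint vocabulary.
#'
#' @param K number of classes.
#' @param J number of items.
#' @param variant_items items whose thresholds differ between classes.
#' @param loadings,means,variances constraint keywords.
#' @return a `model_spec`.
#' @export
mlta_spec <- function(K = 2, J = 9, variant_items = integer(),
                      loadings = "fixed1", means = "fixed0",
                      variances = "fixed1")
  new_model_spec("MLTA", K, J, variant_items, loadings, means, variances)

#' The six standard two-class MLTA parameterizations
#'
#' Named presets for the constraint patterns commonly laddered when a
#' two-class mixture IRT model is fitted to a 9-item scale:
#'
#' 1. invariant item parameters; class-1 mean and variance free, class 2
#'    anchored at N(0, 1);
#' 2. as model 1 but thresholds class-variant for items 1 and 3;
#' 3. thresholds class-variant for all items except item 9; both classes
#'    anchored at N(0, 1);
#' 4. as model 3 but class-1 variance free (means fixed at 0);
#' 5. all thresholds class-variant; means fixed at 0; both variances free;
#' 6. free loadings per item and class; thresholds class-variant except
#'    item 9; both classes anchored at N(0, 1).
#'
#' @param model integer in 1..6.
#' @param K number of classes (default 2).
#' @param J number of items (default 9).
#' @return a `model_spec`.
#' @export
mlta_model <- function(model, K = 2, J = 9) {
  stopifnot(length(model) == 1L, model %in% 1:6)
  all_but_last <- seq_len(J - 1L)
  switch(as.character(model),
    "1" = mlta_spec(K, J, integer(), "fixed1", "free_class1", "free_class1"),
    "2" = mlta_spec(K, J, c(1L, 3L), "fixed1", "free_class1", "free_class1"),
    "3" = mlta_spec(K, J, all_but_last, "fixed1", "fixed0", "fixed1"),
    "4" = mlta_spec(K, J, all_but_last, "fixed1", "fixed0", "free_class1"),
    "5" = mlta_spec(K, J, seq_len(J), "fixed1", "fixed0", "free_per_class"),
    "6" = mlta_spec(K, J, all_but_last, "free", "fixed0", "fixed1"))
}

#' Count free parameters of a model specification
#'
#' LCA with K classes and J items has (K - 1) mixing proportions plus J x K
#' class-conditional item probabilities. Trait models count (K - 1) mixing
#' proportions, one threshold per item plus (K - 1) extra per class-variant
#' item, loadings per the constraint (0, 1 or J x K), plus free means and
#' variances.
#'
#' @param spec a `model_spec`.
#' @return integer count.
#' @export
count_free_parameters <- function(spec) {
  validate_model_spec(spec)
  K <- spec$K; J <- spec$J
  if (spec$family == "LCA") return(as.integer((K - 1L) + J * K))
  n_tau <- J + length(spec$variant_items) * (K - 1L)
  n_lambda <- switch(spec$loadings, fixed1 = 0L, shared = 1L, free = J * K)
  n_mu <- switch(spec$means, fixed0 = 0L, free_class1 = K - 1L)
  n_sig <- switch(spec$variances, fixed1 = 0L, free_class1 = K - 1L,
                  free_per_class = K)
  as.integer((K - 1L) + n_tau + n_lambda + n_mu + n_sig)
}

# TRUE when permuting class indices leaves the constraint pattern invariant
# (then fitted classes can be physically reordered without breaking ties).
is_label_symmetric <- function(spec) {
  if (spec$family == "LCA") return(TRUE)
  if (spec$K == 1L) return(TRUE)
  spec$means == "fixed0" && spec$variances %in% c("fixed1", "free_per_class")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, K = %d, J = %d\n", x$family, x$K, x$J))
  if (x$family != "LCA") {
    vi <- if (length(x$variant_items))
      paste(x$variant_items, collapse = ",") else "none"
    cat(sprintf("  loadings: %s | class-variant thresholds: %s\n",
                x$loadings, vi))
    cat(sprintf("  means: %s | variances: %s\n", x$means, x$variances))
  }
  cat(sprintf("  free parameters: %d\n", count_free_parameters(x)))
  invisible(x)
}
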