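#' MCMC configuration for Bayesian marker-effect models
#'
#' @param n_iter total Gibbs iterations (default 10000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every `thin`-th post-burn-in sample (default 5).
#' @param pi_zero prior probability that a marker effect is exactly zero
#'   (default 0.95, so the prior inclusion probability is 0.05).
#' @param seed RNG seed.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000, burn_in = 2000, thin = 5,
                        pi_zero = 0.95, seed = 1) {
  if (burn_in >= n_iter) stopf("burn_in must be smaller than n_iter")
  if (pi_zero <= 0 || pi_zero >= 1) stopf("pi_zero must lie in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), pi_zero = pi_zero,
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' BayesB: Bayesian variable-selection regression on markers
#'
#' Gibbs sampler for the model in which each marker effect is zero with
#' prior probability `pi_zero` and otherwise normal with its own variance
#' under a scaled-inverse-chi-square prior (a point mass at zero mixed with
#' an inverted chi-square, following Meuwissen-style BayesB). The marker
#' variance scale is set from `var(y)` so that the slab explains about half
#' the phenotypic variance a priori.
#'
#' @param y numeric response.
#' @param W marker matrix (individuals x markers); columns are centered
#'   internally.
#' @param config an [mcmc_config()].
#' @return object of class `bayesb_fit`: `mu`, `effects` (posterior means on
#'   the centered scale), `inclusion_prob`, `ve`, `fitted`, `col_means`,
#'   `config`.
#' @export
bayesb_fit <- function(y, W, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  y <- as.numeric(y)
  W <- as.matrix(W)
  if (anyNA(y) || anyNA(W)) stopf("missing data not allowed")
  if (nrow(W) != length(y)) stopf("rows of W must match length of y")
  col_means <- colMeans(W)
  Wc <- sweep(W, 2, col_means)
  vy <- var(y)
  msx <- sum(apply(Wc, 2, var))
  if (msx == 0) stopf("all markers are constant")
  df0 <- 4.2
  R2 <- 0.5
  S0 <- vy * R2 * (df0 + 2) / (df0 * msx * (1 - config$pi_zero))
  dfe0 <- 5
  Se0 <- vy * (1 - R2) * (dfe0 + 2) / dfe0
  set.seed(config$seed)
  res <- .bayesb_gibbs(y, Wc, config$n_iter, config$burn_in, config$thin,
                       config$pi_zero, df0, S0, dfe0, Se0)
  out <- list(mu = res$mu, effects = setNames(res$effects, colnames(W)),
              inclusion_prob = setNames(res$inclusion_prob, colnames(W)),
              ve = res$ve, col_means = col_means,
              fitted = res$mu + drop(Wc %*% res$effects),
              n_saved = res$n_saved, config = config)
  class(out) <- "bayesb_fit"
  out
}

#' @param object a `bayesb_fit`.
#' @param W_new marker matrix for new individuals (same columns as training).
#' @param ... unused.
#' @rdname bayesb_fit
#' @export
predict.bayesb_fit <- function(object, W_new, ...) {
  W_new <- as.matrix(W_new)
  object$mu + drop(sweep(W_new, 2, object$col_means) %*% object$effects)
}

#' @export
#' @method print bayesb_fit
print.bayesb_fit <- function(x, ...) {
  cat(sprintf("<bayesb_fit> %d markers, %d posterior samples, ve = %.4f\n",
              length(x$effects), x$n_saved, x$ve))
  invisible(x)
}
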