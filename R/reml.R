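#' EM-REML for the additive + dominance genomic mixed model
#'
#' Fits `y = X beta + u_a + u_d + e` with `u_a ~ N(0, K_a phi_a^2)`,
#' `u_d ~ N(0, K_d phi_d^2)`, `e ~ N(0, I sigma^2)` by EM-REML. With kinships
#' built by [additive_kinship()] / [dominance_kinship()] (divisor `m`), this
#' kernel model is exactly the marker-effect model in which every marker
#' effect has variance `phi^2 / m`.
#'
#' The EM update for each component k is
#' `phi_k^2 <- phi_k^2 + (phi_k^4 / n) (y' P K_k P y - tr(P K_k))`, which
#' keeps the restricted log-likelihood monotone non-decreasing; iteration
#' stops when the log-likelihood changes by less than `tol` or after
#' `max_iter` iterations. Components are floored at 1e-10. When only one
#' kernel is supplied the model is rotated to that kernel's eigenbasis once,
#' after which every iteration costs O(n).
#'
#' @param y numeric response (no missing values).
#' @param Ka additive kinship matrix (n x n).
#' @param Kd optional dominance kinship matrix.
#' @param X fixed-effect design matrix; defaults to an intercept.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return object of class `reml_fit`: list with `varcomp` (named vector
#'   `va`, `vd`, `ve`), `beta`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, `Py` (the REML projection of y, equal to
#'   `V^{-1}(y - X beta)`), `fitted` (in-sample genetic predictions plus
#'   fixed effects), `se` (asymptotic standard errors of the variance
#'   components from the expected information matrix), and `n`.
#' @export
reml_fit <- function(y, Ka, Kd = NULL, X = NULL, tol = 1e-6, max_iter = 500) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stopf("y contains non-finite values")
  if (n < 10) stopf("need at least 10 observations")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stopf("singular fixed-effect design matrix")
  if (nrow(Ka) != n || (!is.null(Kd) && nrow(Kd) != n))
    stopf("kinship dimensions do not match y")

  if (is.null(Kd)) {
    fit <- reml_em_rotated(y, Ka, X, tol, max_iter)
  } else {
    fit <- reml_em_dense(y, list(Ka, Kd), X, tol, max_iter)
  }
  vc <- fit$varcomp
  names(vc) <- if (is.null(Kd)) c("va", "ve") else c("va", "vd", "ve")
  out <- list(varcomp = c(va = unname(vc["va"]),
                          vd = if (is.null(Kd)) 0 else unname(vc["vd"]),
                          ve = unname(vc["ve"])),
              beta = fit$beta, loglik = fit$loglik,
              loglik_trace = fit$loglik_trace, converged = fit$converged,
              n_iter = fit$n_iter, Py = fit$Py, se = fit$se, n = n,
              has_dominance = !is.null(Kd))
  gen <- out$varcomp[["va"]] * drop(Ka %*% out$Py)
  if (!is.null(Kd)) gen <- gen + out$varcomp[["vd"]] * drop(Kd %*% out$Py)
  out$fitted <- drop(X %*% out$beta) + gen
  class(out) <- "reml_fit"
  out
}

# Generic dense EM-REML over an arbitrary list of kernels.
reml_em_dense <- function(y, Ks, X, tol, max_iter) {
  n <- length(y)
  nk <- length(Ks)
  vc <- rep(var(y) / (nk + 1), nk + 1)  # kernels..., residual
  if (vc[1] == 0) vc <- rep(1e-6, nk + 1)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    V <- diag(vc[nk + 1], n)
    for (k in seq_len(nk)) V <- V + vc[k] * Ks[[k]]
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_i <- solve(XtViX)
    Py <- Vi %*% y - ViX %*% (XtViX_i %*% crossprod(ViX, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # P = Vi - ViX (X'ViX)^-1 X'Vi, needed for traces
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    for (k in seq_len(nk)) {
      KPy <- Ks[[k]] %*% Py
      upd <- vc[k] + vc[k]^2 / n * (sum(Py * KPy) - sum(P * Ks[[k]]))
      vc[k] <- max(upd, 1e-10)
    }
    vc[nk + 1] <- max(vc[nk + 1] + vc[nk + 1]^2 / n *
                        (sum(Py * Py) - sum(diag(P))), 1e-10)
  }
  # final quantities + expected-information SEs
  V <- diag(vc[nk + 1], n)
  for (k in seq_len(nk)) V <- V + vc[k] * Ks[[k]]
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  XtViX_i <- solve(crossprod(X, ViX))
  beta <- drop(XtViX_i %*% crossprod(ViX, y))
  Py <- drop(Vi %*% y - ViX %*% (XtViX_i %*% crossprod(ViX, y)))
  P <- Vi - ViX %*% XtViX_i %*% t(ViX)
  PKs <- c(lapply(Ks, function(K) P %*% K), list(P))
  info <- matrix(0, nk + 1, nk + 1)
  for (i in seq_len(nk + 1)) for (j in i:(nk + 1)) {
    info[i, j] <- info[j, i] <- 0.5 * sum(PKs[[i]] * t(PKs[[j]]))
  }
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, nk + 1))
  names(vc) <- names(se) <- NULL
  list(varcomp = setNames(vc, c(paste0("k", seq_len(nk)), "ve")[c(seq_len(nk), nk + 1)]),
       beta = beta, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged,
       n_iter = length(ll_trace), Py = Py, se = se)
}

# Single-kernel EM-REML in the kernel eigenbasis: O(n) per iteration.
reml_em_rotated <- function(y, K, X, tol, max_iter) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)
  vc <- c(va = var(y) / 2, ve = var(y) / 2)
  if (vc[1] == 0) vc <- c(va = 1e-6, ve = 1e-6)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  proj <- function(v) {
    # returns list(Py_rot, XtViX, ViX) for diagonal V = diag(v)
    ViX <- Xs / v
    XtViX <- crossprod(Xs, ViX)
    XtViX_i <- solve(XtViX)
    Py <- ys / v - ViX %*% (XtViX_i %*% crossprod(Xs, ys / v))
    list(Py = drop(Py), XtViX = XtViX, XtViX_i = XtViX_i, ViX = ViX)
  }
  for (it in seq_len(max_iter)) {
    v <- vc[1] * lam + vc[2]
    pr <- proj(v)
    Py <- pr$Py
    ll <- -0.5 * (sum(log(v)) + determinant(pr$XtViX)$modulus[1] +
                    sum(ys * Py))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # tr(P K) = sum(lam / v) - tr((X'ViX)^-1 X'Vi Lam Vi X); same for tr(P)
    XtViLViX <- crossprod(Xs / v, (lam / v) * Xs)
    XtViViX <- crossprod(Xs / v, Xs / v)
    trPK <- sum(lam / v) - sum(diag(pr$XtViX_i %*% XtViLViX))
    trP <- sum(1 / v) - sum(diag(pr$XtViX_i %*% XtViViX))
    vc[1] <- max(vc[1] + vc[1]^2 / n * (sum(Py * lam * Py) - trPK), 1e-10)
    vc[2] <- max(vc[2] + vc[2]^2 / n * (sum(Py * Py) - trP), 1e-10)
  }
  v <- vc[1] * lam + vc[2]
  pr <- proj(v)
  beta <- drop(pr$XtViX_i %*% crossprod(Xs, ys / v))
  Py_rot <- pr$Py
  # expected information in rotated space (P is dense only through the small
  # fixed-effect correction; build it explicitly once)
  Pm <- diag(1 / v) - (Xs / v) %*% pr$XtViX_i %*% t(Xs / v)
  PK <- Pm * rep(lam, each = n)  # P %*% diag(lam)
  info <- matrix(0, 2, 2)
  info[1, 1] <- 0.5 * sum(PK * t(PK))
  info[1, 2] <- info[2, 1] <- 0.5 * sum(PK * Pm)
  info[2, 2] <- 0.5 * sum(Pm * Pm)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) c(NA_real_, NA_real_))
  list(varcomp = setNames(unname(vc), c("va", "ve")), beta = beta,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = length(ll_trace),
       Py = drop(U %*% Py_rot), se = se)
}

#' @export
#' @method print reml_fit
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>\n  variance components:\n")
  print(round(x$varcomp, 6))
  cat(sprintf("  logLik %.4f after %d EM iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' GBLUP prediction for new individuals from a kernel fit
#'
#' Predicts `X_test beta + [phi_a^2 K_a,ts + phi_d^2 K_d,ts] V^{-1}
#' (y - X beta)`, using the identity `P y = V^{-1}(y - X beta_gls)` so only
#' the cross-kinship blocks between test and training individuals are
#' needed.
#'
#' @param fit a [reml_fit()].
#' @param Ka_ts additive cross-kinship, test rows x training columns (built
#'   with the training-panel centering).
#' @param Kd_ts optional dominance cross-kinship.
#' @param X_test fixed-effect design for the test rows (default intercept).
#' @return numeric vector of predictions.
#' @export
gblup_predict <- function(fit, Ka_ts, Kd_ts = NULL, X_test = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  Ka_ts <- as.matrix(Ka_ts)
  if (ncol(Ka_ts) != fit$n) stopf("cross-kinship columns must match training size")
  if (is.null(X_test)) X_test <- matrix(1, nrow(Ka_ts), 1)
  pred <- drop(as.matrix(X_test) %*% fit$beta) +
    fit$varcomp[["va"]] * drop(Ka_ts %*% fit$Py)
  if (!is.null(Kd_ts)) {
    if (fit$varcomp[["vd"]] == 0 && !fit$has_dominance)
      stopf("fit has no dominance component")
    pred <- pred + fit$varcomp[["vd"]] * drop(Kd_ts %*% fit$Py)
  }
  pred
}

#' Fit the additive + dominance GBLUP model from a hybrid coding
#'
#' Convenience wrapper: builds the kinship pair, runs [reml_fit()], and
#' back-solves the equivalent per-marker effects
#' `a_hat = (phi_a^2 / m) W_a' P y` (and likewise for dominance), which make
#' prediction of arbitrarily many new hybrids a cheap matrix product.
#'
#' @param y phenotypes aligned with `coding` rows.
#' @param coding a [infer_hybrid_genotypes()] result.
#' @param dominance include the dominance component (default TRUE).
#' @param X fixed-effect design (default intercept).
#' @param ... passed to [reml_fit()].
#' @return object of class `gblup_fit`: the `reml_fit` plus `marker_effects`
#'   (`add`, `dom`), centering (`freqs`, `dmeans`), and `m`.
#' @export
gblup_fit <- function(y, coding, dominance = TRUE, X = NULL, ...) {
  kin <- kinship_pair(coding)
  fit <- reml_fit(y, kin$Ka, if (dominance) kin$Kd else NULL, X = X, ...)
  Wa <- sweep(coding$Za, 2, 2 * kin$freqs)
  eff_a <- drop(crossprod(Wa, fit$Py)) * fit$varcomp[["va"]] / kin$m
  eff_d <- if (dominance) {
    Wd <- sweep(coding$Zd, 2, kin$dmeans)
    drop(crossprod(Wd, fit$Py)) * fit$varcomp[["vd"]] / kin$m
  } else NULL
  out <- c(fit, list(marker_effects = list(add = eff_a, dom = eff_d),
                     freqs = kin$freqs, dmeans = kin$dmeans, m = kin$m,
                     markers = coding$markers, dominance = dominance))
  class(out) <- c("gblup_fit", "reml_fit")
  out
}

#' @param object a `gblup_fit`.
#' @param coding a hybrid coding for the individuals to predict (same
#'   markers as the training coding).
#' @param ... unused.
#' @rdname gblup_fit
#' @export
predict.gblup_fit <- function(object, coding, ...) {
  if (!identical(coding$markers, object$markers))
    stopf("prediction coding must use the training markers")
  pred <- object$beta[1] +
    drop(sweep(coding$Za, 2, 2 * object$freqs) %*% object$marker_effects$add)
  if (object$dominance)
    pred <- pred +
      drop(sweep(coding$Zd, 2, object$dmeans) %*% object$marker_effects$dom)
  setNames(pred, coding$hybrid)
}
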