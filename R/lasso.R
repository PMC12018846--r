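#' LASSO regression on markers by cyclic coordinate descent
#'
#' Minimises `(1/2n) ||y - mu - W b||^2 + lambda ||b||_1` over a log-spaced
#' lambda grid with warm starts, using covariance-form coordinate updates
#' (soft-thresholding). Columns are standardised internally; coefficients
#' are returned on the original scale. The reported `lambda` is chosen by
#' inner k-fold cross-validation (minimum held-out MSE).
#'
#' @param y numeric response.
#' @param W marker matrix (individuals x markers).
#' @param n_lambda grid size (default 50).
#' @param lambda_min_ratio smallest lambda as a fraction of the smallest
#'   lambda that zeroes every coefficient; defaults to 1e-4 when n > p and
#'   0.01 otherwise (the usual convention for wide marker matrices).
#' @param inner_cv_folds folds for the inner lambda selection (default 5).
#' @param seed seed for the inner fold assignment.
#' @param max_iter,tol coordinate-descent controls.
#' @return object of class `lasso_fit`: `mu` (intercept), `effects`
#'   (original-scale coefficients at the selected lambda), `lambda`,
#'   `lambda_grid`, `cv_mse`, `fitted`, `dropped` (zero-variance columns).
#' @export
lasso_fit <- function(y, W, n_lambda = 50, lambda_min_ratio = NULL,
                      inner_cv_folds = 5, seed = 1, max_iter = 1000,
                      tol = 1e-7) {
  y <- as.numeric(y)
  W <- as.matrix(W)
  if (anyNA(y) || anyNA(W)) stopf("missing data not allowed")
  n <- length(y)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (n > ncol(W)) 1e-4 else 0.01
  sds <- apply(W, 2, sd)
  dropped <- colnames(W)[sds == 0]
  if (length(dropped)) {
    warnf("dropping %d zero-variance column(s)", length(dropped))
    W <- W[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(W) == 0) stopf("no usable columns")
  mus <- colMeans(W)
  Ws <- sweep(sweep(W, 2, mus), 2, sds, "/")
  ybar <- mean(y)
  yc <- y - ybar
  lambda_max <- max(abs(crossprod(Ws, yc))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))

  # inner CV over the grid
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(inner_cv_folds), n))
  mse <- matrix(NA_real_, inner_cv_folds, n_lambda)
  for (f in seq_len(inner_cv_folds)) {
    tr <- fold != f
    path <- lasso_path(yc[tr], Ws[tr, , drop = FALSE], grid, max_iter, tol)
    pred <- Ws[!tr, , drop = FALSE] %*% path  # n_test x n_lambda
    mse[f, ] <- colMeans((yc[!tr] - pred)^2)
  }
  cv_mse <- colMeans(mse)
  best <- which.min(cv_mse)
  path <- lasso_path(yc, Ws, grid, max_iter, tol)
  b_std <- path[, best]
  effects <- b_std / sds
  mu <- ybar - sum(effects * mus)
  structure(list(mu = mu, effects = setNames(effects, colnames(W)),
                 lambda = grid[best], lambda_grid = grid, cv_mse = cv_mse,
                 fitted = mu + drop(W %*% effects), dropped = dropped),
            class = "lasso_fit")
}

# Covariance-update coordinate descent over a decreasing lambda grid with
# warm starts (compiled inner loop). X must be standardised, y centered.
# Returns p x n_lambda.
lasso_path <- function(y, X, grid, max_iter, tol) {
  n <- length(y)
  Xty <- drop(crossprod(X, y)) / n
  XtX <- crossprod(X) / n
  .lasso_path_cd(Xty, XtX, as.numeric(grid), as.integer(max_iter), tol)
}

#' @param object a `lasso_fit`.
#' @param W_new marker matrix for new individuals.
#' @param ... unused.
#' @rdname lasso_fit
#' @export
predict.lasso_fit <- function(object, W_new, ...) {
  W_new <- as.matrix(W_new)
  if (!is.null(colnames(W_new)) && !is.null(names(object$effects)))
    W_new <- W_new[, names(object$effects), drop = FALSE]
  object$mu + drop(W_new %*% object$effects)
}

#' @export
#' @method print lasso_fit
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> %d markers, %d non-zero at lambda = %.5f\n",
              length(x$effects), sum(x$effects != 0), x$lambda))
  invisible(x)
}
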