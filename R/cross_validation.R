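#' Repeated k-fold cross-validation of a genomic prediction model
#'
#' Random (stratification-free) folds are re-drawn for every repeat. Within
#' a repeat, held-out predictions from all folds are pooled and a single
#' Pearson correlation with the observed values is reported, so each repeat
#' yields one accuracy; mean and sd are taken over repeats. A repeat whose
#' observed vector is constant (zero variance) is flagged and excluded from
#' the mean.
#'
#' @param y observed values.
#' @param fit_predict function `(train_idx, test_idx) -> predictions for
#'   test_idx`, closing over the genotypes/model of interest.
#' @param folds number of folds (default 5).
#' @param repeats number of repeats (default 20).
#' @param seed seed for fold assignment; the same seed reproduces the exact
#'   same folds and result.
#' @return object of class `cv_result`: `per_repeat` (data.frame: repeat,
#'   accuracy, flagged), `mean`, `sd`, `folds`, `repeats`, `seed`.
#' @export
cross_validate <- function(y, fit_predict, folds = 5, repeats = 20, seed = 1) {
  n <- length(y)
  if (n < folds) stopf("fewer observations (%d) than folds (%d)", n, folds)
  rep_seeds <- derive_seeds(seed, repeats)
  acc <- numeric(repeats)
  flagged <- logical(repeats)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      pred[test] <- fit_predict(train, test)
    }
    if (sd(y) == 0 || sd(pred) == 0) {
      flagged[r] <- TRUE
      acc[r] <- NA_real_
    } else {
      acc[r] <- cor(y, pred)
    }
  }
  structure(list(per_repeat = data.frame(repeat_ = seq_len(repeats),
                                         accuracy = acc, flagged = flagged),
                 mean = mean(acc[!flagged]), sd = sd(acc[!flagged]),
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repeats: accuracy %.3f +/- %.3f\n",
              x$folds, x$repeats, x$mean, x$sd))
  invisible(x)
}

#' Cross-validate hybrid prediction for the three GS models
#'
#' Convenience wrappers around [cross_validate()] with fold assignment at
#' the hybrid level. `cv_gblup` refits the additive+dominance REML model in
#' every fold; `cv_bayesb` and `cv_lasso` regress on the column-bound
#' additive and dominance codings.
#'
#' @param y hybrid phenotypes aligned with `coding`.
#' @param coding a [infer_hybrid_genotypes()] result.
#' @param folds,repeats,seed see [cross_validate()].
#' @param ... passed to the underlying fitter.
#' @return a `cv_result`.
#' @export
cv_gblup <- function(y, coding, folds = 5, repeats = 20, seed = 1, ...) {
  cross_validate(y, function(train, test) {
    tr_coding <- coding_rows(coding, train)
    fit <- gblup_fit(y[train], tr_coding, ...)
    predict(fit, coding_rows(coding, test))
  }, folds, repeats, seed)
}

#' @rdname cv_gblup
#' @param config an [mcmc_config()] for the BayesB sampler.
#' @export
cv_bayesb <- function(y, coding, folds = 5, repeats = 20, seed = 1,
                      config = mcmc_config(n_iter = 3000, burn_in = 1000)) {
  W <- coding_design(coding)
  cross_validate(y, function(train, test) {
    fit <- bayesb_fit(y[train], W[train, , drop = FALSE], config)
    predict(fit, W[test, , drop = FALSE])
  }, folds, repeats, seed)
}

#' @rdname cv_gblup
#' @export
cv_lasso <- function(y, coding, folds = 5, repeats = 20, seed = 1, ...) {
  W <- coding_design(coding)
  cross_validate(y, function(train, test) {
    fit <- suppressWarnings(lasso_fit(y[train], W[train, , drop = FALSE], ...))
    predict(fit, W[test, , drop = FALSE])
  }, folds, repeats, seed)
}

#' Column-bound additive + dominance design with unique column names
#' @noRd
coding_design <- function(coding) {
  W <- cbind(coding$Za, coding$Zd)
  colnames(W) <- c(paste0("a_", coding$markers), paste0("d_", coding$markers))
  W
}

#' Row subset of a hybrid coding
#' @noRd
coding_rows <- function(coding, idx) {
  coding$Za <- coding$Za[idx, , drop = FALSE]
  coding$Zd <- coding$Zd[idx, , drop = FALSE]
  coding$hybrid <- coding$hybrid[idx]
  coding$parents <- coding$parents[idx, , drop = FALSE]
  coding
}
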