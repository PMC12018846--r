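# Independent oracle: mixed-model-equation ridge on the markers. With
# K = W W'/m and per-marker variance phi^2/m, solving
# [W'W + ve D^-1] u = W'(y - X beta) reproduces kernel BLUP exactly.
ridge_oracle <- function(y, Wa, Wd = NULL, va, vd = 0, ve,
                         Wa_new = NULL, Wd_new = NULL) {
  n <- length(y)
  m <- ncol(Wa)
  W <- if (is.null(Wd)) Wa else cbind(Wa, Wd)
  pen <- if (is.null(Wd)) rep(m * ve / va, m)
         else c(rep(m * ve / va, m), rep(m * ve / vd, m))
  K <- tcrossprod(Wa) * (va / m) + (if (is.null(Wd)) 0 else
    tcrossprod(Wd) * (vd / m))
  V <- K + diag(ve, n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  beta <- drop(solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y)))
  u <- solve(crossprod(W) + diag(pen), crossprod(W, y - X %*% beta))
  W_pred <- if (is.null(Wa_new)) W else if (is.null(Wd)) Wa_new
            else cbind(Wa_new, Wd_new)
  list(beta = beta, pred = unname(beta + drop(W_pred %*% u)),
       Py = drop(Vi %*% (y - X %*% beta)))
}

coding_rows_test <- function(coding, idx) {
  coding$Za <- coding$Za[idx, , drop = FALSE]
  coding$Zd <- coding$Zd[idx, , drop = FALSE]
  coding$hybrid <- coding$hybrid[idx]
  coding$parents <- coding$parents[idx, , drop = FALSE]
  coding
}

test_that("kernel GBLUP equals marker ridge to machine precision", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 30; m <- 25
    Wa <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    Wd <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
    Wa <- scale(Wa, scale = FALSE)
    Wd <- scale(Wd, scale = FALSE)
    y <- rnorm(n)
    va <- runif(1, 0.5, 3); vd <- runif(1, 0.2, 2); ve <- runif(1, 0.5, 2)
    Ka <- tcrossprod(Wa) / m
    Kd <- tcrossprod(Wd) / m
    orc <- ridge_oracle(y, Wa, Wd, va, vd, ve)
    kern <- drop(orc$beta + (va * Ka + vd * Kd) %*% orc$Py)
    expect_equal(kern, orc$pred, tolerance = 1e-8)
  }
})

test_that("EM-REML recovers planted variance components", {
  set.seed(202)
  pop <- make_population(n_lines = 80, n_snps = 400, n_qtl = 40, seed = 15,
                         n_crosses = 500)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  kin <- kinship_pair(coding)
  # normalise each kernel to unit mean diagonal so the planted components
  # are on a comparable, well-identified scale
  Ka <- kin$Ka / mean(diag(kin$Ka))
  Kd <- kin$Kd / mean(diag(kin$Kd))
  va <- 2; vd <- 0.5; ve <- 1
  La <- chol(Ka + diag(1e-8, 500))
  Ld <- chol(Kd + diag(1e-8, 500))
  y <- 5 + sqrt(va) * drop(crossprod(La, rnorm(500))) +
    sqrt(vd) * drop(crossprod(Ld, rnorm(500))) + rnorm(500, 0, sqrt(ve))
  fit <- reml_fit(y, Ka, Kd, max_iter = 2000)
  expect_true(fit$converged)
  expect_lt(abs(fit$varcomp[["va"]] - va), 3 * fit$se[1])
  expect_lt(abs(fit$varcomp[["vd"]] - vd), 3 * fit$se[2])
  expect_lt(abs(fit$varcomp[["ve"]] - ve), 3 * fit$se[3])
})

test_that("EM-REML log-likelihood is monotone non-decreasing", {
  set.seed(303)
  pop <- make_population(n_lines = 30, n_snps = 150, n_qtl = 15, seed = 21,
                         n_crosses = 80)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  kin <- kinship_pair(coding)
  fit2 <- reml_fit(pop$trait$hybrid$phenotype, kin$Ka, kin$Kd)
  expect_true(all(diff(fit2$loglik_trace) > -1e-8))
  fit1 <- reml_fit(pop$trait$hybrid$phenotype, kin$Ka)
  expect_true(all(diff(fit1$loglik_trace) > -1e-8))
})

test_that("a zero dominance kernel reproduces the additive-only fit", {
  set.seed(404)
  pop <- make_population(n_lines = 40, n_snps = 200, n_qtl = 20, seed = 33,
                         n_crosses = 120)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  kin <- kinship_pair(coding)
  y <- pop$trait$hybrid$phenotype
  f_single <- reml_fit(y, kin$Ka)
  f_zero <- reml_fit(y, kin$Ka, matrix(0, 120, 120))
  expect_equal(f_single$varcomp[["va"]], f_zero$varcomp[["va"]],
               tolerance = 1e-4)
  expect_equal(f_single$varcomp[["ve"]], f_zero$varcomp[["ve"]],
               tolerance = 1e-4)
  expect_equal(f_single$loglik, f_zero$loglik, tolerance = 1e-5)
})

test_that("constant phenotypes drive the genetic variances to zero", {
  pop <- make_population(n_lines = 20, n_snps = 80, n_qtl = 8, seed = 5,
                         n_crosses = 40)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  kin <- kinship_pair(coding)
  fit <- reml_fit(rep(3, 40), kin$Ka, kin$Kd)
  expect_lt(fit$varcomp[["va"]], 1e-6)
  expect_lt(fit$varcomp[["vd"]], 1e-6)
})

test_that("reml_fit rejects malformed inputs", {
  K <- diag(12)
  expect_error(reml_fit(c(rnorm(11), NA), K), "non-finite")
  expect_error(reml_fit(rnorm(12), K, X = matrix(1, 12, 2)), "singular")
  expect_error(reml_fit(rnorm(5), diag(5)), "at least 10")
})

test_that("GBLUP interpolates a training individual as noise vanishes", {
  set.seed(505)
  pop <- make_population(n_lines = 30, n_snps = 150, n_qtl = 15, h2 = 0.95,
                         seed = 17, n_crosses = 100)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  y <- pop$trait$hybrid$genetic_value  # noiseless
  fit <- gblup_fit(y, coding)
  # a duplicated training hybrid must be predicted back almost exactly
  pred <- predict(fit, coding_rows_test(coding, 1:10))
  expect_gt(cor(pred, y[1:10]), 0.99)
  expect_lt(mean(abs(pred - y[1:10])) / sd(y), 0.1)
})

test_that("gblup_fit predictions match the ridge oracle on new hybrids", {
  set.seed(606)
  pop <- make_population(n_lines = 30, n_snps = 100, n_qtl = 10, seed = 19,
                         n_crosses = 80)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  y <- pop$trait$hybrid$phenotype
  fit <- gblup_fit(y, coding)
  new_plan <- data.frame(parent1 = lines_of(pop$geno)[1:5],
                         parent2 = lines_of(pop$geno)[26:30])
  new_coding <- infer_hybrid_genotypes(pop$geno, new_plan)
  Wa <- sweep(coding$Za, 2, 2 * fit$freqs)
  Wd <- sweep(coding$Zd, 2, fit$dmeans)
  Wa_new <- sweep(new_coding$Za, 2, 2 * fit$freqs)
  Wd_new <- sweep(new_coding$Zd, 2, fit$dmeans)
  orc <- ridge_oracle(y, Wa, Wd, fit$varcomp[["va"]], fit$varcomp[["vd"]],
                      fit$varcomp[["ve"]], Wa_new, Wd_new)
  expect_equal(unname(predict(fit, new_coding)), orc$pred, tolerance = 1e-6)
})
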