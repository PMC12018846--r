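#' Multi-environment entry BLUPs
#'
#' Fits `value = mean + environment (fixed) + genotype (random) +
#' genotype x environment (random) + residual` by REML (via lme4) on a long
#' replicated trial table and returns one BLUP phenotype per genotype: the
#' average predicted environment mean plus the genotype's random effect.
#' Unbalanced data are allowed; the G x E term is dropped automatically when
#' there is at most one plot per genotype-environment cell (it would be
#' confounded with the residual).
#'
#' Significance: environment is tested with a Wald chi-square on the fixed
#' effects; genotype (and G x E when present) with a REML likelihood-ratio
#' test against the model without that random term.
#'
#' @param data data.frame with columns `genotype`, `env`, `value` (extra
#'   columns such as `rep` are ignored by the model but tolerated).
#' @return object of class `env_blup`: `blup` (named vector, one adjusted
#'   phenotype per genotype), `varcomp`, `tests` (data.frame: term,
#'   statistic, df, p_value), and the fitted `model`.
#' @export
env_blup <- function(data) {
  data <- as.data.frame(data)
  need <- c("genotype", "env", "value")
  if (!all(need %in% names(data)))
    stopf("data must have columns %s", paste(need, collapse = ", "))
  data <- data[!is.na(data$value), , drop = FALSE]
  obs <- table(data$genotype)
  zero <- setdiff(unique(data$genotype), names(obs)[obs > 0])
  if (length(zero))
    warnf("excluding %d genotype(s) with no observed plots", length(zero))
  data$genotype <- factor(data$genotype)
  data$env <- factor(data$env)
  cell <- table(data$genotype, data$env)
  with_gxe <- max(cell) > 1
  form <- if (with_gxe)
    value ~ env + (1 | genotype) + (1 | genotype:env)
  else
    value ~ env + (1 | genotype)
  fit <- lme4::lmer(form, data = data, REML = TRUE)

  # entry BLUP: mean over predicted environment means + genotype effect
  fe <- lme4::fixef(fit)
  env_means <- fe[1] + c(0, fe[-1])
  mu <- mean(env_means)
  u <- lme4::ranef(fit)$genotype
  blup <- setNames(mu + u[[1]], rownames(u))

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, vc$grp)

  # environment: Wald chi-square on the env contrasts
  b <- fe[-1]
  Vb <- as.matrix(vcov(fit))[-1, -1, drop = FALSE]
  w <- if (length(b)) drop(t(b) %*% solve(Vb, b)) else NA_real_
  env_p <- if (length(b)) pchisq(w, df = length(b), lower.tail = FALSE) else NA
  tests <- data.frame(term = "env", statistic = w, df = length(b),
                      p_value = env_p, stringsAsFactors = FALSE)
  # genotype (and GxE): REML LRT
  lrt_row <- function(term, reduced_form) {
    has_re <- length(lme4::findbars(reduced_form)) > 0
    ll0 <- if (has_re)
      as.numeric(logLik(lme4::lmer(reduced_form, data = data, REML = TRUE)))
    else
      as.numeric(logLik(lm(reduced_form, data = data), REML = TRUE))
    stat <- max(0, 2 * (as.numeric(logLik(fit)) - ll0))
    data.frame(term = term, statistic = stat, df = 1,
               p_value = 0.5 * pchisq(stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  tests <- rbind(tests, lrt_row("genotype", if (with_gxe)
    value ~ env + (1 | genotype:env) else value ~ env))
  if (with_gxe)
    tests <- rbind(tests, lrt_row("genotype:env",
                                  value ~ env + (1 | genotype)))
  structure(list(blup = blup, varcomp = varcomp, tests = tests,
                 model = fit, with_gxe = with_gxe),
            class = "env_blup")
}

#' @export
#' @method print env_blup
print.env_blup <- function(x, ...) {
  cat(sprintf("<env_blup> %d genotypes%s\n", length(x$blup),
              if (x$with_gxe) " (with GxE term)" else ""))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
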