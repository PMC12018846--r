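#' Predict every potential single-cross hybrid of a line set
#'
#' Enumerates all `n(n-1)/2` unordered non-self pairs, infers each chunk's
#' additive/dominance coding from the parental genotypes, and predicts it
#' with the trained model. Evaluation is chunked, so peak memory is bounded
#' by `chunk_size` hybrids regardless of the panel size.
#'
#' @param fit a trained [gblup_fit()], [bayesb_fit()] or [lasso_fit()].
#' @param geno parental [geno_matrix()] (post-QC).
#' @param lines line IDs to cross (default: all lines in `geno`).
#' @param chunk_size hybrids per evaluation chunk (default 5000).
#' @return data.frame with columns `hybrid`, `parent1`, `parent2`,
#'   `predicted`.
#' @export
predict_all_hybrids <- function(fit, geno, lines = NULL, chunk_size = 5000) {
  if (!inherits(fit, c("gblup_fit", "bayesb_fit", "lasso_fit")))
    stopf("fit must be a trained gblup, bayesb or lasso model")
  lines <- lines %||% lines_of(geno)
  pairs <- enumerate_potential_hybrids(lines)
  n_pairs <- nrow(pairs)
  starts <- seq(1, n_pairs, by = chunk_size)
  out <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk_size - 1, n_pairs)
    coding <- infer_hybrid_genotypes(geno, pairs[idx, , drop = FALSE])
    pred <- if (inherits(fit, "gblup_fit")) predict(fit, coding)
            else predict(fit, coding_design(coding))
    out[[ci]] <- data.frame(hybrid = coding$hybrid,
                            parent1 = pairs$parent1[idx],
                            parent2 = pairs$parent2[idx],
                            predicted = unname(pred),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genomic estimation of general combining ability (GCA)
#'
#' A line's GCA is its average performance over hybrid combinations: the
#' mean predicted (or observed) value of every hybrid containing the line,
#' minus the grand mean of all supplied hybrids. Over a complete diallel the
#' GCAs therefore sum to exactly zero.
#'
#' @param predictions data.frame with columns `parent1`, `parent2` and a
#'   value column (default `predicted`; pass observed values the same way).
#' @param lines restrict to these lines (default: every parent present).
#' @param value_col name of the value column.
#' @param groups optional named vector line -> heterotic group, recorded in
#'   the output.
#' @return data.frame of class `gca_table`: `line`, `gca`,
#'   `n_combinations`, and `group` when supplied; the all-hybrid grand mean
#'   is attached as attribute `grand_mean`.
#' @export
estimate_gca <- function(predictions, lines = NULL, value_col = "predicted",
                         groups = NULL) {
  predictions <- as.data.frame(predictions)
  if (!value_col %in% names(predictions))
    stopf("no column '%s' in predictions", value_col)
  v <- predictions[[value_col]]
  lines <- lines %||% sort(unique(c(predictions$parent1, predictions$parent2)))
  grand <- mean(v)
  long_line <- c(predictions$parent1, predictions$parent2)
  long_val <- c(v, v)
  keep <- long_line %in% lines
  sums <- tapply(long_val[keep], long_line[keep], sum)
  counts <- tapply(long_val[keep], long_line[keep], length)
  missing_lines <- setdiff(lines, names(sums))
  if (length(missing_lines))
    stopf("line(s) with zero hybrid combinations: %s",
          paste(head(missing_lines, 5), collapse = ", "))
  gca <- sums[lines] / counts[lines] - grand
  out <- data.frame(line = lines, gca = unname(gca),
                    n_combinations = unname(counts[lines]),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) out$group <- unname(groups[lines])
  attr(out, "grand_mean") <- grand
  class(out) <- c("gca_table", "data.frame")
  out
}

#' Heterotic-group summary of GCA with multiple comparisons
#'
#' Per-group mean and sd, one-way ANOVA across groups, and Tukey HSD
#' pairwise comparisons with a compact letter display at the given alpha.
#' Groups with fewer than 2 lines are dropped from the test with a warning.
#'
#' @param gca a [estimate_gca()] table with a `group` column (or pass
#'   `groups`).
#' @param groups optional named vector line -> group overriding the table.
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `summary` (group, n, mean, sd, letter), `anova_f`,
#'   `anova_p`, `tukey` (pairwise table), `alpha`.
#' @export
gca_group_summary <- function(gca, groups = NULL, alpha = 0.05) {
  df <- as.data.frame(gca)
  if (!is.null(groups)) df$group <- unname(groups[df$line])
  if (is.null(df$group)) stopf("no heterotic-group information supplied")
  cnt <- table(df$group)
  small <- names(cnt)[cnt < 2]
  if (length(small))
    warnf("dropping group(s) with < 2 lines from testing: %s",
          paste(small, collapse = ", "))
  test_df <- df[!df$group %in% small, , drop = FALSE]
  agg <- aggregate(gca ~ group, df, function(z) c(n = length(z),
                                                  mean = mean(z), sd = sd(z)))
  summary <- data.frame(group = agg$group, n = agg$gca[, "n"],
                        mean = agg$gca[, "mean"], sd = agg$gca[, "sd"])
  if (length(unique(test_df$group)) < 2) {
    summary$letter <- "a"
    return(list(summary = summary, anova_f = NA_real_, anova_p = NA_real_,
                tukey = NULL, alpha = alpha))
  }
  test_df$group <- factor(test_df$group)
  fit <- aov(gca ~ group, data = test_df)
  an <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  letters <- cld_letters(rownames(tk), tk[, "p adj"], levels(test_df$group),
                         tapply(test_df$gca, test_df$group, mean), alpha)
  summary$letter <- letters[summary$group]
  list(summary = summary, anova_f = an$`F value`[1], anova_p = an$`Pr(>F)`[1],
       tukey = as.data.frame(tk), alpha = alpha)
}

# Compact letter display by insert-and-absorb over the non-significant pairs.
cld_letters <- function(pair_names, p_adj, groups, means, alpha) {
  groups <- names(sort(means, decreasing = TRUE))
  k <- length(groups)
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_along(pair_names)) {
    gs <- strsplit(pair_names[i], "-", fixed = TRUE)[[1]]
    if (!all(gs %in% groups)) next
    if (p_adj[i] < alpha) nsd[gs[1], gs[2]] <- nsd[gs[2], gs[1]] <- FALSE
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (all(nsd[g, sets[[si]]])) {
        sets[[si]] <- c(sets[[si]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  }
  sets <- sets[keep]
  out <- setNames(rep("", k), groups)
  for (si in seq_along(sets)) {
    out[sets[[si]]] <- paste0(out[sets[[si]]], letters[si])
  }
  out
}

#' Cross-validated predictability of GCA from line genotypes
#'
#' Folds partition the *lines* (not the hybrids), so no line contributes to
#' both training and test; the model regresses training-line GCA on the
#' lines' own additive dosages and accuracy is the Pearson correlation on
#' held-out lines.
#'
#' @param gca a [estimate_gca()] table.
#' @param geno [geno_matrix()] of the lines.
#' @param model `"gblup"`, `"bayesb"` or `"lasso"`.
#' @param folds,repeats,seed see [cross_validate()].
#' @param config [mcmc_config()] for BayesB.
#' @return a `cv_result`.
#' @export
gca_cv <- function(gca, geno, model = c("gblup", "bayesb", "lasso"),
                   folds = 5, repeats = 20, seed = 1,
                   config = mcmc_config(n_iter = 3000, burn_in = 1000)) {
  model <- match.arg(model)
  df <- as.data.frame(gca)
  if (!all(df$line %in% lines_of(geno)))
    stopf("GCA table contains lines missing from the genotype panel")
  if (nrow(df) < folds) stopf("fewer lines than folds")
  X <- geno$dosage[df$line, , drop = FALSE]
  y <- df$gca
  fitter <- switch(model,
    gblup = function(train, test) {
      kin <- additive_kinship(X[train, , drop = FALSE])
      fit <- reml_fit(y[train], kin$K)
      W_tr <- sweep(X[train, , drop = FALSE], 2, 2 * kin$freqs)
      W_te <- sweep(X[test, , drop = FALSE], 2, 2 * kin$freqs)
      Kts <- tcrossprod(W_te, W_tr) / kin$m
      gblup_predict(fit, Kts)
    },
    bayesb = function(train, test) {
      fit <- bayesb_fit(y[train], X[train, , drop = FALSE], config)
      predict(fit, X[test, , drop = FALSE])
    },
    lasso = function(train, test) {
      fit <- suppressWarnings(lasso_fit(y[train], X[train, , drop = FALSE]))
      predict(fit, X[test, , drop = FALSE])
    })
  cross_validate(y, fitter, folds, repeats, seed)
}

#' Rank parent lines by GCA
#'
#' Deterministic ranking with ties broken lexicographically by line ID.
#' Optionally annotates each line with membership of the parents of
#' supplied top/bottom hybrid sets (as in a selection audit).
#'
#' @param gca a [estimate_gca()] table.
#' @param direction `"desc"` (larger GCA is better, default) or `"asc"`.
#' @param top_hybrids,bottom_hybrids optional data.frames with `parent1`,
#'   `parent2` columns.
#' @return the table sorted by rank with columns `rank`, `in_top`,
#'   `in_bottom` (the last two only when the hybrid sets are given).
#' @export
rank_parents <- function(gca, direction = c("desc", "asc"),
                         top_hybrids = NULL, bottom_hybrids = NULL) {
  direction <- match.arg(direction)
  df <- as.data.frame(gca)
  ord <- order(if (direction == "desc") -df$gca else df$gca, df$line)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (!is.null(top_hybrids))
    df$in_top <- df$line %in% c(top_hybrids$parent1, top_hybrids$parent2)
  if (!is.null(bottom_hybrids))
    df$in_bottom <- df$line %in% c(bottom_hybrids$parent1,
                                   bottom_hybrids$parent2)
  rownames(df) <- NULL
  df
}

#' Write a GCA table as TSV
#' @param gca a [estimate_gca()] table.
#' @param path file path.
#' @export
write_gca <- function(gca, path) {
  data.table::fwrite(as.data.frame(gca), path, sep = "\t", quote = FALSE)
  invisible(path)
}
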