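# Brute-force GCA oracle: mean value of the hybrids containing each line
# minus the grand mean, computed with plain loops.
gca_oracle <- function(pred) {
  lines <- sort(unique(c(pred$parent1, pred$parent2)))
  grand <- mean(pred$predicted)
  sapply(lines, function(ln) {
    sel <- pred$parent1 == ln | pred$parent2 == ln
    mean(pred$predicted[sel]) - grand
  })
}

test_that("complete-diallel GCA sums to zero and matches the brute-force oracle", {
  set.seed(71)
  lines <- paste0("L", 1:8)
  pairs <- enumerate_potential_hybrids(lines)
  pairs$predicted <- rnorm(nrow(pairs))
  gca <- estimate_gca(pairs)
  expect_equal(sum(gca$gca), 0, tolerance = 1e-12)
  expect_equal(setNames(gca$gca, gca$line), gca_oracle(pairs),
               tolerance = 1e-12)
  expect_true(all(gca$n_combinations == 7))
  # all-equal predictions give all-zero GCA
  pairs$predicted <- 5
  expect_true(all(estimate_gca(pairs)$gca == 0))
})

test_that("noiseless additive complete diallel recovers true GCA exactly", {
  cfg <- sim_config(n_lines = 30, n_snps = 150, n_qtl = 15,
                    dominance_ratio = 0, seed = 73)
  sim <- sim_genotypes(cfg)
  pairs <- enumerate_potential_hybrids(lines_of(sim$genotypes))
  trait <- sim_trait(sim, pairs, cfg)
  pred <- data.frame(parent1 = pairs$parent1, parent2 = pairs$parent2,
                     predicted = trait$hybrid$genetic_value)
  gca <- estimate_gca(pred)
  expect_equal(setNames(gca$gca, gca$line), trait$true_gca[gca$line],
               tolerance = 1e-10)
  expect_gt(cor(gca$gca, trait$true_gca[gca$line]), 0.999999)
})

test_that("GCA matches the Griffing method-4 moment estimator up to scaling", {
  # For a complete diallel without parents/reciprocals the textbook
  # estimator is g_i = [n ybar_i. - 2 ybar..] * n/(n-2) in deviation form;
  # our average-performance GCA is its (n-2)/n multiple, so the two agree
  # after rescaling and both sum to zero.
  set.seed(75)
  lines <- paste0("P", 1:6)
  pairs <- enumerate_potential_hybrids(lines)
  pairs$predicted <- rnorm(15, mean = 100, sd = 10)
  n <- 6
  gca <- estimate_gca(pairs)
  ydd <- mean(pairs$predicted)
  griffing <- sapply(lines, function(ln) {
    sel <- pairs$parent1 == ln | pairs$parent2 == ln
    ybar_i <- mean(pairs$predicted[sel])
    (n - 1) / (n - 2) * (ybar_i - ydd)
  })
  expect_equal(setNames(gca$gca, gca$line) * (n - 1) / (n - 2), griffing,
               tolerance = 1e-12)
  expect_equal(sum(griffing), 0, tolerance = 1e-10)
})

test_that("estimate_gca errors for lines without combinations", {
  pairs <- data.frame(parent1 = "A", parent2 = "B", predicted = 1)
  expect_error(estimate_gca(pairs, lines = c("A", "B", "C")),
               "zero hybrid combinations")
})

test_that("group summary detects shifted group means and handles edge cases", {
  set.seed(77)
  gca <- data.frame(line = sprintf("L%03d", 1:90),
                    gca = c(rnorm(30, 0), rnorm(30, 1), rnorm(30, 2)))
  groups <- setNames(rep(c("HG1", "HG2", "HG3"), each = 30), gca$line)
  res <- gca_group_summary(gca, groups)
  expect_lt(res$anova_p, 0.05)
  expect_equal(nrow(res$summary), 3)
  expect_true(all(nchar(res$summary$letter) >= 1))
  # clearly separated extremes get different letters
  expect_false(res$summary$letter[res$summary$group == "HG1"] ==
                 res$summary$letter[res$summary$group == "HG3"])
  single <- gca_group_summary(gca[1:30, ], groups[1:30])
  expect_true(is.na(single$anova_p))
})

test_that("group-mean test keeps its type-I error under the null", {
  set.seed(79)
  reps <- 200
  pvals <- replicate(reps, {
    gca <- data.frame(line = sprintf("L%02d", 1:40), gca = rnorm(40))
    groups <- setNames(rep(c("A", "B"), each = 20), gca$line)
    gca_group_summary(gca, groups)$anova_p
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("line-level GCA cross-validation recovers a noiseless additive signal", {
  # with unlinked markers, held-out-line accuracy is capped by relatedness;
  # a structured panel (fst 0.4) and a dense trait make GCA highly (not
  # perfectly) predictable from line genotypes alone
  set.seed(81)
  cfg <- sim_config(n_lines = 200, n_snps = 1000, n_qtl = 1000, fst = 0.4,
                    dominance_ratio = 0, seed = 83)
  sim <- sim_genotypes(cfg)
  pairs <- enumerate_potential_hybrids(lines_of(sim$genotypes))
  trait <- sim_trait(sim, pairs, cfg)
  gca <- data.frame(line = names(trait$true_gca), gca = trait$true_gca)
  res <- gca_cv(gca, sim$genotypes, model = "gblup", folds = 5, repeats = 2,
                seed = 85)
  expect_gt(res$mean, 0.8)
})

test_that("permuted GCA labels show no positive leakage and seeds reproduce", {
  # pooled CV correlation under the null is slightly negative (held-out
  # folds are anti-correlated with training means); any clearly positive
  # mean would indicate information leaking through the folds
  set.seed(87)
  cfg <- sim_config(n_lines = 60, n_snps = 200, n_qtl = 20, seed = 89)
  sim <- sim_genotypes(cfg)
  gca <- data.frame(line = lines_of(sim$genotypes), gca = rnorm(60))
  r1 <- gca_cv(gca, sim$genotypes, folds = 5, repeats = 5, seed = 7)
  expect_lt(r1$mean, 0.1)
  expect_gt(r1$mean, -0.5)
  r2 <- gca_cv(gca, sim$genotypes, folds = 5, repeats = 5, seed = 7)
  expect_identical(r1$per_repeat, r2$per_repeat)
})

test_that("rank_parents is deterministic, tie-stable and antisymmetric", {
  gca <- data.frame(line = c("B", "A", "C"), gca = c(1, 1, 2))
  up <- rank_parents(gca, "desc")
  expect_equal(up$line, c("C", "A", "B"))  # tie broken lexicographically
  distinct <- data.frame(line = c("B", "A", "C"), gca = c(1, 3, 2))
  expect_equal(rank_parents(distinct, "asc")$line,
               rev(rank_parents(distinct, "desc")$line))
  all_equal <- data.frame(line = c("b", "c", "a"), gca = c(1, 1, 1))
  expect_equal(rank_parents(all_equal)$line, c("a", "b", "c"))
  expect_error(rank_parents(gca, "sideways"))
})

test_that("parents of top hybrids rank high in GCA on simulated data", {
  pop <- make_population(n_lines = 60, n_snps = 300, n_qtl = 30, seed = 91,
                         n_crosses = 250)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  fit <- gblup_fit(pop$trait$hybrid$phenotype, coding)
  pred <- predict_all_hybrids(fit, pop$geno)
  gca <- estimate_gca(pred, groups = pop$groups)
  sel <- select_extremes(pred, k_top = 100, k_bottom = 100)
  ranked <- rank_parents(gca, "desc", top_hybrids = sel$top,
                         bottom_hybrids = sel$bottom)
  top_ranks <- ranked$rank[ranked$in_top]
  expect_lt(mean(top_ranks), nrow(ranked) / 3)  # top tertile on average
})

test_that("predicted hybrid values decompose into GCA parts as dominance vanishes", {
  cfg <- sim_config(n_lines = 40, n_snps = 200, n_qtl = 20,
                    dominance_ratio = 0, seed = 93)
  sim <- sim_genotypes(cfg)
  pairs <- enumerate_potential_hybrids(lines_of(sim$genotypes))
  trait <- sim_trait(sim, pairs, cfg)
  pred <- data.frame(parent1 = pairs$parent1, parent2 = pairs$parent2,
                     predicted = trait$hybrid$genetic_value)
  gca <- estimate_gca(pred)
  n <- 40
  # Griffing scaling (n-1)/(n-2) makes the additive decomposition exact
  g <- setNames(gca$gca, gca$line) * (n - 1) / (n - 2)
  mu <- attr(gca, "grand_mean")
  sca_resid <- pred$predicted - (mu + g[pred$parent1] + g[pred$parent2])
  expect_lt(var(sca_resid) / var(pred$predicted), 1e-10)
  # the unscaled average-performance GCA leaves only an O(1/n^2) residual
  g0 <- setNames(gca$gca, gca$line)
  resid0 <- pred$predicted - (mu + g0[pred$parent1] + g0[pred$parent2])
  expect_lt(var(resid0) / var(pred$predicted), 4 / (n - 2)^2)
})

test_that("predict_all_hybrids enumerates all pairs and is chunk-invariant", {
  pop <- make_population(n_lines = 25, n_snps = 100, n_qtl = 10, seed = 95,
                         n_crosses = 60)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  fit <- gblup_fit(pop$trait$hybrid$phenotype, coding)
  p1 <- predict_all_hybrids(fit, pop$geno, chunk_size = 37)
  p2 <- predict_all_hybrids(fit, pop$geno, chunk_size = 5000)
  expect_equal(nrow(p1), 300)
  expect_equal(p1, p2)
  # identical genotypes give identical predictions against any partner
  d <- pop$geno$dosage
  d["L002", ] <- d["L001", ]
  gdup <- geno_matrix(d, pop$geno$map)
  pd <- predict_all_hybrids(fit, gdup)
  pred_1 <- pd$predicted[pd$parent1 == "L001" & pd$parent2 == "L010"]
  pred_2 <- pd$predicted[pd$parent1 == "L002" & pd$parent2 == "L010"]
  expect_equal(pred_1, pred_2, tolerance = 1e-12)
  # training hybrids are reproduced by in-sample fit
  tr_pred <- predict(fit, coding)
  expect_gt(cor(tr_pred, fit$fitted), 0.99)
})
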