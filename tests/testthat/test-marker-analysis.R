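test_that("the marker-based significance threshold is log10(m)", {
  expect_equal(round(significance_threshold(108541), 3), 5.036)
  expect_equal(significance_threshold(1000), 3)
  expect_equal(significance_threshold(10), 1)
  expect_error(significance_threshold(0), "count")
})

test_that("the association scan finds a strong QTL and calibrates under the null", {
  set.seed(61)
  cfg <- sim_config(n_lines = 400, n_snps = 300, n_groups = 4, n_qtl = 10,
                    seed = 63)
  sim <- sim_genotypes(cfg)
  x <- sim$genotypes$dosage[, 150]
  g <- x * 1  # QTL explaining ~10% of variance
  y <- g + rnorm(400, 0, sqrt(var(g) * 9))
  tab <- assoc_scan(y, sim$genotypes, n_pcs = 3)
  thr <- significance_threshold(300)
  expect_gt(tab$score[150], thr)
  # permuted phenotype: the -log10(1/m) threshold admits about one false
  # positive per scan (m * 10^-log10(m) = 1), so hits ~ Poisson(1)
  hits <- replicate(20, {
    tabp <- assoc_scan(sample(y), sim$genotypes, n_pcs = 3)
    sum(tabp$score >= thr)
  })
  expect_lt(mean(hits), 2.5)
  expect_gt(mean(hits == 0), 0.1)
})

test_that("zero PCs reduces the scan to simple regression p-values", {
  set.seed(65)
  cfg <- sim_config(n_lines = 100, n_snps = 50, n_qtl = 5, seed = 67)
  sim <- sim_genotypes(cfg)
  y <- rnorm(100)
  tab <- assoc_scan(y, sim$genotypes, n_pcs = 0)
  p_lm <- vapply(1:50, function(j) {
    x <- sim$genotypes$dosage[, j]
    if (var(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients[2, 4]
  }, numeric(1))
  ok <- !is.na(p_lm)
  expect_equal(tab$score[ok], -log10(p_lm[ok]), tolerance = 1e-8)
  expect_true(all(tab$score[!ok] == 0))
})

test_that("consensus requires the stated number of distinct methods", {
  mk <- function(method, snps) {
    k <- length(snps)
    data.frame(snp = snps, trait = rep("EW", k), target = rep("gca", k),
               method = rep(method, k), score = rep(6, k),
               score_type = rep("neglog10p", k))
  }
  tables <- list(mk("m1", c("s1", "s2", "s3")),
                 mk("m2", c("s2", "s3", "s4")),
                 mk("m3", c("s3", "s5")))
  expect_setequal(consensus_snps(tables, 1), paste0("s", 1:5))
  expect_setequal(consensus_snps(tables, 2), c("s2", "s3"))
  expect_setequal(consensus_snps(tables, 3), "s3")
  expect_error(consensus_snps(tables, 4), "exceeds")
  expect_equal(consensus_snps(list(mk("m1", character(0))), 1), character(0))
  # nesting invariant
  expect_true(all(consensus_snps(tables, 3) %in% consensus_snps(tables, 2)))
  expect_true(all(consensus_snps(tables, 2) %in% consensus_snps(tables, 1)))
})

test_that("thresholding honours each method's own rule and commutes with consensus", {
  tab <- data.frame(snp = paste0("s", 1:4), trait = "EW", target = "gca",
                    method = c("p1", "p1", "lod1", "lod1"),
                    score = c(5.1, 4.9, 3.2, 2.8),
                    score_type = c("neglog10p", "neglog10p", "lod", "lod"))
  kept <- threshold_associations(tab, m = 108541)
  expect_setequal(kept$snp, c("s1", "s3"))
  # thresholding before or after pooling gives the same consensus
  t1 <- consensus_snps(threshold_associations(tab, 108541), 1)
  t2 <- consensus_snps(list(threshold_associations(tab[1:2, ], 108541),
                            threshold_associations(tab[3:4, ], 108541)), 1)
  expect_setequal(t1, t2)
})

test_that("the nine marker sets have the right schema, sizes and determinism", {
  all_snps <- sprintf("snp%03d", 1:200)
  sets <- build_marker_sets(gca_snp1 = all_snps[1:20],
                            gca_snp2 = all_snps[1:7],
                            trait_snp1 = all_snps[30:60],
                            trait_snp2 = all_snps[30:40],
                            all_snps = all_snps, seed = 11)
  expect_setequal(names(sets),
                  c("All", "GCA_SNP1", "GCA_SNP2", "Trait_SNP1",
                    "Trait_SNP2", "Rnd_GCA_SNP1", "Rnd_GCA_SNP2",
                    "Rnd_Trait_SNP1", "Rnd_Trait_SNP2"))
  expect_equal(length(sets$Rnd_GCA_SNP1), length(sets$GCA_SNP1))
  expect_equal(length(sets$Rnd_Trait_SNP2), length(sets$Trait_SNP2))
  sets2 <- build_marker_sets(all_snps[1:20], all_snps[1:7],
                             all_snps[30:60], all_snps[30:40],
                             all_snps, seed = 11)
  expect_identical(sets, sets2)
  expect_warning(build_marker_sets(character(0), all_snps[1:3],
                                   all_snps[5:8], all_snps[9:10],
                                   all_snps, seed = 1),
                 "empty reference")
})

test_that("the full-panel marker set reproduces the plain GBLUP prediction", {
  pop <- make_population(n_lines = 30, n_snps = 120, n_qtl = 12, seed = 97,
                         n_crosses = 100)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  y <- pop$trait$hybrid$phenotype
  tr_idx <- 1:80
  te_idx <- 81:100
  tr <- spdc:::coding_rows(coding, tr_idx)
  te <- spdc:::coding_rows(coding, te_idx)
  sets <- list(All = colnames(pop$geno$dosage))
  res <- evaluate_marker_sets(sets, tr, te, y[tr_idx], y[te_idx],
                              model = "gblup")
  direct <- predict(gblup_fit(y[tr_idx], tr), te)
  expect_equal(res$accuracy, cor(y[te_idx], direct), tolerance = 1e-10)
  expect_error(evaluate_marker_sets(list(Empty = character(0)), tr, te,
                                    y[tr_idx], y[te_idx]), "empty")
  expect_error(evaluate_marker_sets(sets, tr, tr, y[tr_idx], y[tr_idx]),
               "disjoint")
})

test_that("superior genotypes are definitional and direction-sensitive", {
  vals <- c(a = 1, b = 1.2, c = 5, d = 5.5, e = 1.1, f = 5.2,
            g = 0.9, h = 5.1, i = 1.05, j = 5.3)
  geno <- matrix(c(0, 0, 2, 2, 0, 2, 0, 2, 0, 2), 10, 1,
                 dimnames = list(names(vals), "s1"))
  res <- superior_genotypes("s1", vals, geno, direction = "higher",
                            min_class_size = 2)
  expect_equal(res$superior$superior_class, 2)
  res_low <- superior_genotypes("s1", vals, geno, direction = "lower",
                                min_class_size = 2)
  expect_equal(res_low$superior$superior_class, 0)
  # counts flip with direction
  expect_equal(unname(res$counts + res_low$counts), rep(1, 10))
  mono <- matrix(0, 10, 1, dimnames = list(names(vals), "s2"))
  expect_error(suppressWarnings(superior_genotypes("s2", vals, mono)),
               "no SNP")
})

test_that("favourable-allele accumulation separates top and bottom hybrids", {
  pop <- make_population(n_lines = 60, n_snps = 300, n_qtl = 30, h2 = 0.7,
                         seed = 99, n_crosses = 250)
  coding <- infer_hybrid_genotypes(pop$geno, pop$plan)
  fit <- gblup_fit(pop$trait$hybrid$phenotype, coding)
  pred <- predict_all_hybrids(fit, pop$geno)
  gca <- estimate_gca(pred)
  gca_vals <- setNames(gca$gca, gca$line)
  # use the true QTL as the "significant SNP" list
  snps <- pop$trait$qtl$marker
  full_pairs <- enumerate_potential_hybrids(lines_of(pop$geno))
  full_coding <- infer_hybrid_genotypes(pop$geno, full_pairs)
  res <- suppressWarnings(superior_genotypes(snps, gca_vals,
                                             pop$geno$dosage,
                                             geno_count = full_coding$Za))
  sel <- select_extremes(pred, 100, 100)
  top_ids <- spdc:::hybrid_id(sel$top$parent1, sel$top$parent2)
  bottom_ids <- spdc:::hybrid_id(sel$bottom$parent1, sel$bottom$parent2)
  expect_gt(mean(res$counts[top_ids]), mean(res$counts[bottom_ids]))
})

test_that("phenotype differs across accumulation counts on QTL-driven data", {
  cfg <- sim_config(n_lines = 45, n_snps = 200, n_qtl = 20, h2 = 0.7,
                    seed = 103)
  sim <- sim_genotypes(cfg)
  pairs <- enumerate_potential_hybrids(lines_of(sim$genotypes))  # 990
  trait <- sim_trait(sim, pairs, cfg)
  coding <- infer_hybrid_genotypes(sim$genotypes, pairs)
  snps <- trait$qtl$marker
  line_vals <- trait$line_value
  res <- suppressWarnings(superior_genotypes(snps, line_vals,
                                             sim$genotypes$dosage,
                                             geno_count = coding$Za))
  counts <- res$counts
  y <- trait$hybrid$phenotype
  an <- anova(aov(y ~ factor(counts)))
  expect_lt(an$`Pr(>F)`[1], 0.01)
  expect_gt(length(y), 900)
})

test_that("SNP type classification follows the decision tree on fixtures", {
  set.seed(105)
  n_i <- 60; n_h <- 90
  geno_i <- matrix(rep(c(0, 2), each = n_i / 2), n_i, 3,
                   dimnames = list(paste0("I", 1:n_i), c("s1", "s2", "s3")))
  geno_h <- matrix(rep(c(0, 1, 2), each = n_h / 3), n_h, 3,
                   dimnames = list(paste0("H", 1:n_h), c("s1", "s2", "s3")))
  base_i <- rnorm(n_i, 0, 0.3)
  base_h <- rnorm(n_h, 0, 0.3)
  # s1: inbred 2 >> 0; hybrid 2 >> 1 >> 0 -> Type I
  vi1 <- base_i + ifelse(geno_i[, 1] == 2, 3, 0)
  vh1 <- base_h + c(`0` = 0, `1` = 2, `2` = 4)[as.character(geno_h[, 1])]
  r1 <- classify_snp_types("s1", vi1, geno_i, vh1, geno_h)
  expect_equal(r1$type, "I")
  # s2: hybrid heterozygote strictly best, homozygotes equal -> Type III
  vh2 <- base_h + ifelse(geno_h[, 2] == 1, 3, 0)
  vi2 <- base_i + ifelse(geno_i[, 2] == 2, 3, 0)
  r2 <- classify_snp_types("s2", vi2, geno_i, vh2, geno_h)
  expect_equal(r2$type, "III")
  # s3: no differences anywhere -> Type V
  r3 <- classify_snp_types("s3", base_i, geno_i, base_h, geno_h)
  expect_equal(r3$type, "V")
})

test_that("Type II and IV capture shared-superior and reversed-homozygote cases", {
  set.seed(107)
  n_i <- 60; n_h <- 90
  geno_i <- matrix(rep(c(0, 2), each = n_i / 2), n_i, 2,
                   dimnames = list(paste0("I", 1:n_i), c("s1", "s2")))
  geno_h <- matrix(rep(c(0, 1, 2), each = n_h / 3), n_h, 2,
                   dimnames = list(paste0("H", 1:n_h), c("s1", "s2")))
  base_i <- rnorm(n_i, 0, 0.3)
  base_h <- rnorm(n_h, 0, 0.3)
  # s1: hybrid het and hom-2 jointly best (2 also superior in inbreds) -> II
  vi1 <- base_i + ifelse(geno_i[, 1] == 2, 3, 0)
  vh1 <- base_h + c(`0` = 0, `1` = 3, `2` = 3)[as.character(geno_h[, 1])]
  r1 <- classify_snp_types("s1", vi1, geno_i, vh1, geno_h)
  expect_equal(r1$type, "II")
  # s2: superior hybrid homozygote opposite to the inbred one -> IV
  vi2 <- base_i + ifelse(geno_i[, 2] == 2, 3, 0)
  vh2 <- base_h + c(`0` = 4, `1` = 2, `2` = 0)[as.character(geno_h[, 2])]
  r2 <- classify_snp_types("s2", vi2, geno_i, vh2, geno_h)
  expect_equal(r2$type, "IV")
})

test_that("association tables round-trip through TSV", {
  tab <- data.frame(snp = c("s1", "s2"), chrom = c("chr1", "chr2"),
                    pos = c(100L, 200L), trait = "EW", target = "gca",
                    method = "lm_pc", score = c(5.2, 0.1),
                    score_type = "neglog10p")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab, path)
  tab2 <- read_association_table(path)
  expect_equal(tab2, tab)
})
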