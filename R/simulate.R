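#' Configuration for the synthetic breeding population
#'
#' Defines the study conditions the simulator emulates: a structured panel of
#' fully homozygous inbred lines in several heterotic groups, biallelic SNPs
#' spread over `n_chromosomes`, and traits controlled by `n_qtl` evenly
#' spaced QTL whose absolute additive effects follow a gamma distribution
#' with random signs; each QTL carries a dominance effect
#' `d = dominance_ratio * |a|` so crosses show heterosis.
#'
#' @param n_lines number of inbred lines.
#' @param n_snps number of biallelic SNPs.
#' @param n_groups number of heterotic groups (default 5).
#' @param n_chromosomes number of chromosomes (default 10).
#' @param fst differentiation between heterotic groups, in (0, 1)
#'   (default 0.2).
#' @param n_qtl number of QTL controlling the trait (default 200).
#' @param h2 target broad-sense heritability of the simulated trait on the
#'   hybrid set, in (0, 1) (default 0.7).
#' @param dominance_ratio magnitude of each QTL dominance effect relative to
#'   its additive effect (default 0.5; 0 gives a purely additive trait).
#' @param effect_shape,effect_scale gamma parameters for |additive effect|
#'   (defaults 1, 1).
#' @param seed master RNG seed; identical config => bit-identical outputs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines, n_snps, n_groups = 5, n_chromosomes = 10,
                       fst = 0.2, n_qtl = 200, h2 = 0.7,
                       dominance_ratio = 0.5, effect_shape = 1,
                       effect_scale = 1, seed = 1) {
  cfg <- list(n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
              n_groups = as.integer(n_groups),
              n_chromosomes = as.integer(n_chromosomes), fst = fst,
              n_qtl = as.integer(n_qtl), h2 = h2,
              dominance_ratio = dominance_ratio,
              effect_shape = effect_shape, effect_scale = effect_scale,
              seed = as.integer(seed))
  if (cfg$n_groups > cfg$n_lines) stopf("more groups than lines")
  if (cfg$fst <= 0 || cfg$fst >= 1) stopf("fst must lie in (0, 1)")
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stopf("h2 must lie in (0, 1)")
  if (cfg$n_qtl > cfg$n_snps) stopf("n_qtl cannot exceed n_snps")
  if (cfg$dominance_ratio < 0) stopf("dominance_ratio must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Write / read a simulation config as YAML
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate a structured panel of homozygous inbred lines
#'
#' Balding-Nichols scheme: each SNP draws an ancestral frequency
#' `p ~ U(0.05, 0.95)`; each heterotic group then draws its own frequency
#' from `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, and every inbred
#' line in that group is homozygous for the allele with that probability, so
#' dosages are in \{0, 2\} with no heterozygotes. Markers are assigned evenly
#' to chromosomes with increasing bp positions (about one SNP per 100 kb).
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [geno_matrix()]) and `groups` (named
#'   character vector line -> heterotic group, near-equal sizes).
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines; m <- config$n_snps; K <- config$n_groups
  sizes <- rep(n %/% K, K) + c(rep(1, n %% K), rep(0, K - n %% K))
  grp <- rep(paste0("HG", seq_len(K)), sizes)
  lines <- sprintf("L%03d", seq_len(n))
  p <- runif(m, 0.05, 0.95)
  shape_mult <- (1 - config$fst) / config$fst
  d <- matrix(0, n, m, dimnames = list(lines, sprintf("snp%05d", seq_len(m))))
  for (k in seq_len(K)) {
    pk <- rbeta(m, p * shape_mult, (1 - p) * shape_mult)
    rows <- which(grp == paste0("HG", k))
    d[rows, ] <- 2 * matrix(rbinom(length(rows) * m, 1, rep(pk, each = length(rows))),
                            length(rows), m)
  }
  per_chr <- ceiling(m / config$n_chromosomes)
  chrom <- as.character(rep(seq_len(config$n_chromosomes), each = per_chr)[seq_len(m)])
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(length(idx) * 100000L, length(idx)))
  }
  map <- data.frame(marker = colnames(d), chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  list(genotypes = geno_matrix(d, map), groups = setNames(grp, lines))
}

#' QTL positions for a simulated trait
#'
#' Evenly spaced marker indices genome-wide: with spacing `s = n_snps /
#' n_qtl`, the q-th QTL sits at index `floor(s / 2) + floor((q - 1) s)`
#' (1-based, clamped to the marker range).
#' @noRd
qtl_indices <- function(n_snps, n_qtl) {
  s <- n_snps / n_qtl
  idx <- floor(s / 2) + floor((seq_len(n_qtl) - 1) * s) + 1L
  pmin(pmax(idx, 1L), n_snps)
}

#' Simulate a QTL-controlled trait over a hybrid set
#'
#' QTL are placed at evenly spaced marker indices; absolute additive effects
#' are drawn from `Gamma(effect_shape, scale = effect_scale)` with
#' independent random signs, and each QTL's dominance effect is
#' `dominance_ratio * |a|`. The genetic value of hybrid (i, j) is
#' `sum_q a_q x_add + d_q x_dom` with `x_add` the mean parental dosage and
#' `x_dom = 1` where the parents differ. The residual variance is calibrated
#' on the realized hybrid set so that `Var(g) / Var(g + e)` matches the
#' target `h2` in expectation, and phenotypes are `g + e`.
#'
#' True GCAs are computed over the complete diallel of all lines in the
#' panel: the mean genetic value of every hybrid containing the line, minus
#' the all-hybrid mean (so they sum to exactly zero).
#'
#' @param sim result of [sim_genotypes()] (or a list with `genotypes`).
#' @param plan a [cross_plan()] (or data.frame with `parent1`, `parent2`)
#'   giving the hybrids to phenotype.
#' @param config the [sim_config()].
#' @return object of class `true_genetics`: list with `qtl` (data.frame:
#'   marker, index, add_effect, dom_effect), `hybrid` (data.frame: hybrid,
#'   parent1, parent2, genetic_value, phenotype), `true_gca` (named vector
#'   over all panel lines), `line_value` (genetic value of each inbred line
#'   itself), `var_e`, `h2_realized`.
#' @export
sim_trait <- function(sim, plan, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- sim$genotypes
  plan <- as.data.frame(plan)
  if (nrow(plan) == 0) stopf("empty hybrid set")
  set.seed(config$seed + 1L)
  m <- ncol(g$dosage)
  qi <- qtl_indices(m, config$n_qtl)
  a <- rgamma(config$n_qtl, shape = config$effect_shape,
              scale = config$effect_scale) *
    sample(c(-1, 1), config$n_qtl, replace = TRUE)
  dd <- config$dominance_ratio * abs(a)
  X <- g$dosage[, qi, drop = FALSE]  # lines x QTL

  gv_pairs <- function(p1, p2) {
    x1 <- X[p1, , drop = FALSE]
    x2 <- X[p2, , drop = FALSE]
    drop(((x1 + x2) / 2) %*% a + ((x1 != x2) * 1) %*% dd)
  }
  gval <- gv_pairs(plan$parent1, plan$parent2)
  var_g <- var(gval)
  var_e <- var_g * (1 - config$h2) / config$h2
  e <- rnorm(nrow(plan), 0, sqrt(var_e))
  pheno <- gval + e

  # true GCA over the complete diallel of the whole panel
  lines <- rownames(X)
  s_add <- drop(X %*% a) / 2
  Gmat <- outer(s_add, s_add, "+")
  for (q in seq_along(qi)) {
    xq <- X[, q]
    Gmat <- Gmat + dd[q] * (outer(xq, xq, "!=") * 1)
  }
  diag(Gmat) <- NA
  grand <- mean(Gmat[upper.tri(Gmat)])
  true_gca <- rowMeans(Gmat, na.rm = TRUE) - grand

  line_value <- drop(X %*% a)  # a line's own genetic value (selfs: no dominance)

  structure(list(
    qtl = data.frame(marker = colnames(g$dosage)[qi], index = qi,
                     add_effect = a, dom_effect = dd,
                     stringsAsFactors = FALSE),
    hybrid = data.frame(hybrid = hybrid_id(plan$parent1, plan$parent2),
                        parent1 = plan$parent1, parent2 = plan$parent2,
                        genetic_value = gval, phenotype = pheno,
                        stringsAsFactors = FALSE),
    true_gca = true_gca,
    line_value = setNames(line_value, lines),
    var_e = var_e,
    h2_realized = var_g / var(pheno)), class = "true_genetics")
}

#' Design-efficiency study: GCA accuracy vs panel and training sizes
#'
#' For every combination of `n_lines_grid` x `n_hybrids_grid` and each
#' replicate: draws that many lines from the simulated panel, samples a
#' sparse partial diallel among them in which every sampled line appears at
#' least once, simulates phenotypes at the config heritability, fits the
#' additive genomic model on the sampled hybrids, estimates the GCA of
#' *every* panel line from the fitted marker effects, and records the
#' correlation with the true GCA of all panel lines.
#'
#' @param config a [sim_config()]; `config$n_lines` must cover the largest
#'   grid value.
#' @param n_lines_grid,n_hybrids_grid integer grids.
#' @param n_reps replicates per cell (default 20).
#' @param between_fraction passed to [generate_spdc_plan()].
#' @return list with `results` (data.frame: n_lines, n_hybrids, rep,
#'   accuracy) and `summary` (mean and sd per cell).
#' @export
sim_design_study <- function(config, n_lines_grid, n_hybrids_grid,
                             n_reps = 20, between_fraction = 0.8) {
  stopifnot(length(n_lines_grid) > 0, length(n_hybrids_grid) > 0)
  if (max(n_lines_grid) > config$n_lines)
    stopf("grid exceeds the %d lines in the config", config$n_lines)
  for (L in n_lines_grid) for (H in n_hybrids_grid) {
    if (H < ceiling(L / 2))
      stopf("infeasible cell: %d hybrids cannot cover %d lines", H, L)
    if (H > L * (L - 1) / 2)
      stopf("infeasible cell: %d hybrids exceed the %d pairs of %d lines",
            H, L * (L - 1) / 2, L)
  }
  sim <- sim_genotypes(config)
  geno <- sim$genotypes
  full_plan <- enumerate_potential_hybrids(lines_of(geno))
  truth <- sim_trait(sim, full_plan, config)
  gv <- setNames(truth$hybrid$genetic_value, truth$hybrid$hybrid)
  var_g <- var(truth$hybrid$genetic_value)
  var_e <- var_g * (1 - config$h2) / config$h2
  X_all <- geno$dosage

  cells <- expand.grid(n_lines = n_lines_grid, n_hybrids = n_hybrids_grid)
  seeds <- matrix(derive_seeds(config$seed + 2L, nrow(cells) * n_reps),
                  nrow(cells), n_reps)
  res <- vector("list", nrow(cells) * n_reps)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    L <- cells$n_lines[ci]; H <- cells$n_hybrids[ci]
    for (r in seq_len(n_reps)) {
      set.seed(seeds[ci, r])
      sel <- sample(lines_of(geno), L)
      plan <- generate_spdc_plan(sim$groups[sel], n_crosses = H,
                                 between_fraction = between_fraction,
                                 seed = seeds[ci, r])
      y <- gv[hybrid_id(plan$parent1, plan$parent2)] +
        rnorm(H, 0, sqrt(var_e))
      coding <- infer_hybrid_genotypes(geno, plan)
      kin <- additive_kinship(coding$Za)
      fit <- reml_fit(unname(y), kin$K)
      # marker-effect view of the additive fit -> GCA of every panel line
      eff <- drop(crossprod(sweep(coding$Za, 2, 2 * kin$freqs), fit$Py)) *
        fit$varcomp[["va"]] / kin$m
      score <- drop(X_all %*% eff) / 2
      est_gca <- score - mean(score)
      k <- k + 1L
      res[[k]] <- data.frame(n_lines = L, n_hybrids = H, rep = r,
                             accuracy = cor(est_gca, truth$true_gca))
    }
  }
  results <- do.call(rbind, res)
  agg <- aggregate(accuracy ~ n_lines + n_hybrids, results,
                   function(z) c(mean = mean(z), sd = sd(z)))
  summary <- data.frame(agg[1:2], mean = agg$accuracy[, "mean"],
                        sd = agg$accuracy[, "sd"])
  list(results = results, summary = summary)
}
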