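# Shared builders for a small but realistic synthetic breeding population.

# Panel + plan + trait in one call; sizes kept small so the full suite stays
# fast while leaving enough signal for the statistical checks.
make_population <- function(n_lines = 60, n_snps = 400, n_qtl = 40,
                            h2 = 0.7, dominance_ratio = 0.5, fst = 0.2,
                            n_crosses = 200, seed = 42) {
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps, n_qtl = n_qtl,
                    h2 = h2, dominance_ratio = dominance_ratio, fst = fst,
                    seed = seed)
  sim <- sim_genotypes(cfg)
  plan <- generate_spdc_plan(sim$groups, n_crosses = n_crosses, seed = seed)
  trait <- sim_trait(sim, plan, cfg)
  list(config = cfg, sim = sim, geno = sim$genotypes, groups = sim$groups,
       plan = plan, trait = trait)
}

# Tiny deterministic inbred panel for hand-computable checks.
toy_geno <- function() {
  d <- rbind(L1 = c(0, 0, 2, 2),
             L2 = c(2, 0, 0, 2),
             L3 = c(0, 2, 2, 0),
             L4 = c(2, 2, 0, 0))
  colnames(d) <- paste0("m", 1:4)
  geno_matrix(d)
}

toy_groups <- function() c(L1 = "A", L2 = "A", L3 = "B", L4 = "B")
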