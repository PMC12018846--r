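---
title: "Genomic hybrid breeding with sparse partial diallel crosses"
author: "spdc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic hybrid breeding with sparse partial diallel crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdc)
```

## The problem

Single-cross hybrid breeding in maize (and other outcrossers) faces a
combinatorial wall: a few hundred inbred parents span tens of thousands of
potential crosses (n parents give n(n-1)/2 hybrids; 266 give 35,245), of
which only a small fraction can ever be made and phenotyped. The workflow
this package implements attacks the problem with three connected ideas:

1. **A sparse partial diallel between heterotic groups.** Instead of a
   complete diallel or a tester design, a randomized sparse subset of
   crosses is realized, mostly between heterotic groups, with every parent
   participating at least once. This one training population supports all
   downstream genomic analyses.
2. **Whole-genome prediction of every potential hybrid.** Hybrid genotypes
   are inferred from their (homozygous) parents, an additive + dominance
   genomic mixed model is trained on the realized crosses, and all
   potential crosses are predicted.
3. **Genomic estimation of general combining ability (GCA).** A parent's
   GCA is its average predicted performance over all its hybrid
   combinations, centered on the all-hybrid mean — turning the predicted
   hybrid space into a parental ranking, and feeding marker-set discovery
   (GWAS consensus), superior-genotype analysis and top-cross selection.

## The model

For hybrid phenotypes $y$ the package fits

$$y = X\beta + Z_a\gamma_a + Z_d\gamma_d + \varepsilon$$

where row $h$ of $Z_a$ holds the expected F1 minor-allele dosage of hybrid
$h$ (the mean of its parents' dosages) and row $h$ of $Z_d$ the per-marker
heterozygosity indicator (1 where the parents differ). Marker effects are
random, $\gamma_a \sim N(0, \tfrac{1}{m}\phi_a^2 I)$ and
$\gamma_d \sim N(0, \tfrac{1}{m}\phi_d^2 I)$ with $m$ the marker count, and
$\varepsilon \sim N(0, I\sigma^2)$.

Rather than fitting $2m$ effects directly, the equivalent kernel form is
used: $u_a \sim N(0, K_a\phi_a^2)$ with $K_a = W_aW_a'/m$ ($W_a$ the
allele-frequency-centered $Z_a$) and $K_d = W_dW_d'/m$ ($W_d$ the
mean-centered $Z_d$). With the $1/m$ divisor the kernel model is *exactly*
marker ridge regression with penalty $m\sigma^2/\phi^2$ — an identity the
test suite checks to 1e-8 — so fitted models convert freely between kernel
form (cheap when hybrids are few) and marker-effect form (cheap when
predicting tens of thousands of new hybrids; `predict_all_hybrids()` uses
it with chunked evaluation, so memory stays bounded).

Variance components are estimated by EM-REML (`reml_fit()`): the classic
fixed-point update
$\phi_k^2 \leftarrow \phi_k^2 + (\phi_k^4/n)\,(y'PK_kPy - \mathrm{tr}(PK_k))$,
which provably never decreases the restricted likelihood (asserted in the
tests at every iteration). Convergence is declared when the log-likelihood
moves by less than 1e-6 (500-iteration cap, reported via the `converged`
flag); components are floored at 1e-10 so kernels stay valid. When only one
kernel is present the model is rotated into its eigenbasis once, after
which each iteration is $O(n)$ — this path makes the design-efficiency
study and line-level GCA cross-validation fast. Asymptotic standard errors
come from the expected information matrix
$\mathcal{I}_{kl} = \tfrac12\mathrm{tr}(PK_kPK_l)$.

Two more predictors complete the trio commonly compared in genomic
selection:

* **BayesB** (`bayesb_fit()`): each marker effect is exactly zero with
  prior probability $\pi$ and otherwise normal with its own variance under
  a scaled-inverse-chi-square prior — the point-mass + inverted-chi-square
  mixture. A compiled Gibbs sampler updates inclusion indicators with the
  effect integrated out, per-marker variances, the intercept and the
  residual variance. Defaults: 10,000 iterations, 2,000 burn-in, thinning
  5, $\pi = 0.95$; the slab scale is set from $\mathrm{var}(y)$ so the
  included markers explain about half the phenotypic variance a priori.
  These are declared package defaults, exposed through `mcmc_config()`.
* **LASSO** (`lasso_fit()`): cyclic coordinate descent with
  soft-thresholding on standardised columns, covariance-form updates in
  compiled code, a 50-point log-spaced lambda grid with warm starts
  (smallest lambda $10^{-4}\lambda_{max}$ when $n > p$, else
  $10^{-2}\lambda_{max}$), and inner 5-fold CV picking the
  minimum-MSE lambda.

### From hybrid predictions to GCA

`estimate_gca()` implements the average-performance definition:
$\widehat{g}_i = \overline{\hat y}_{i\cdot} - \overline{\hat y}_{\cdot\cdot}$
over **all** potential partners (between- and within-group alike), because
the prediction step covers the full enumerated hybrid space before
averaging; selfs are excluded. Over a complete diallel these deviations sum
to exactly zero by construction. The classical Griffing method-4 estimator
is the $(n-1)/(n-2)$ rescaling of this quantity; with purely additive
values the rescaled version reproduces every hybrid as
$\mu + g_i + g_j$ *exactly*, while the average-performance form leaves an
$O(1/n^2)$ remainder — both identities are pinned down in the tests.

Cross-validation conventions matter here and are deliberate:

* Hybrid prediction is cross-validated at the **hybrid** level (5 folds,
  20 repeats by default), pooling each repeat's held-out predictions into a
  single Pearson correlation — one accuracy per repeat, mean ± sd across
  repeats.
* GCA predictability (`gca_cv()`) folds at the **line** level, so a
  held-out line never leaks information through hybrids it parented. Under
  a pure null this pooled scheme is slightly *negative* (held-out folds are
  anti-correlated with their training means — a compositional artifact of
  pooling), which the tests treat as the expected signature of a
  leakage-free engine.

## The synthetic population

`sim_genotypes()` draws structured homozygous inbred panels under a
Balding–Nichols model: per SNP an ancestral frequency
$p \sim U(0.05, 0.95)$, per heterotic group a frequency from
$\mathrm{Beta}(p\theta, (1-p)\theta)$ with $\theta = (1-F_{st})/F_{st}$,
and each line homozygous (dosage 0 or 2) at the group frequency. Markers
spread evenly over 10 chromosomes (~1 per 100 kb). Defaults: 5 groups of
near-equal size, $F_{st} = 0.2$ — enough structure that PCA separates
groups while crosses stay informative.

`sim_trait()` emulates the study conditions used for design evaluation: a
trait controlled by **200 QTL evenly spaced** across the genome (first QTL
at index $\lfloor m/2q \rfloor$, spacing $m/q$), absolute additive effects
from $\mathrm{Gamma}(1, 1)$ with independent random signs, and **target
heritability 0.7** on the hybrid set. The gamma shape/scale and the sign
convention are exposed in `sim_config()` since only the distributional
family is fixed by the emulated conditions. Each QTL also carries a
dominance effect $d = 0.5\,|a|$ by default so heterosis exists; the
dominance ratio is a config knob (0 gives a purely additive trait). The
residual variance is calibrated *empirically* on the realized hybrid set
($\sigma_e^2 = \mathrm{var}(g)(1-h^2)/h^2$) rather than analytically — the
realized heritability then matches the target up to sampling error
(±0.05 at 1,000+ hybrids).

What the simulator does **not** emulate: linkage disequilibrium between
markers (draws are independent given group frequencies), pedigree
relatedness beyond group membership, multi-trait correlations, genotype ×
environment interaction at the marker level. Consequently, passing tests
demonstrate that the machinery is correct and well-calibrated under the
stated genetic architecture; they do not certify accuracy levels on real
panels, where LD between markers and QTL is the main driver of prediction.
One concrete consequence: held-out-line GCA accuracy on unlinked markers is
capped by realized relatedness (≈0.85–0.9 in structured panels here), even
for a noiseless additive trait.

## Design-efficiency study

`sim_design_study()` re-enacts the question "how many parents, how many
crosses?": for every grid cell it samples a sparse partial diallel with
full parental coverage, simulates phenotypes at the target heritability,
fits the additive kernel model on the sampled hybrids, converts the fit to
marker effects, scores **every** panel line, and correlates with the true
GCA. The additive-only model is used for the sweep (GCA is an
additive-level quantity and the eigen-rotated path makes 100+ fits cheap);
the full additive+dominance model remains the default everywhere hybrids
themselves are predicted. The reproduced pattern: accuracy climbs steeply
with the number of parental lines, while at a fixed line count the two
largest training sizes are nearly interchangeable.

## Post-GWAS machinery

The five published multi-locus GWAS tools stay out of scope; their result
tables are first-class inputs (`read_association_table()`), and a simple
PC-corrected single-marker scan (`assoc_scan()`, method label `lm_pc`) is
provided as plumbing so the pipeline runs end-to-end on synthetic data.
Thresholds follow the two conventions: $-\log_{10}(1/m) = \log_{10}(m)$
for p-value scores (5.036 at 108,541 SNPs — note this admits about one
false positive per scan by construction) and LOD ≥ 3 for LOD scores.
Consensus sets are intersections over distinct methods (≥1, ≥2, ≥3);
`build_marker_sets()` assembles the nine named sets with size-matched
random controls (matched on count only, not MAF or chromosome).

Superior-genotype analysis takes the favourable direction per trait
(higher for yield components, lower for e.g. plant height), calls the
genotype class with the most favourable mean "superior" (classes under 5
carriers ignored), and counts per hybrid how many listed SNPs carry the
superior class. The SNP type classification (I–V) uses a Welch t-test for
the two inbred homozygote classes and one-way ANOVA + Tukey HSD among the
hybrid classes at $\alpha = 0.05$; the hybrid "superior set" is the best
class plus any class Tukey cannot separate from it. The tests behind these
calls are package conventions (the workflow is standard but no specific
test is canonical); both are exposed as arguments.

## Numerical and design choices worth knowing

* **QC boundaries are strict inequalities**: a marker at exactly 20%
  missingness or exactly 5% MAF survives. MAF is computed before
  imputation; surviving missing calls are mean-imputed.
* **Dosages are panel-minor-allele counts**; VCF/HapMap input is
  re-oriented so frequency ≤ 0.5 panel-wide.
* Residual heterozygous calls in inbred parents are tolerated to 5% per
  line and resolved to the marker's major homozygote with a warning;
  beyond that the offending line is named in an error.
* **Kinship scale**: the $1/m$ divisor is kept (not $\sum 2p_kq_k$) to
  preserve the exact ridge equivalence; any kernel rescaling shifts the
  variance-component scale but not predictions. The dominance kernel's
  mean diagonal is ~0.2 under these codings — when planting known variance
  components in validation work, normalise kernels to unit mean diagonal
  or the components sit on non-comparable scales.
* **Plan generation** first covers every line once (preferring
  between-group partners with the target probability), then fills to size
  with under-used parents favoured; realized between-group fractions land
  within ±5 points of the request. The exact cell-filling rule of the
  original field design is not algorithmically specified anywhere, so this
  generator is a faithful stand-in, not a reconstruction.
* **Ties** break lexicographically everywhere a ranking is produced
  (selection lists, parent rankings), making every ranking reproducible
  under permutation of the input.
* **Selection gains** are computed over validated entries only, with the
  validated-set mean as the `gain_vs_mean` baseline, and check-exceedance
  counted at the check value and at check × 1.05.
* NJ trees come from the standard Saitou–Nei algorithm (via ape) on simple
  matching distances, with negative branch lengths clamped to zero; LD
  decay distance is read from an isotonic (monotone non-increasing) fit to
  binned mean $r^2$, the first bin midpoint below the threshold.

## Problem sizes in the shipped checks

The package's own test-suite and the acceptance script run the whole
pipeline at reduced scale, chosen so every statistical check retains its
power: panels of 30–266 lines with 50–1,200 SNPs, training sets of 80–500
hybrids, a design sweep over lines {30, 60, 120} × hybrids {150, 300, 450}
(the 30-line panel has only 435 possible pairs, so its 450-hybrid cell is
infeasible by arithmetic and excluded), 20 replicates per cell, and
BayesB chains of 2,000–3,000 iterations. At these sizes the realized
heritability lands within ±0.05 of the 0.7 target, fivefold CV accuracy of
the additive+dominance model falls in the 0.4–0.95 band, and the complete
pipeline — simulate, cross, fit, predict 7,140 hybrids, rank parents,
select extremes — runs in well under a minute.

## Limitations

* No LD simulation (and hence no LD-decay realism in the synthetic data;
  `ld_decay()` is exercised on purpose-built Markov-correlated fixtures).
* GCA is reported without specific combining ability; reciprocal effects
  and maternal effects are ignored (crosses are unordered).
* `env_blup()` fits genotype and genotype × environment as independent
  random effects; spatial field trends and repeatability structures are
  out of scope.
* The EM-REML fixed point is robust but slow near variance boundaries;
  fits that walk a component to zero may report `converged = FALSE` at the
  iteration cap with the remaining components essentially final.
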