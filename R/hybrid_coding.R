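#' Infer hybrid genotypes from inbred parents
#'
#' For each cross in `plan`, builds the additive row `Z_a = (g_p1 + g_p2) / 2`
#' (expected F1 minor-allele dosage) and the dominance indicator row
#' `Z_d = 1[g_p1 != g_p2]` (F1 heterozygosity). With homozygous parents
#' `Z_a` is integer-valued and `Z_d = 1` exactly where `Z_a = 1`.
#'
#' Residual heterozygous calls in the parents (dosage 1) are tolerated up to
#' `het_tolerance` per line and resolved to the marker's major homozygote
#' class with a warning; lines above the tolerance raise an error naming the
#' line.
#'
#' @param g a [geno_matrix()] holding the parental inbreds (no missing data).
#' @param plan a [cross_plan()] or data.frame with columns `parent1`,
#'   `parent2`.
#' @param het_tolerance maximum tolerated per-line heterozygous call rate
#'   (default 0.05).
#' @return an object of class `hybrid_coding`: list with `hybrid` (IDs,
#'   "p1/p2"), `parents` (two-column data.frame), `Za` and `Zd` matrices
#'   (hybrids x markers), and `markers`.
#' @export
infer_hybrid_genotypes <- function(g, plan, het_tolerance = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  plan <- as.data.frame(plan)
  if (nrow(plan) == 0) stopf("empty cross plan")
  d <- g$dosage
  if (anyNA(d)) stopf("parental genotypes contain missing calls; run qc_filter first")
  miss_parents <- setdiff(unique(c(plan$parent1, plan$parent2)), rownames(d))
  if (length(miss_parents))
    stopf("unknown parent line(s): %s", paste(head(miss_parents, 5), collapse = ", "))
  het <- rowMeans(d == 1)
  used <- unique(c(plan$parent1, plan$parent2))
  over <- used[het[used] > het_tolerance]
  if (length(over))
    stopf("parent heterozygosity above tolerance (%.0f%%): %s",
          100 * het_tolerance, paste(head(over, 5), collapse = ", "))
  if (any(het[used] > 0)) {
    warnf("resolving residual heterozygous calls in %d line(s) to the major homozygote",
          sum(het[used] > 0))
    p <- colMeans(d) / 2
    major <- ifelse(p >= 0.5, 2, 0)
    for (ln in used[het[used] > 0]) {
      hz <- d[ln, ] == 1
      d[ln, hz] <- major[hz]
    }
  }
  g1 <- d[plan$parent1, , drop = FALSE]
  g2 <- d[plan$parent2, , drop = FALSE]
  Za <- (g1 + g2) / 2
  Zd <- (g1 != g2) * 1
  ids <- hybrid_id(plan$parent1, plan$parent2)
  rownames(Za) <- rownames(Zd) <- ids
  structure(list(hybrid = ids,
                 parents = data.frame(parent1 = plan$parent1,
                                      parent2 = plan$parent2,
                                      stringsAsFactors = FALSE),
                 Za = Za, Zd = Zd, markers = colnames(d)),
            class = "hybrid_coding")
}

#' @export
#' @method print hybrid_coding
print.hybrid_coding <- function(x, ...) {
  cat(sprintf("<hybrid_coding> %d hybrids x %d markers\n",
              nrow(x$Za), ncol(x$Za)))
  invisible(x)
}

#' Subset a hybrid coding to a marker set
#' @param coding a [infer_hybrid_genotypes()] result.
#' @param markers character vector of marker IDs to keep.
#' @return a `hybrid_coding` restricted to `markers`.
#' @export
subset_coding <- function(coding, markers) {
  idx <- match(markers, coding$markers)
  if (anyNA(idx)) stopf("unknown marker(s) in subset")
  coding$Za <- coding$Za[, idx, drop = FALSE]
  coding$Zd <- coding$Zd[, idx, drop = FALSE]
  coding$markers <- coding$markers[idx]
  coding
}

#' Additive genomic kinship
#'
#' VanRaden-style frequency-centered kernel `K_a = W_a W_a' / m` with
#' `W_a = Z_a - 2p` column-wise. The divisor `m` (marker count) matches a
#' marker-effect model in which each effect has variance `phi_a^2 / m`, so
#' kernel GBLUP with this matrix is exactly equivalent to ridge regression on
#' the markers.
#'
#' @param Za additive dosage matrix (individuals x markers).
#' @param freqs allele frequencies used for centering; defaults to the column
#'   means of `Za / 2`. Pass the training-panel frequencies when coding test
#'   individuals.
#' @return list with `K` (kinship), `freqs`, and `m`.
#' @export
additive_kinship <- function(Za, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(Za) / 2
  W <- sweep(Za, 2, 2 * freqs)
  if (all(abs(W) < 1e-12))
    stopf("all markers monomorphic: additive kinship undefined")
  m <- ncol(Za)
  list(K = tcrossprod(W) / m, freqs = freqs, m = m)
}

#' Dominance genomic kinship
#'
#' Mean-centered heterozygosity kernel `K_d = W_d W_d' / m` with
#' `W_d = Z_d - mean(Z_d)` column-wise.
#'
#' @param Zd dominance indicator matrix (individuals x markers).
#' @param means centering means; defaults to column means of `Zd`.
#' @return list with `K`, `means`, and `m`.
#' @export
dominance_kinship <- function(Zd, means = NULL) {
  if (is.null(means)) means <- colMeans(Zd)
  W <- sweep(Zd, 2, means)
  m <- ncol(Zd)
  list(K = tcrossprod(W) / m, means = means, m = m)
}

#' Additive + dominance kinship pair for a hybrid coding
#'
#' @param coding a [infer_hybrid_genotypes()] result (or any list with `Za`,
#'   `Zd`).
#' @param freqs,dmeans optional training-panel centering values.
#' @return object of class `kinship_pair`: list with `Ka`, `Kd`, `freqs`,
#'   `dmeans`, `m`.
#' @export
kinship_pair <- function(coding, freqs = NULL, dmeans = NULL) {
  a <- additive_kinship(coding$Za, freqs)
  d <- dominance_kinship(coding$Zd, dmeans)
  structure(list(Ka = a$K, Kd = d$K, freqs = a$freqs, dmeans = d$means,
                 m = a$m), class = "kinship_pair")
}
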