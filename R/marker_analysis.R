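#' Bonferroni-style GWAS significance threshold
#'
#' The marker-based threshold `-log10(1 / m) = log10(m)` for a panel of `m`
#' SNPs (e.g. 108,541 markers give 5.036).
#'
#' @param m marker count.
#' @return the -log10(p) threshold.
#' @examples
#' significance_threshold(108541)  # 5.036
#' @export
significance_threshold <- function(m) {
  if (!is.numeric(m) || m < 1) stopf("m must be a count >= 1")
  log10(m)
}

#' Single-marker association scan with PC covariates
#'
#' A simple per-SNP linear model `y ~ SNP + PC1..PCk` giving two-sided
#' p-values (method label `"lm_pc"`). This is plumbing so the consensus and
#' marker-set machinery runs end-to-end on synthetic data; result tables
#' from external multi-locus GWAS tools can be imported with
#' [read_association_table()] and used interchangeably.
#'
#' @param y phenotype (or GCA) per line, aligned with `geno` rows.
#' @param geno a post-QC [geno_matrix()].
#' @param n_pcs number of principal components as covariates (default 3;
#'   0 reduces to simple regression).
#' @param trait trait label recorded in the table.
#' @param target `"trait"` or `"gca"` (what was scanned).
#' @return an association table: data.frame with columns `snp`, `chrom`,
#'   `pos`, `trait`, `target`, `method`, `score` (-log10 p, 0 for constant
#'   SNPs), `score_type = "neglog10p"`.
#' @export
assoc_scan <- function(y, geno, n_pcs = 3, trait = "trait",
                       target = c("trait", "gca")) {
  target <- match.arg(target)
  y <- as.numeric(y)
  X <- geno$dosage
  if (length(y) != nrow(X)) stopf("y must align with genotype rows")
  n <- length(y)
  if (n_pcs > 0) {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    C <- cbind(1, pc$x[, seq_len(n_pcs), drop = FALSE])
  } else {
    C <- matrix(1, n, 1)
  }
  # residualize y and every SNP on the covariates, then per-SNP t-test
  Q <- qr.Q(qr(C))
  ry <- y - Q %*% crossprod(Q, y)
  RX <- X - Q %*% crossprod(Q, X)
  df <- n - ncol(C) - 1
  ssx <- colSums(RX^2)
  const <- ssx < 1e-12
  bhat <- drop(crossprod(RX, ry)) / ifelse(const, 1, ssx)
  rss <- drop(sum(ry^2) - bhat^2 * ssx)
  sigma2 <- rss / df
  tstat <- bhat / sqrt(sigma2 / ssx)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  score <- -log10(p)
  score[const | !is.finite(score)] <- 0
  data.frame(snp = geno$map$marker, chrom = geno$map$chrom,
             pos = geno$map$pos, trait = trait, target = target,
             method = "lm_pc", score = score, score_type = "neglog10p",
             stringsAsFactors = FALSE)
}

#' Read / write association tables
#'
#' TSV with columns `snp, chrom, pos, trait, target, method, score,
#' score_type`; `score_type` is `"neglog10p"` or `"lod"`.
#'
#' @param path file path.
#' @export
read_association_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("snp", "trait", "target", "method", "score", "score_type")
  if (!all(need %in% names(df)))
    stopf("association table must have columns %s",
          paste(need, collapse = ", "))
  if (any(df$score < 0)) stopf("scores must be >= 0")
  df
}

#' @rdname read_association_table
#' @param table an association table.
#' @export
write_association_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Apply each method's own significance rule to an association table
#'
#' Rows with `score_type = "neglog10p"` are kept when `score >= log10(m)`;
#' rows with `score_type = "lod"` when `score >= lod_threshold`.
#'
#' @param table association table.
#' @param m marker count behind the -log10 threshold.
#' @param lod_threshold LOD cutoff (default 3).
#' @return the significant subset of `table`.
#' @export
threshold_associations <- function(table, m, lod_threshold = 3) {
  table <- as.data.frame(table)
  thr <- ifelse(table$score_type == "lod", lod_threshold,
                significance_threshold(m))
  table[table$score >= thr, , drop = FALSE]
}

#' Cross-method consensus SNPs
#'
#' SNPs significant for the same trait and target in at least `min_methods`
#' distinct methods. Tables must already be thresholded by their own rule
#' (see [threshold_associations()]).
#'
#' @param tables one thresholded association table or a list of them.
#' @param min_methods minimum number of distinct supporting methods.
#' @return character vector of SNP IDs (empty if nothing qualifies).
#' @export
consensus_snps <- function(tables, min_methods = 2) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, lapply(tables, as.data.frame))
  n_methods <- length(unique(tab$method))
  if (nrow(tab) == 0) n_methods <- 0
  if (min_methods > max(n_methods, length(tables)))
    stopf("min_methods (%d) exceeds the %d method(s) supplied", min_methods,
          n_methods)
  if (nrow(tab) == 0) return(character(0))
  key <- paste(tab$snp, tab$trait, tab$target, sep = "\r")
  support <- tapply(tab$method, key, function(z) length(unique(z)))
  hits <- names(support)[support >= min_methods]
  sort(unique(vapply(strsplit(hits, "\r"), `[`, character(1), 1)))
}

#' Build the nine prediction marker sets
#'
#' `All` (every genotyped SNP); `GCA_SNP1` / `GCA_SNP2` (GCA-associated
#' SNPs supported by >= 1 / >= 2 methods); `Trait_SNP1` / `Trait_SNP2`
#' (same for the trait per se); and a size-matched random counterpart for
#' each of the four consensus sets, drawn uniformly without replacement
#' from the genotyped panel (seed-deterministic).
#'
#' @param gca_snp1,gca_snp2,trait_snp1,trait_snp2 character vectors of SNP
#'   IDs (from [consensus_snps()] at levels 1 and 2).
#' @param all_snps all genotyped SNP IDs.
#' @param seed seed for the random sets.
#' @return named list of class `marker_sets`: nine character vectors.
#' @export
build_marker_sets <- function(gca_snp1, gca_snp2, trait_snp1, trait_snp2,
                              all_snps, seed = 1) {
  refs <- list(GCA_SNP1 = gca_snp1, GCA_SNP2 = gca_snp2,
               Trait_SNP1 = trait_snp1, Trait_SNP2 = trait_snp2)
  bad <- unlist(lapply(refs, setdiff, y = all_snps))
  if (length(bad))
    stopf("consensus SNP(s) not in the genotyped panel: %s",
          paste(head(bad, 5), collapse = ", "))
  set.seed(as.integer(seed))
  rnd <- lapply(refs, function(ref) {
    if (length(ref) == 0) {
      warnf("empty reference set: its random counterpart is empty too")
      return(character(0))
    }
    sample(all_snps, length(ref))
  })
  names(rnd) <- paste0("Rnd_", names(refs))
  structure(c(list(All = all_snps), refs, rnd), class = "marker_sets")
}

#' Prediction accuracy of each marker set on a validation hybrid set
#'
#' Trains the model on the training hybrids using only the SNPs of each
#' set, predicts the disjoint test hybrids, and reports the Pearson
#' correlation with their observed values.
#'
#' @param sets a [build_marker_sets()] collection (or named list of SNP ID
#'   vectors).
#' @param train_coding,test_coding hybrid codings sharing the same marker
#'   panel.
#' @param y_train,y_test phenotypes aligned with the codings.
#' @param model `"gblup"` (additive + dominance kernels, default),
#'   `"gblup_a"` (additive only), `"bayesb"` or `"lasso"`.
#' @param config [mcmc_config()] for BayesB.
#' @return data.frame with columns `set`, `n_snps`, `accuracy`.
#' @export
evaluate_marker_sets <- function(sets, train_coding, test_coding, y_train,
                                 y_test,
                                 model = c("gblup", "gblup_a", "bayesb",
                                           "lasso"),
                                 config = mcmc_config(n_iter = 3000,
                                                      burn_in = 1000)) {
  model <- match.arg(model)
  if (length(intersect(train_coding$hybrid, test_coding$hybrid)))
    stopf("train and test hybrid sets must be disjoint")
  res <- lapply(names(sets), function(nm) {
    snps <- sets[[nm]]
    if (length(snps) == 0) stopf("marker set '%s' is empty", nm)
    tr <- subset_coding(train_coding, snps)
    te <- subset_coding(test_coding, snps)
    pred <- switch(model,
      gblup = predict(gblup_fit(y_train, tr), te),
      gblup_a = predict(gblup_fit(y_train, tr, dominance = FALSE), te),
      bayesb = predict(bayesb_fit(y_train, coding_design(tr), config),
                       coding_design(te)),
      lasso = predict(suppressWarnings(lasso_fit(y_train, coding_design(tr))),
                      coding_design(te)))
    data.frame(set = nm, n_snps = length(snps),
               accuracy = cor(y_test, pred), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Superior genotype per SNP and per-hybrid accumulation counts
#'
#' For each SNP, the superior genotype is the dosage class whose carriers
#' have the most favourable mean value (`direction = "higher"` for yield
#' traits, `"lower"` for e.g. plant height); classes with fewer than
#' `min_class_size` carriers are ignored, and SNPs with only one usable
#' class are skipped with a warning. Given a second population (typically
#' the hybrids), each individual's accumulation count is the number of
#' listed SNPs at which it carries the superior genotype.
#'
#' @param snps SNP IDs to analyse.
#' @param values named numeric vector (GCA or phenotype) for the reference
#'   individuals.
#' @param geno_ref dosage matrix (or [geno_matrix()]) of the reference
#'   individuals x markers.
#' @param geno_count optional dosage matrix of the individuals to score
#'   (default: the reference individuals).
#' @param direction `"higher"` or `"lower"`.
#' @param min_class_size minimum carriers per class (default 5).
#' @return list with `superior` (data.frame: snp, superior_class,
#'   class_means...) and `counts` (named integer vector of accumulation
#'   counts).
#' @export
superior_genotypes <- function(snps, values, geno_ref, geno_count = NULL,
                               direction = c("higher", "lower"),
                               min_class_size = 5) {
  direction <- match.arg(direction)
  X <- if (inherits(geno_ref, "geno_matrix")) geno_ref$dosage else geno_ref
  Xc <- if (is.null(geno_count)) X
        else if (inherits(geno_count, "geno_matrix")) geno_count$dosage
        else geno_count
  ids <- names(values) %||% rownames(X)
  vals <- as.numeric(values)
  missing_snps <- setdiff(snps, colnames(X))
  if (length(missing_snps)) stopf("SNP(s) not genotyped: %s",
                                  paste(head(missing_snps, 3), collapse = ", "))
  sup <- list()
  for (s in snps) {
    cls <- X[ids, s]
    tab <- table(cls)
    usable <- names(tab)[tab >= min_class_size]
    if (length(usable) < 2) {
      warnf("SNP %s skipped: fewer than 2 usable genotype classes", s)
      next
    }
    cm <- tapply(vals[cls %in% as.numeric(usable)],
                 cls[cls %in% as.numeric(usable)], mean)
    best <- if (direction == "higher") names(cm)[which.max(cm)]
            else names(cm)[which.min(cm)]
    sup[[s]] <- data.frame(snp = s, superior_class = as.numeric(best),
                           mean_best = cm[[best]],
                           n_classes = length(usable),
                           stringsAsFactors = FALSE)
  }
  if (!length(sup)) stopf("no SNP with at least two usable genotype classes")
  superior <- do.call(rbind, sup)
  rownames(superior) <- NULL
  counts <- integer(nrow(Xc))
  for (k in seq_len(nrow(superior))) {
    counts <- counts + (Xc[, superior$snp[k]] == superior$superior_class[k])
  }
  list(superior = superior, counts = setNames(counts, rownames(Xc)),
       direction = direction)
}

#' Classify trait-associated SNPs by inbred/hybrid genotype-class behaviour
#'
#' Decision tree at significance level `alpha`: the two homozygote classes
#' in the inbreds are compared with a Welch t-test; the (up to three)
#' genotype classes in the hybrids with one-way ANOVA followed by Tukey HSD,
#' where the hybrid "superior set" contains the best class plus any class
#' not significantly worse than it.
#'
#' * Type I  - both tests significant; hybrid superior set is the single
#'   homozygote that is also superior in the inbreds.
#' * Type II - both significant; superior set = that homozygote plus the
#'   heterozygote.
#' * Type III - hybrid classes differ with the heterozygote alone superior
#'   (overdominance-like).
#' * Type IV - both significant but the superior hybrid homozygote is the
#'   *other* homozygote than in the inbreds.
#' * Type V  - no significant differences in either population.
#'
#' Records matching none of the rules are labelled `"unclassified"` with
#' diagnostics kept in the output.
#'
#' @param snps SNP IDs.
#' @param inbred_values named values (GCA or BLUP phenotype) of the inbred
#'   lines; `inbred_geno` dosage matrix of the same lines.
#' @param hybrid_values named values of the hybrids; `hybrid_geno` dosage
#'   matrix of the hybrids (classes 0/1/2).
#' @param inbred_geno,hybrid_geno dosage matrices (or `geno_matrix`).
#' @param direction `"higher"` if larger values are favourable.
#' @param alpha significance level (default 0.05).
#' @param min_class_size minimum individuals per usable class (default 5).
#' @return data.frame: `snp`, `type`, `inbred_p`, `hybrid_p`,
#'   `inbred_superior`, `hybrid_superior` (classes collapsed with "+"),
#'   `note`.
#' @export
classify_snp_types <- function(snps, inbred_values, inbred_geno,
                               hybrid_values, hybrid_geno,
                               direction = c("higher", "lower"),
                               alpha = 0.05, min_class_size = 5) {
  direction <- match.arg(direction)
  Xi <- if (inherits(inbred_geno, "geno_matrix")) inbred_geno$dosage else inbred_geno
  Xh <- if (inherits(hybrid_geno, "geno_matrix")) hybrid_geno$dosage else hybrid_geno
  better <- function(a, b) if (direction == "higher") a > b else a < b
  out <- lapply(snps, function(s) {
    row <- data.frame(snp = s, type = "unclassified", inbred_p = NA_real_,
                      hybrid_p = NA_real_, inbred_superior = NA_character_,
                      hybrid_superior = NA_character_, note = "",
                      stringsAsFactors = FALSE)
    ci <- Xi[, s]
    ch <- Xh[, s]
    ti <- table(ci)
    usable_i <- as.numeric(names(ti)[ti >= min_class_size])
    usable_i <- usable_i[usable_i %in% c(0, 2)]
    if (length(usable_i) < 2) {
      row$note <- "inbred homozygote class missing"
      return(row)
    }
    vi <- inbred_values
    tt <- t.test(vi[ci == 0], vi[ci == 2])
    row$inbred_p <- tt$p.value
    mi <- c(`0` = mean(vi[ci == 0]), `2` = mean(vi[ci == 2]))
    inbred_sup <- names(mi)[if (direction == "higher") which.max(mi) else which.min(mi)]
    row$inbred_superior <- inbred_sup
    th <- table(ch)
    usable_h <- as.numeric(names(th)[th >= min_class_size])
    if (length(usable_h) < 2) {
      row$note <- "hybrid classes missing"
      return(row)
    }
    if (length(usable_h) < 3) row$note <- "hybrid class missing; classified with available classes"
    sel <- ch %in% usable_h
    vh <- hybrid_values[sel]
    fh <- factor(ch[sel])
    fit <- aov(vh ~ fh)
    row$hybrid_p <- anova(fit)$`Pr(>F)`[1]
    mh <- tapply(vh, fh, mean)
    tk <- TukeyHSD(fit)$fh
    best_h <- names(mh)[if (direction == "higher") which.max(mh) else which.min(mh)]
    # superior set: best class + classes not significantly worse than it
    sup_set <- best_h
    for (g in setdiff(names(mh), best_h)) {
      pr <- tk[rownames(tk) %in% c(paste(g, best_h, sep = "-"),
                                   paste(best_h, g, sep = "-")), "p adj"]
      if (length(pr) && pr[1] >= alpha) sup_set <- c(sup_set, g)
    }
    sup_set <- sort(sup_set)
    row$hybrid_superior <- paste(sup_set, collapse = "+")
    inbred_sig <- row$inbred_p < alpha
    hybrid_sig <- row$hybrid_p < alpha
    if (!inbred_sig && !hybrid_sig) {
      row$type <- "V"
    } else if (inbred_sig && hybrid_sig) {
      if (identical(sup_set, "1")) {
        row$type <- "III"
      } else if (length(sup_set) == 1 && sup_set %in% c("0", "2")) {
        row$type <- if (sup_set == inbred_sup) "I" else "IV"
      } else if (length(sup_set) == 2 && "1" %in% sup_set) {
        hom <- setdiff(sup_set, "1")
        row$type <- if (hom == inbred_sup) "II" else "IV"
      }
    } else if (inbred_sig && !hybrid_sig) {
      row$note <- paste0(row$note, " inbred-only significance")
    } else if (hybrid_sig && identical(sup_set, "1")) {
      row$type <- "III"
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
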