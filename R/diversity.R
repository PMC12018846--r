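#' Simple matching distance between lines
#'
#' `d(i, j)` is the proportion of markers at which the two lines carry
#' different dosage calls. Identical lines are at distance 0, fully
#' complementary homozygous lines at distance 1.
#'
#' @param g a [geno_matrix()] without missing data (run [qc_filter()]
#'   first), or with `pairwise_complete = TRUE` to use, per pair, only the
#'   markers observed in both lines.
#' @param pairwise_complete handle missing data pairwise (default FALSE).
#' @return symmetric numeric matrix with zero diagonal and line labels.
#' @export
simple_matching_distance <- function(g, pairwise_complete = FALSE) {
  d <- g$dosage
  if (nrow(d) < 2) stopf("need at least 2 lines")
  if (anyNA(d) && !pairwise_complete)
    stopf("missing data present; run qc_filter or use pairwise_complete")
  levs <- sort(unique(as.vector(d[!is.na(d)])))
  if (!anyNA(d)) {
    m <- ncol(d)
    match_count <- matrix(0, nrow(d), nrow(d))
    for (lev in levs) {
      ind <- (d == lev) * 1
      match_count <- match_count + tcrossprod(ind)
    }
    out <- 1 - match_count / m
  } else {
    obs <- !is.na(d)
    d0 <- d
    d0[!obs] <- Inf
    match_count <- matrix(0, nrow(d), nrow(d))
    for (lev in levs) {
      ind <- (d0 == lev) * 1
      match_count <- match_count + tcrossprod(ind)
    }
    both <- tcrossprod(obs * 1)
    out <- 1 - match_count / both
  }
  diag(out) <- 0
  dimnames(out) <- list(rownames(d), rownames(d))
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape). Negative branch lengths, which NJ
#' can produce on non-additive distances, are clamped to zero with a
#' message.
#'
#' @param d symmetric distance matrix with labels.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stopf("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamping %d negative branch length(s) to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Write a tree in newick format
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Principal-component scores of a genotype panel
#'
#' Eigendecomposition of the covariance of the column-centered dosage
#' matrix (via `prcomp`, no scaling).
#'
#' @param g a post-QC [geno_matrix()].
#' @param n_components number of components to return (default 3).
#' @return list with `scores` (data.frame: line, PC1..PCk) and
#'   `var_explained` (fraction per returned component; the fractions of a
#'   full decomposition sum to 1).
#' @export
pca_scores <- function(g, n_components = 3) {
  d <- g$dosage
  if (anyNA(d)) stopf("missing data present; run qc_filter first")
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank)
    stopf("n_components (%d) exceeds matrix rank (%d)", n_components, rank)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(line = rownames(d),
                       pc$x[, seq_len(n_components), drop = FALSE],
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, var_explained = ve[seq_len(n_components)],
       var_explained_all = ve)
}

#' Linkage-disequilibrium decay with physical distance
#'
#' For every intra-chromosomal marker pair within `max_dist_bp`, computes
#' `r^2` as the squared Pearson correlation of the dosage vectors, bins the
#' pairs by distance, and reports the mean `r^2` per bin. The decay distance
#' is the midpoint of the first bin at which the monotone-smoothed curve
#' (isotonic non-increasing regression on the bin means) drops below
#' `r2_threshold`; `NA` if it never does within `max_dist_bp`.
#'
#' @param g a post-QC [geno_matrix()] with a marker map.
#' @param max_dist_bp largest pair distance considered.
#' @param bin_bp bin width in bp.
#' @param r2_threshold threshold defining the decay distance (default 0.2).
#' @return object of class `ld_curve`: list with `bins` (data.frame:
#'   bin_start, bin_end, mid, mean_r2, smoothed_r2, n_pairs),
#'   `decay_distance`, `r2_threshold`.
#' @export
ld_decay <- function(g, max_dist_bp, bin_bp, r2_threshold = 0.2) {
  d <- g$dosage
  if (anyNA(d)) stopf("missing data present; run qc_filter first")
  map <- g$map
  pairs_dist <- numeric(0)
  pairs_r2 <- numeric(0)
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    if (length(idx) < 2) next
    ord <- idx[order(map$pos[idx])]
    pos <- map$pos[ord]
    sub <- d[, ord, drop = FALSE]
    cm <- suppressWarnings(cor(sub))
    dist_m <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(dist_m) & dist_m <= max_dist_bp
    ok <- sel & !is.na(cm)
    pairs_dist <- c(pairs_dist, dist_m[ok])
    pairs_r2 <- c(pairs_r2, cm[ok]^2)
  }
  if (!length(pairs_dist)) stopf("no marker pairs within max_dist_bp")
  brk <- seq(0, max_dist_bp + bin_bp, by = bin_bp)
  bin <- cut(pairs_dist, brk, include.lowest = TRUE, right = TRUE)
  mean_r2 <- tapply(pairs_r2, bin, mean)
  n_pairs <- tapply(pairs_r2, bin, length)
  keep <- !is.na(mean_r2)
  lev <- which(keep)
  bins <- data.frame(bin_start = brk[lev], bin_end = brk[lev + 1],
                     mid = (brk[lev] + brk[lev + 1]) / 2,
                     mean_r2 = as.numeric(mean_r2[keep]),
                     n_pairs = as.integer(n_pairs[keep]))
  # monotone non-increasing smoothing: isotonic regression on reversed bins
  iso <- isoreg(rev(bins$mean_r2))
  bins$smoothed_r2 <- rev(iso$yf)
  below <- which(bins$smoothed_r2 < r2_threshold)
  decay <- if (length(below)) bins$mid[below[1]] else NA_real_
  structure(list(bins = bins, decay_distance = decay,
                 r2_threshold = r2_threshold), class = "ld_curve")
}

#' @export
#' @method print ld_curve
print.ld_curve <- function(x, ...) {
  cat(sprintf("<ld_curve> %d bins; decay below r2 = %.2f at %s bp\n",
              nrow(x$bins), x$r2_threshold,
              if (is.na(x$decay_distance)) "NA" else
                format(x$decay_distance, big.mark = ",")))
  invisible(x)
}
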