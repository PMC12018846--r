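#' Genotype matrix container
#'
#' A `geno_matrix` holds a lines x markers minor-allele dosage matrix together
#' with a marker map (chromosome label and 1-based bp position). Dosages are
#' minor-allele counts in \{0, 1, 2\}; `NA` marks missing calls. Inbred panels
#' are expected to be (near) homozygous, i.e. essentially \{0, 2\}.
#'
#' @param dosage numeric matrix, lines in rows (rownames = line IDs), markers
#'   in columns (colnames = marker IDs). Values in \{0, 1, 2\} or `NA`.
#' @param map optional data.frame with columns `marker`, `chrom`, `pos`
#'   (1-based bp). When omitted a single-chromosome map with unit spacing is
#'   synthesised.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (the matrix) and `map` (the marker map, one row per column of `dosage`).
#' @examples
#' g <- geno_matrix(matrix(c(0, 2, 2, 0), 2, 2,
#'                         dimnames = list(c("L1", "L2"), c("s1", "s2"))))
#' g
#' @export
geno_matrix <- function(dosage, map = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("L", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stopf("duplicate line identifiers in genotype matrix")
  if (anyDuplicated(colnames(dosage)))
    stopf("duplicate marker identifiers in genotype matrix")
  ok <- dosage[!is.na(dosage)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    stopf("dosages must lie in [0, 2]")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage),
                      chrom = "1",
                      pos = seq_len(ncol(dosage)),
                      stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    stopf("map must have columns marker, chrom, pos")
  if (nrow(map) != ncol(dosage) || !all(map$marker == colnames(dosage)))
    stopf("map rows must match dosage columns (same markers, same order)")
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom))))
  nmiss <- sum(is.na(x$dosage))
  if (nmiss > 0) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Line identifiers of a genotype panel
#' @param g a [geno_matrix()]
#' @return character vector of line IDs.
#' @export
lines_of <- function(g) rownames(g$dosage)

#' Per-marker minor allele frequency
#'
#' Frequencies are computed on non-missing calls only, so MAF reflects the
#' observed panel before any imputation.
#'
#' @param g a [geno_matrix()]
#' @return named numeric vector of minor-allele frequencies (in \[0, 0.5\]).
#' @export
maf <- function(g) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter markers on missing rate and minor allele frequency
#'
#' Removes markers whose missing rate exceeds `max_missing` or whose minor
#' allele frequency falls below `min_maf` (both comparisons strict, so a
#' marker at exactly the boundary is kept). Remaining missing calls are
#' replaced by the marker mean dosage. MAF is computed on the observed calls
#' before imputation.
#'
#' @param g a [geno_matrix()]
#' @param max_missing markers with missing rate strictly above this are
#'   removed (default 0.20).
#' @param min_maf markers with MAF strictly below this are removed
#'   (default 0.05).
#' @return a `geno_matrix` with the surviving markers, no missing values, and
#'   a `qc_report` attribute (see [qc_report()]).
#' @export
qc_filter <- function(g, max_missing = 0.20, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- colMeans(is.na(g$dosage))
  freq <- maf(g)
  drop_missing <- miss > max_missing
  drop_maf <- !drop_missing & (is.nan(freq) | freq < min_maf)
  keep <- !(drop_missing | drop_maf)
  report <- list(n_input = ncol(g$dosage),
                 n_removed_missing = sum(drop_missing),
                 n_removed_maf = sum(drop_maf),
                 n_kept = sum(keep),
                 max_missing = max_missing,
                 min_maf = min_maf)
  if (!any(keep))
    stopf("qc_filter removed all markers (%d by missing rate, %d by MAF)",
          report$n_removed_missing, report$n_removed_maf)
  d <- g$dosage[, keep, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- geno_matrix(d, g$map[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param g a filtered `geno_matrix`
#' @return list with removal counts per rule, or `NULL` if not filtered.
#' @export
qc_report <- function(g) attr(g, "qc_report")

#' Subset a genotype panel
#'
#' @param g a [geno_matrix()]
#' @param lines,markers character vectors (or indices) selecting rows/columns;
#'   `NULL` keeps everything.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, lines = NULL, markers = NULL) {
  d <- g$dosage
  map <- g$map
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, colnames(d))
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  geno_matrix(d, map)
}
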