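#' Read a genotype panel from VCF, HapMap or dosage TSV
#'
#' All formats are reduced to the same representation: a lines x markers
#' dosage matrix oriented to the minor allele of the input panel (so a dosage
#' of 2 always means two copies of the panel-minor allele). Multi-allelic
#' sites are dropped with a message.
#'
#' * `vcf`: GT fields only (phasing ignored); requires the vcfR package.
#' * `hapmap`: tab-separated with the usual 11 metadata columns
#'   (`rs#, alleles, chrom, pos, strand, ...`) followed by one column per
#'   line holding diploid calls such as `AA`, `AG`, `NN`.
#' * `dosage`: TSV with a `line` ID column and one numeric column per marker.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"vcf"`, `"hapmap"`, `"dosage"`. `"auto"`
#'   guesses from the file extension/header.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "hapmap", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.(hmp|hapmap)(\\.txt)?$", path)) "hapmap"
      else "dosage"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         hapmap = read_genotypes_hapmap(path),
         dosage = read_genotypes_dosage(path))
}

read_genotypes_dosage <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (names(dt)[1] != "line")
    stopf("dosage TSV must have a first column named 'line'")
  if (anyDuplicated(dt$line)) stopf("duplicate line IDs in %s", path)
  d <- as.matrix(dt[, -1, drop = FALSE])
  rownames(d) <- dt$line
  geno_matrix(d)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    message(sprintf("dropping %d multi-allelic site(s)", sum(multi)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(gt) == 0) stopf("no biallelic SNPs in %s", path)
  # ALT-allele dosage from GT strings (phased or unphased)
  alt_count <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(z) {
      if (any(z == "." | is.na(z))) return(NA_real_)
      sum(z == "1")
    }, numeric(1))
  }
  d <- t(apply(gt, 1, alt_count))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(d) <- ids
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  orient_minor(geno_matrix(t(d), map))
}

read_genotypes_hapmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  meta_n <- 11L
  if (ncol(dt) <= meta_n) stopf("HapMap file has no sample columns")
  alleles <- strsplit(dt[[2]], "/")
  bad <- lengths(alleles) != 2
  if (any(bad))
    message(sprintf("dropping %d non-biallelic HapMap row(s)", sum(bad)))
  dt <- dt[!bad, , drop = FALSE]
  alleles <- alleles[!bad]
  calls <- as.matrix(dt[, -(1:meta_n), drop = FALSE])
  a2 <- vapply(alleles, `[`, character(1), 2)
  d <- matrix(NA_real_, nrow(calls), ncol(calls))
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    known <- cc != "NN" & !is.na(cc)
    d[i, known] <- vapply(strsplit(cc[known], ""), function(z)
      sum(z == a2[i]), numeric(1))
  }
  rownames(d) <- dt[[1]]
  colnames(d) <- names(dt)[-(1:meta_n)]
  map <- data.frame(marker = dt[[1]], chrom = as.character(dt[[3]]),
                    pos = as.integer(dt[[4]]), stringsAsFactors = FALSE)
  orient_minor(geno_matrix(t(d), map))
}

#' Orient dosages to the panel minor allele
#'
#' Flips any marker whose counted allele has frequency above 0.5 in the panel
#' (dosage becomes `2 - dosage`), so downstream code can assume minor-allele
#' dosages throughout.
#'
#' @param g a [geno_matrix()]
#' @return a `geno_matrix` with all allele frequencies at most 0.5.
#' @export
orient_minor <- function(g) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  flip <- !is.nan(p) & p > 0.5
  if (any(flip)) g$dosage[, flip] <- 2 - g$dosage[, flip]
  g
}

#' Write a genotype panel as dosage TSV
#' @param g a [geno_matrix()]
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(line = rownames(g$dosage), g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a genotype panel as minimal VCF (GT-only)
#'
#' Emits unphased genotypes with the minor allele as ALT, which round-trips
#' through [read_genotypes()].
#'
#' @param g a [geno_matrix()] with homozygous or heterozygous integer dosages.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(g, path) {
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosage)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(g$dosage))) {
    calls <- ifelse(is.na(g$dosage[, j]), "./.", gt[g$dosage[, j] + 1])
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$marker[j],
                       "A", "T", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a labelled square matrix (kinship, distance) as TSV
#' @param m square numeric matrix with dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
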