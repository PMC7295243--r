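#' Read genotype dosages from a delimited file or VCF
#'
#' Loads genotypes, removes SNPs below a minor-allele-frequency threshold,
#' mean-imputes missing dosages per SNP, orients every column to the minor
#' allele and returns SNPs sorted by `(chrom, pos)`.
#'
#' The delimited format is a TSV whose first column (`sample_id`) holds sample
#' identifiers and whose remaining header names are SNP ids, one row per
#' sample; a sidecar TSV (columns `snp_id`, `chrom`, `pos`, `ref`, `alt`)
#' carries the SNP metadata. For VCF input the `DS` FORMAT field is used when
#' present, otherwise dosages are counted from `GT`.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"vcf"`.
#' @param maf_min SNPs with minor-allele frequency below this are removed
#'   (default 0.05, the usual common-variant threshold).
#' @param sidecar path to the SNP metadata TSV (delimited format only;
#'   defaults to `<path>.snps.tsv`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf"),
                           maf_min = 0.05, sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    if (names(tab)[1] != "sample_id")
      stop("delimited genotype file must start with a sample_id column")
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- as.character(tab$sample_id)
    if (is.null(sidecar)) sidecar <- paste0(path, ".snps.tsv")
    if (!file.exists(sidecar)) stop("SNP sidecar not found: ", sidecar)
    info <- read.table(sidecar, header = TRUE, sep = "\t",
                       colClasses = c("character", "character", "integer",
                                      "character", "character"))
    info <- info[match(colnames(dos), info$snp_id), , drop = FALSE]
    if (anyNA(info$snp_id)) stop("sidecar is missing some SNP ids")
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
    if ("DS" %in% fmt) {
      dos <- t(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    } else if ("GT" %in% fmt) {
      gt <- vcfR::extract.gt(v, element = "GT")
      cnt <- function(g) {
        ifelse(is.na(g), NA_real_,
               vapply(strsplit(gsub("\\|", "/", g), "/"),
                      function(a) sum(a == "1"), numeric(1)))
      }
      dos <- t(apply(gt, 2, cnt))
      colnames(dos) <- rownames(gt)
    } else stop("VCF has neither GT nor DS fields")
    fix <- vcfR::getFIX(v)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    colnames(dos) <- ids
    info <- data.frame(snp_id = ids, chrom = as.character(fix[, "CHROM"]),
                       pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                       alt = fix[, "ALT"], stringsAsFactors = FALSE)
  }
  storage.mode(dos) <- "double"

  # mean-impute missing dosages per SNP
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      obs <- !is.na(dos[, j])
      if (!any(obs)) { dos[, j] <- 0 } else dos[!obs, j] <- mean(dos[obs, j])
    }
  }
  keep_var <- apply(dos, 2, function(x) var(x) > 0)
  if (any(!keep_var)) {
    warning(sprintf("dropped %d zero-variance SNP(s) after imputation",
                    sum(!keep_var)))
  }
  maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  keep <- keep_var & maf >= maf_min
  if (!any(keep)) stop("all SNPs removed by the MAF/variance filters")
  genotype_matrix(dos[, keep, drop = FALSE], chrom = info$chrom[keep],
                  pos = info$pos[keep], ref = info$ref[keep],
                  alt = info$alt[keep])
}

#' Write a genotype matrix to the delimited format
#'
#' Inverse of [read_genotypes()] for the delimited format; `read(write(G))`
#' reproduces the dosages bit-exactly.
#'
#' @param G a [genotype_matrix()].
#' @param path output TSV; the SNP sidecar is written to `<path>.snps.tsv`
#'   unless `sidecar` is given.
#' @param sidecar optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(path, ".snps.tsv")
  num <- apply(G$dosages, 2, function(x) sprintf("%.17g", x))  # lossless
  tab <- data.frame(sample_id = rownames(G$dosages), num,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", colnames(G$dosages))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(G$info[, c("snp_id", "chrom", "pos", "ref", "alt")], sidecar,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait (or covariate) table
#'
#' TSV with a header; the first column, `sample_id`, holds sample ids and the
#' remaining columns one trait each. Empty cells or `NA` mark missing values.
#'
#' @param path TSV file.
#' @param genes optional data frame of gene coordinates passed to
#'   [trait_matrix()].
#' @return A [trait_matrix()].
#' @export
read_traits <- function(path, genes = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("trait file must start with a sample_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$sample_id)
  trait_matrix(m, genes = genes)
}

#' @rdname read_traits
#' @return `read_covariates()`: a [covariate_table()].
#' @export
read_covariates <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("covariate file must start with a sample_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$sample_id)
  covariate_table(m)
}

#' @rdname write_genotypes
#' @param Y a [trait_matrix()] (for `write_traits`).
#' @export
write_traits <- function(Y, path) {
  num <- apply(Y$values, 2, function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  tab <- data.frame(sample_id = rownames(Y$values), num,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", colnames(Y$values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
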