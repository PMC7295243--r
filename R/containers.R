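#' Genotype dosage matrix with SNP metadata
#'
#' Container for an `n x p` matrix of expected minor-allele dosages (entries
#' in `[0, 2]`, fractional values allowed for imputed genotypes) together with
#' per-SNP metadata: identifier, chromosome, 1-based position, reference and
#' alternative allele, and minor-allele frequency. The stored MAF is always
#' recomputed from the dosages, so it cannot drift from the data.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; no
#'   missing values (impute before construction, see [read_genotypes()]).
#'   Row names are sample ids, column names SNP ids (generated if absent).
#' @param chrom,pos chromosome label and 1-based base-pair position per SNP.
#' @param ref,alt allele labels per SNP (defaults `"A"`/`"B"` when unknown).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (the matrix) and `info` (data frame with columns `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`), SNPs sorted by `(chrom, pos)`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  if (anyNA(dosages)) stop("dosages must not contain missing values")
  if (min(dosages) < -1e-9 || max(dosages) > 2 + 1e-9)
    stop("dosages must lie in [0, 2]")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp_%05d", seq_len(p))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("sample_%04d", seq_len(nrow(dosages)))
  if (length(chrom) != p || length(pos) != p)
    stop("chrom and pos must have one entry per SNP")
  if (any(pos < 0) || any(pos != round(pos)))
    stop("positions must be non-negative integers")
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("B", p)

  maf <- colMeans(dosages) / 2
  flip <- maf > 0.5
  if (any(flip)) {  # orient every column to the minor allele
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
    maf <- colMeans(dosages) / 2  # recompute so stored == recomputed exactly
  }
  info <- data.frame(snp_id = colnames(dosages), chrom = as.character(chrom),
                     pos = as.integer(pos), ref = ref, alt = alt, maf = maf,
                     stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(info$chrom, info$pos)
  structure(list(dosages = dosages[, ord, drop = FALSE],
                 info = info[ord, , drop = FALSE]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$info$chrom), collapse = ", ")))
  cat(sprintf("  MAF range: [%.3f, %.3f]\n",
              min(x$info$maf), max(x$info$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Trait matrix of molecular outcomes
#'
#' Container for an `n x q` matrix of continuous molecular levels (protein,
#' transcript or metabolite abundances). Missing values are allowed and kept
#' as an explicit observation mask; they are never imputed -- downstream
#' inference restricts every inner product to each trait's observed samples.
#' Optional gene coordinates per trait enable cis/trans annotation of hits.
#'
#' @param values numeric matrix, samples in rows, traits in columns; `NA`
#'   marks missing measurements. Row/column names as in [genotype_matrix()].
#' @param genes optional data frame with columns `trait_id`, `gene_chrom`,
#'   `gene_start`, `gene_end` (1-based, inclusive).
#'
#' @return An object of class `trait_matrix` with elements `values`, `mask`
#'   (logical, `TRUE` where observed) and `genes` (or `NULL`).
#' @export
trait_matrix <- function(values, genes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("trait_%03d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%04d", seq_len(nrow(values)))
  mask <- is.finite(values)
  if (any(colSums(mask) < 2))
    stop("each trait needs at least 2 observed values")
  values[!mask] <- NA_real_
  if (!is.null(genes)) {
    need <- c("trait_id", "gene_chrom", "gene_start", "gene_end")
    if (!all(need %in% names(genes)))
      stop("genes must have columns ", paste(need, collapse = ", "))
    genes <- genes[match(colnames(values), genes$trait_id), , drop = FALSE]
  }
  structure(list(values = values, mask = mask, genes = genes),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  nmis <- sum(!x$mask)
  cat(sprintf("trait_matrix: %d samples x %d traits (%d missing entries)\n",
              nrow(x$values), ncol(x$values), nmis))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Covariate table
#'
#' Sample-level covariates (e.g. age, sex indicator, BMI) used to adjust
#' traits before mapping. The design `[1, C]` must have full column rank.
#'
#' @param values numeric matrix or data frame, samples in rows.
#' @return Object of class `covariate_table` with element `values`.
#' @export
covariate_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("covariates must be complete")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("covar_%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%04d", seq_len(nrow(values)))
  d <- cbind(1, values)
  if (qr(d)$rank < ncol(d))
    stop("covariate design is rank-deficient after adding an intercept")
  structure(list(values = values), class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("covariate_table: %d samples x %d covariates (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' Align genotype, trait and covariate tables on shared samples
#'
#' Inner join on sample identifiers (row names); the number of shared
#' samples is reported. Order follows the genotype object.
#'
#' @param G a [genotype_matrix()].
#' @param Y optional [trait_matrix()].
#' @param C optional [covariate_table()].
#' @param quiet suppress the message.
#' @return List with the aligned `G`, and `Y`/`C` when given.
#' @export
align_samples <- function(G, Y = NULL, C = NULL, quiet = FALSE) {
  ids <- rownames(G$dosages)
  if (!is.null(Y)) ids <- intersect(ids, rownames(Y$values))
  if (!is.null(C)) ids <- intersect(ids, rownames(C$values))
  if (length(ids) == 0) stop("no samples shared across inputs")
  if (!quiet)
    message(sprintf("aligned %d shared samples", length(ids)))
  G$dosages <- G$dosages[ids, , drop = FALSE]
  out <- list(G = G)
  if (!is.null(Y)) {
    Y$values <- Y$values[ids, , drop = FALSE]
    Y$mask <- Y$mask[ids, , drop = FALSE]
    out$Y <- Y
  }
  if (!is.null(C)) {
    C$values <- C$values[ids, , drop = FALSE]
    out$C <- C
  }
  out
}
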