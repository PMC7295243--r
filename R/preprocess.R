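#' Center matrix columns on their observed entries
#'
#' Subtracts each column's mean computed over observed entries; missing
#' entries are left untouched. Both genotypes and traits are centered (never
#' variance-standardized) before model fitting, so effect sizes stay on the
#' per-minor-allele scale.
#'
#' @param M numeric matrix.
#' @param mask optional logical matrix marking observed entries; defaults to
#'   `is.finite(M)`.
#' @return Matrix of the same shape with observed column means zero.
#' @export
center_columns <- function(M, mask = NULL) {
  M <- as.matrix(M)
  if (length(M) == 0) stop("empty matrix")
  if (is.null(mask)) mask <- is.finite(M)
  if (any(colSums(mask) == 0)) stop("column with no observed entries")
  mu <- colSums(ifelse(mask, M, 0)) / colSums(mask)
  out <- sweep(M, 2, mu, "-")
  out[!mask] <- M[!mask]
  out
}

#' Residualize traits on covariates
#'
#' Replaces each trait by its least-squares residuals on `[1, C]`, computed
#' over that trait's observed samples. This is how covariate adjustment (age,
#' sex, BMI and similar) enters the workflow: the mapping model itself has no
#' covariate term, so traits are adjusted up front; genotypes are not.
#'
#' @param Y a [trait_matrix()].
#' @param C a [covariate_table()] with the same samples in the same order.
#' @return A [trait_matrix()] of residuals (gene coordinates preserved).
#' @export
residualize_covariates <- function(Y, C) {
  stopifnot(inherits(Y, "trait_matrix"), inherits(C, "covariate_table"))
  if (nrow(C$values) != nrow(Y$values))
    stop("trait and covariate tables have different sample counts")
  d <- cbind(`(Intercept)` = 1, C$values)
  if (qr(d)$rank < ncol(d)) stop("rank-deficient covariate design")
  vals <- Y$values
  for (t in seq_len(ncol(vals))) {
    obs <- Y$mask[, t]
    if (sum(obs) <= ncol(d))
      stop(sprintf("trait %s has too few observations (%d) for %d covariates",
                   colnames(vals)[t], sum(obs), ncol(d) - 1L))
    fit <- lm.fit(d[obs, , drop = FALSE], vals[obs, t])
    vals[obs, t] <- fit$residuals
  }
  trait_matrix(vals, genes = Y$genes)
}

#' Greedy windowed LD pruning
#'
#' Scans SNPs in position order within each chromosome and keeps a SNP unless
#' its squared Pearson correlation with an already-kept SNP closer than
#' `window_bp` exceeds `r2_max`. The greedy position order makes the retained
#' set deterministic and stable under appending duplicates of kept SNPs, and
#' emulates the tag-SNP panels produced by the usual pruning tools.
#'
#' @param G a [genotype_matrix()] (position-sorted, as the class guarantees).
#' @param r2_max squared-correlation threshold in `(0, 1]` (default 0.95,
#'   a light pruning that removes near-duplicate markers only).
#' @param window_bp comparison window in base pairs (default 1 Mb).
#' @return A pruned [genotype_matrix()].
#' @export
ld_prune <- function(G, r2_max = 0.95, window_bp = 1e6) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  keep <- logical(ncol(G$dosages))
  for (ch in unique(G$info$chrom)) {
    idx <- which(G$info$chrom == ch)
    kept <- integer(0)
    for (j in idx) {
      near <- kept[G$info$pos[j] - G$info$pos[kept] <= window_bp]
      ok <- TRUE
      if (length(near)) {
        r2 <- cor(G$dosages[, j], G$dosages[, near, drop = FALSE])^2
        ok <- all(r2 <= r2_max, na.rm = TRUE)
      }
      if (ok) {
        keep[j] <- TRUE
        kept <- c(kept, j)
      }
    }
  }
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  chrom = G$info$chrom[keep], pos = G$info$pos[keep],
                  ref = G$info$ref[keep], alt = G$info$alt[keep])
}
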