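#' Univariate association scan (single-pair OLS comparator)
#'
#' The standard single-pair baseline: for every SNP-trait pair, an ordinary
#' least-squares regression of the (covariate-residualized) trait on the SNP
#' dosage with a two-sided Wald test, restricted to the trait's observed
#' samples. Fully vectorized but numerically identical to fitting each pair
#' with [lm()]. Simulated cohorts are unrelated, so no relatedness
#' correction is needed here.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param Y a [trait_matrix()] or trait matrix (`NA` allowed).
#' @param covariates optional [covariate_table()]; traits are residualized
#'   on it first.
#' @return List of class `univariate_scan` with p x q matrices `effect`,
#'   `se`, `p_value`, logical `flagged` (zero-variance SNP-trait pairs, for
#'   which the effect is 0 and the p-value 1) and `df`.
#' @export
univariate_scan <- function(G, Y, covariates = NULL) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (!inherits(Y, "trait_matrix")) Y <- trait_matrix(as.matrix(Y))
  if (!is.null(covariates)) {
    if (!inherits(covariates, "covariate_table"))
      covariates <- covariate_table(as.matrix(covariates))
    Y <- residualize_covariates(Y, covariates)
  }
  if (nrow(X) != nrow(Y$values)) stop("sample counts differ")
  M <- Y$mask * 1
  Y0 <- ifelse(Y$mask, Y$values, 0)
  nt <- colSums(M)

  Sx <- crossprod(X, M)            # p x q sums of x over observed samples
  Sxx <- crossprod(X^2, M)
  Sxy <- crossprod(X, Y0)
  Sy <- matrix(colSums(Y0), nrow(Sx), ncol(Sx), byrow = TRUE)
  Syy <- matrix(colSums(Y0^2), nrow(Sx), ncol(Sx), byrow = TRUE)
  Nt <- matrix(nt, nrow(Sx), ncol(Sx), byrow = TRUE)

  Sxx_c <- Sxx - Sx^2 / Nt
  Sxy_c <- Sxy - Sx * Sy / Nt
  Syy_c <- Syy - Sy^2 / Nt
  bad <- Sxx_c <= 1e-12
  Sxx_c[bad] <- 1

  slope <- Sxy_c / Sxx_c
  rss <- pmax(Syy_c - slope * Sxy_c, 0)
  df <- Nt - 2
  se <- sqrt(rss / df / Sxx_c)
  tstat <- slope / se
  pval <- 2 * pt(-abs(tstat), df)
  slope[bad] <- 0; se[bad] <- NA_real_; pval[bad] <- 1
  pval[!is.finite(pval)] <- 1
  dn <- list(colnames(X), colnames(Y$values))
  dimnames(slope) <- dimnames(se) <- dimnames(pval) <- dn
  structure(list(effect = slope, se = se, p_value = pval, flagged = bad,
                 df = df),
            class = "univariate_scan")
}

#' Truncated standardized partial AUC
#'
#' Trapezoidal partial area under the ROC curve over false-positive rates in
#' `[0, fpr_max]`, rescaled (McClish standardization) so a perfect ranking
#' scores 1 and chance scores 0.5 in expectation:
#' \deqn{\frac{1}{2}\left(1 + \frac{pAUC - pAUC_{min}}{pAUC_{max} -
#' pAUC_{min}}\right)}
#' with \eqn{pAUC_{max} = f} and \eqn{pAUC_{min} = f^2/2} at truncation
#' point \eqn{f}. With `fpr_max = 1` this equals the full Mann-Whitney AUC.
#' Ties in the scores are handled as single operating points (diagonal ROC
#' segments).
#'
#' @param scores numeric ranking scores (larger = more strongly called).
#' @param truth logical (or 0/1) ground-truth labels, same length.
#' @param fpr_max truncation point in `(0, 1]` (default 0.05: only the
#'   low-false-positive regime a QTL study operates in).
#' @return Standardized partial AUC in `[0, 1]`.
#' @export
standardized_pauc <- function(scores, truth, fpr_max = 0.05) {
  scores <- as.numeric(scores); truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), fpr_max > 0, fpr_max <= 1)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("truth must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; tr <- truth[ord]
  # operating points: one per distinct score value
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(tr); fp <- cumsum(!tr)
  at <- which(diff(c(grp, Inf)) != 0)  # last index of each tie group
  fpr <- c(0, fp[at] / n0)
  tpr <- c(0, tp[at] / n1)
  # clip the polyline at fpr_max (linear interpolation)
  if (max(fpr) > fpr_max) {
    j <- which(fpr > fpr_max)[1]
    w <- (fpr_max - fpr[j - 1]) / (fpr[j] - fpr[j - 1])
    fpr <- c(fpr[1:(j - 1)], fpr_max)
    tpr <- c(tpr[1:(j - 1)], tpr[j - 1] + w * (tpr[j] - tpr[j - 1]))
  } else if (max(fpr) < fpr_max) {
    fpr <- c(fpr, fpr_max); tpr <- c(tpr, max(tpr))
  }
  pauc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  pmin_ <- fpr_max^2 / 2
  pmax_ <- fpr_max
  0.5 * (1 + (pauc - pmin_) / (pmax_ - pmin_))
}

# matched 95% normal-approximation CI half-width used in benchmark reports
ci_half <- function(x) 1.96 * sd(x) / sqrt(length(x))

#' Replicate power benchmark: joint model vs univariate scan
#'
#' Generates one genotype panel from the design, then for each replicate
#' redraws the causal pattern, effect sizes and trait levels (genotypes are
#' held fixed across replicates), runs the requested methods, scores every
#' SNP-trait pair (posterior inclusion probability for the joint model,
#' `1 - p` for the univariate scan) and computes the truncated standardized
#' partial AUC against the simulated truth.
#'
#' @param design a [simulation_design()].
#' @param methods subset of `c("joint", "univariate")` (`"joint"` is the
#'   multivariate spike-and-slab fit).
#' @param replicates number of replicates (`>= 2`).
#' @param seed master seed; every replicate's seeds derive from it.
#' @param fpr_max truncation point(s) for [standardized_pauc()]; the first
#'   is used for the summary, all are reported per replicate.
#' @param control [jqtl_control()] for the joint fits.
#' @return Object of class `power_benchmark`: `summary` (per-method mean
#'   pAUC with 95% normal-approximation confidence half-widths), `pauc`
#'   (replicate x method x fpr_max array), `design`, `seed`.
#' @export
run_power_benchmark <- function(design, methods = c("joint", "univariate"),
                                replicates = 10, seed = design$seed,
                                fpr_max = 0.05,
                                control = jqtl_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 2)
  G <- simulate_genotypes(design, seed = seed)
  pauc <- array(NA_real_, c(replicates, length(methods), length(fpr_max)),
                dimnames = list(NULL, methods, paste0("fpr", fpr_max)))
  for (r in seq_len(replicates)) {
    base <- seed + 1000L * r
    pat <- simulate_pattern(design, seed = base + 1L)
    st <- simulate_traits(G, pat, design, seed = base + 2L)
    for (m in methods) {
      score <- if (m == "joint") {
        jqtl(G, st$traits, control = control)$ppi
      } else {
        1 - univariate_scan(G, st$traits)$p_value
      }
      for (k in seq_along(fpr_max))
        pauc[r, m, k] <- standardized_pauc(score, st$truth$gamma,
                                           fpr_max = fpr_max[k])
    }
  }
  sm <- do.call(rbind, lapply(methods, function(m) {
    x <- pauc[, m, 1]
    data.frame(method = m, mean_pauc = mean(x), ci_half = ci_half(x),
               ci_lo = mean(x) - ci_half(x), ci_hi = mean(x) + ci_half(x),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = sm, pauc = pauc, fpr_max = fpr_max,
                 replicates = replicates, design = design, seed = seed),
            class = "power_benchmark")
}

#' @export
print.power_benchmark <- function(x, ...) {
  cat(sprintf("Power benchmark: %d replicates, fpr_max = %s\n",
              x$replicates, paste(x$fpr_max, collapse = "/")))
  cat(sprintf("  design: n = %d, p = %d, q = %d, %d causal SNPs x %d traits\n",
              x$design$n, x$design$p, x$design$q, x$design$n_active_snps,
              x$design$n_active_traits))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s mean standardized pAUC %.3f +/- %.3f\n",
                s$method[i], s$mean_pauc[i], s$ci_half[i]))
  invisible(x)
}

#' Batch-split power study
#'
#' Quantifies the benefit of modelling all traits jointly: the traits are
#' randomly partitioned into batches of size `q0`, the joint model is fitted
#' independently on each batch, the posterior inclusion probabilities are
#' pooled back into one p x q matrix, and selection performance is measured
#' by the full-range standardized AUC. `q0 = 1` is a per-trait univariate
#' spike-and-slab fit with no cross-trait sharing; `q0 = q` is the usual
#' fully joint fit.
#'
#' @param design a [simulation_design()].
#' @param batch_sizes trait-batch sizes; defaults to
#'   `c(1, 8, 33, design$q)`.
#' @param replicates replicates (pattern and traits redrawn; genotypes
#'   fixed).
#' @param seed master seed.
#' @param control [jqtl_control()] applied to every batch fit.
#' @return Object of class `batch_split`: `summary` (per-`q0` mean AUC with
#'   95% CI half-width), `auc` (replicate x q0 matrix), `design`, `seed`.
#' @export
batch_split_experiment <- function(design,
                                   batch_sizes = c(1, 8, 33, design$q),
                                   replicates = 20, seed = design$seed,
                                   control = jqtl_control()) {
  batch_sizes <- sort(unique(as.integer(batch_sizes)))
  if (any(batch_sizes > design$q)) stop("batch size exceeds trait count")
  if (any(batch_sizes < 1)) stop("batch sizes must be >= 1")
  G <- simulate_genotypes(design, seed = seed)
  auc <- matrix(NA_real_, replicates, length(batch_sizes),
                dimnames = list(NULL, paste0("q0_", batch_sizes)))
  q <- design$q
  Xc <- sweep(G$dosages, 2, colMeans(G$dosages))
  for (r in seq_len(replicates)) {
    base <- seed + 1000L * r
    pat <- simulate_pattern(design, seed = base + 1L)
    st <- simulate_traits(G, pat, design, seed = base + 2L)
    Yc <- center_columns(st$traits$values, st$traits$mask)
    for (k in seq_along(batch_sizes)) {
      q0 <- batch_sizes[k]
      set.seed(base + 3L + k)
      # a single full batch is exactly the ordinary joint fit
      perm <- if (q0 == q) seq_len(q) else sample.int(q)
      ppi <- matrix(NA_real_, design$p, q)
      for (b in split(perm, ceiling(seq_along(perm) / q0))) {
        fit <- jqtl_fit_centered(Xc, Yc[, b, drop = FALSE],
                                 control = control)
        ppi[, b] <- fit$ppi
      }
      auc[r, k] <- standardized_pauc(ppi, st$truth$gamma, fpr_max = 1)
    }
  }
  sm <- data.frame(q0 = batch_sizes, mean_auc = colMeans(auc),
                   ci_half = apply(auc, 2, ci_half), row.names = NULL)
  sm$ci_lo <- sm$mean_auc - sm$ci_half
  sm$ci_hi <- sm$mean_auc + sm$ci_half
  structure(list(summary = sm, auc = auc, design = design, seed = seed,
                 replicates = replicates),
            class = "batch_split")
}

#' @export
print.batch_split <- function(x, ...) {
  cat(sprintf("Batch-split study: %d replicates\n", x$replicates))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  q0 = %3d traits/batch: mean standardized AUC %.3f +/- %.3f\n",
                s$q0[i], s$mean_auc[i], s$ci_half[i]))
  invisible(x)
}
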