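#' Bayesian FDR selection from posterior inclusion probabilities
#'
#' Sorts all SNP-trait pairs by decreasing posterior inclusion probability
#' and estimates the false discovery rate of the top-`k` set as the mean of
#' `1 - PPI` over that set; the selection is the largest set whose estimate
#' stays at or below `level`. Raising `level` can only enlarge the selection.
#'
#' @param ppi a p x q matrix of posterior inclusion probabilities, or a
#'   [jqtl()] fit (whose SNP metadata and effects are then carried along).
#' @param level FDR level in `(0, 1)` (default 0.05).
#' @return A hit-table data frame, one row per selected pair, with columns
#'   `snp_id`, `trait_id`, `ppi`, `fdr_at_selection` (the running estimate at
#'   that rank), `stage = "discovery"`, plus `chrom`, `pos`, `beta_mean` when
#'   available. Zero rows is a valid outcome.
#' @export
bayesian_fdr_select <- function(ppi, level = 0.05) {
  stopifnot(level > 0, level < 1)
  fit <- NULL
  if (inherits(ppi, "jqtl")) { fit <- ppi; ppi <- fit$ppi }
  ppi <- as.matrix(ppi)
  if (any(ppi < 0 | ppi > 1)) stop("PPIs must lie in [0, 1]")
  if (is.null(rownames(ppi))) rownames(ppi) <- sprintf("snp_%05d", seq_len(nrow(ppi)))
  if (is.null(colnames(ppi))) colnames(ppi) <- sprintf("trait_%03d", seq_len(ncol(ppi)))

  ord <- order(ppi, decreasing = TRUE)
  run_fdr <- cumsum(1 - ppi[ord]) / seq_along(ord)
  k <- which(run_fdr <= level)
  k <- if (length(k)) max(k) else 0L
  sel <- ord[seq_len(k)]
  idx <- arrayInd(sel, dim(ppi))
  out <- data.frame(snp_id = rownames(ppi)[idx[, 1]],
                    trait_id = colnames(ppi)[idx[, 2]],
                    ppi = ppi[sel], fdr_at_selection = run_fdr[seq_len(k)],
                    stage = rep("discovery", k),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(fit)) {
    out$beta_mean <- fit$beta_mean[sel]
    if (!is.null(fit$snp_info)) {
      m <- match(out$snp_id, fit$snp_info$snp_id)
      out$chrom <- fit$snp_info$chrom[m]
      out$pos <- fit$snp_info$pos[m]
    }
  }
  out
}

#' Replicate discovered pairs in an independent cohort
#'
#' Two-stage validation: each discovered SNP-trait pair is re-tested in the
#' replication cohort by an ordinary least-squares regression of the
#' (covariate-residualized) trait on the SNP dosage with a two-sided Wald
#' test; Benjamini-Hochberg adjustment is applied across exactly the
#' discovered pairs, and pairs with adjusted p at or below `level` are
#' flagged validated.
#'
#' @param discovery hit table from [bayesian_fdr_select()].
#' @param G2 replication-cohort [genotype_matrix()].
#' @param Y2 replication-cohort [trait_matrix()].
#' @param C2 optional replication [covariate_table()].
#' @param level FDR level for validation (default 0.05).
#' @return The discovery table augmented with `effect_rep`, `se_rep`,
#'   `p_value`, `p_adj`, `validated` and `stage = "replication"`. Pairs whose
#'   SNP or trait is absent (or whose SNP has zero variance) in the
#'   replication data are dropped with a warning.
#' @export
replicate_hits <- function(discovery, G2, Y2, C2 = NULL, level = 0.05) {
  stopifnot(level > 0, level < 1)
  if (nrow(discovery) == 0) {
    discovery$p_value <- discovery$p_adj <- numeric(0)
    discovery$validated <- logical(0)
    return(discovery)
  }
  if (!is.null(C2)) Y2 <- residualize_covariates(Y2, C2)
  ok <- discovery$snp_id %in% colnames(G2$dosages) &
        discovery$trait_id %in% colnames(Y2$values)
  zv <- apply(G2$dosages, 2, var) == 0
  ok <- ok & !(discovery$snp_id %in% colnames(G2$dosages)[zv])
  if (any(!ok))
    warning(sprintf("%d pair(s) unresolvable or zero-variance in replication",
                    sum(!ok)))
  out <- discovery[ok, , drop = FALSE]
  n <- nrow(out)
  eff <- se <- pv <- numeric(n)
  for (i in seq_len(n)) {
    x <- G2$dosages[, out$snp_id[i]]
    y <- Y2$values[, out$trait_id[i]]
    obs <- is.finite(y)
    f <- summary(lm(y[obs] ~ x[obs]))$coefficients
    eff[i] <- f[2, 1]; se[i] <- f[2, 2]; pv[i] <- f[2, 4]
  }
  out$effect_rep <- eff; out$se_rep <- se
  out$p_value <- pv
  out$p_adj <- p.adjust(pv, method = "BH")
  out$validated <- out$p_adj <= level
  out$stage <- "replication"
  out
}

#' Merge hits into loci
#'
#' Chains, per trait and chromosome, consecutive position-sorted hits into a
#' single locus while the gap between consecutive hits is at most `max_gap`
#' (1 Mb by default, inclusive). The locus sentinel is the member with the
#' largest PPI, ties broken by smaller position. Merging is idempotent and
#' ignores the input row order.
#'
#' @param hits hit table with columns `snp_id`, `trait_id`, `chrom`, `pos`
#'   and a score column `ppi`.
#' @param max_gap maximum base-pair gap between consecutive hits of one
#'   locus.
#' @return Locus-table data frame: `locus_id`, `trait_id`, `chrom`, `start`,
#'   `end`, `sentinel_snp`, `sentinel_pos`, `sentinel_ppi`, `n_snps`,
#'   `member_snps` (comma-separated).
#' @export
merge_loci <- function(hits, max_gap = 1e6) {
  need <- c("snp_id", "trait_id", "chrom", "pos")
  if (!all(need %in% names(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "))
  if (nrow(hits) == 0)
    return(data.frame(locus_id = character(0), trait_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), sentinel_snp = character(0),
                      sentinel_pos = integer(0), sentinel_ppi = numeric(0),
                      n_snps = integer(0), member_snps = character(0)))
  hits <- unique(hits[, intersect(c(need, "ppi"), names(hits))])
  hits <- hits[order(hits$trait_id, hits$chrom, hits$pos), , drop = FALSE]
  out <- do.call(rbind, lapply(
    split(hits, list(hits$trait_id, hits$chrom), drop = TRUE),
    function(h) {
      brk <- c(0, cumsum(diff(h$pos) > max_gap))
      do.call(rbind, lapply(split(h, brk), function(g) {
        sc <- if ("ppi" %in% names(g)) g$ppi else rep(0, nrow(g))
        sent <- order(-sc, g$pos)[1]
        data.frame(trait_id = g$trait_id[1], chrom = g$chrom[1],
                   start = min(g$pos), end = max(g$pos),
                   sentinel_snp = g$snp_id[sent], sentinel_pos = g$pos[sent],
                   sentinel_ppi = sc[sent], n_snps = nrow(g),
                   member_snps = paste(g$snp_id, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    }))
  out <- out[order(out$trait_id, out$chrom, out$start), , drop = FALSE]
  out$locus_id <- sprintf("locus_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus_id", "trait_id", "chrom", "start", "end", "sentinel_snp",
          "sentinel_pos", "sentinel_ppi", "n_snps", "member_snps")]
}

#' Classify loci as cis or trans
#'
#' A locus is *cis* when its sentinel SNP lies on the chromosome of the gene
#' encoding the controlled trait and within `margin` (1 Mb, inclusive at the
#' boundary) of the gene body `[gene_start, gene_end]`; otherwise *trans*.
#' Traits without gene coordinates are classified `unknown`.
#'
#' @param loci locus table from [merge_loci()].
#' @param genes data frame with columns `trait_id`, `gene_chrom`,
#'   `gene_start`, `gene_end`.
#' @param margin cis window in base pairs (default 1 Mb).
#' @return `loci` with a `cis_trans` column.
#' @export
classify_cis_trans <- function(loci, genes, margin = 1e6) {
  m <- match(loci$trait_id, genes$trait_id)
  ct <- rep("unknown", nrow(loci))
  has <- !is.na(m)
  same <- has & as.character(loci$chrom) ==
    as.character(genes$gene_chrom[m])
  within <- same &
    loci$sentinel_pos >= genes$gene_start[m] - margin &
    loci$sentinel_pos <= genes$gene_end[m] + margin
  ct[has] <- ifelse(within[has], "cis", "trans")
  loci$cis_trans <- ct
  loci
}

#' Export loci as BED
#'
#' Writes the locus table in BED format; the 1-based inclusive coordinates
#' are converted to BED's 0-based half-open convention at export.
#'
#' @param loci locus table from [merge_loci()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
loci_to_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L,
                    end = loci$end, name = paste0(loci$locus_id, "_",
                                                  loci$trait_id))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Resampling-based enrichment test
#'
#' Draws `B` random subsets of the universe with the size of the selected
#' set, evaluates the set statistic on each, and returns the add-one
#' empirical p-value `(1 + #resamples >= observed) / (B + 1)`.
#'
#' @param selected_ids selected identifiers (subset of `universe_ids`).
#' @param universe_ids identifiers to resample from.
#' @param statistic function mapping a character vector of ids to a number.
#' @param B number of resamples (default `1e5`).
#' @param seed integer seed for reproducibility.
#' @return List with `p_value`, `observed`, `B` and the resampled null
#'   statistics.
#' @export
resampling_enrichment <- function(selected_ids, universe_ids, statistic,
                                  B = 1e5, seed = 1L) {
  selected_ids <- unique(selected_ids)
  universe_ids <- unique(universe_ids)
  if (!all(selected_ids %in% universe_ids))
    stop("selected ids must be a subset of the universe")
  if (B < 1) stop("B must be >= 1")
  obs <- statistic(selected_ids)
  set.seed(seed)
  null <- vapply(seq_len(B), function(i)
    statistic(sample(universe_ids, length(selected_ids))), numeric(1))
  list(p_value = (1 + sum(null >= obs)) / (B + 1), observed = obs, B = B,
       null = null)
}
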