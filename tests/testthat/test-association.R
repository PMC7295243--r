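test_that("Bayesian FDR selection reproduces the running-estimate example", {
  ppi <- matrix(c(0.99, 0.98, 0.90, 0.50), 4, 1)
  hits <- bayesian_fdr_select(ppi, level = 0.05)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$ppi, c(0.99, 0.98, 0.90))
  expect_equal(hits$fdr_at_selection, c(0.010, 0.015, 0.13 / 3),
               tolerance = 1e-12)
  # the 4th pair would push the estimate to 0.1575 > 0.05
  expect_equal(mean(1 - ppi), 0.1575)

  all1 <- bayesian_fdr_select(matrix(1, 2, 2), level = 0.05)
  expect_equal(nrow(all1), 4L)
  expect_equal(all1$fdr_at_selection, rep(0, 4))

  none <- bayesian_fdr_select(matrix(0.5, 3, 3), level = 0.05)
  expect_equal(nrow(none), 0L)
})

test_that("FDR selection is monotone in the level", {
  set.seed(20)
  ppi <- matrix(runif(200), 20, 10)
  prev <- 0
  for (lev in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    k <- nrow(bayesian_fdr_select(ppi, level = lev))
    expect_gte(k, prev)
    prev <- k
  }
})

test_that("replication applies BH across discovered pairs only", {
  # hand-computed BH example via an explicit discovery table
  set.seed(21)
  n <- 200
  X <- matrix(rbinom(3 * n, 2, 0.3), n, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  B <- c(0.35, 0.3, 0.02)
  Y <- sapply(1:3, function(j) B[j] * X[, j] + rnorm(n))
  colnames(Y) <- c("t1", "t2", "t3")
  G2 <- toy_genotypes(X)
  Y2 <- trait_matrix(Y)
  disc <- data.frame(snp_id = c("s1", "s2", "s3"),
                     trait_id = c("t1", "t2", "t3"),
                     ppi = c(0.99, 0.98, 0.97), stage = "discovery")
  rep_ <- replicate_hits(disc, G2, Y2, level = 0.05)
  expect_equal(rep_$p_adj, p.adjust(rep_$p_value, "BH"))
  # oracle per-pair regression agrees
  or <- lm_scan(X, Y)
  expect_equal(rep_$p_value, diag(or$p_value), tolerance = 1e-10)
  expect_equal(rep_$effect_rep, diag(or$effect), tolerance = 1e-10)

  # BH arithmetic on fixed p-values
  expect_equal(p.adjust(c(0.01, 0.02, 0.2), "BH"), c(0.03, 0.03, 0.2))
  # single test: BH is the identity
  one <- replicate_hits(disc[1, ], G2, Y2, level = 0.05)
  expect_equal(one$p_adj, one$p_value)
  expect_true(one$validated)
})

test_that("unresolvable or zero-variance pairs are dropped with a warning", {
  n <- 50
  X <- cbind(s1 = rbinom(n, 2, 0.4), s2 = rep(1, n))
  X[1, 2] <- 1  # keep zero variance
  G2 <- genotype_matrix(X, chrom = c("1", "1"), pos = c(1, 2))
  Y2 <- trait_matrix(cbind(t1 = rnorm(n)))
  disc <- data.frame(snp_id = c("s1", "s2", "missing"),
                     trait_id = c("t1", "t1", "t1"),
                     ppi = c(0.9, 0.9, 0.9), stage = "discovery")
  expect_warning(rep_ <- replicate_hits(disc, G2, Y2), "unresolvable")
  expect_equal(rep_$snp_id, "s1")
})

test_that("replication favors true over false discoveries in simulation", {
  set.seed(22)
  rate_true <- rate_false <- numeric(0)
  for (s in 1:8) {
    d <- simulation_design(n = 250, p = 120, q = 8, n_active_snps = 3,
                           n_active_traits = 4, ld_rho = 0,
                           max_trait_pve = 0.3, seed = 400 + s)
    G1 <- simulate_genotypes(d, seed = d$seed)
    G2 <- simulate_genotypes(d, seed = d$seed + 50L)
    pat <- simulate_pattern(d, seed = d$seed + 1L)
    st1 <- simulate_traits(G1, pat, d, seed = d$seed + 2L)
    st2 <- simulate_traits(G2, pat, d, seed = d$seed + 3L)
    ids <- expand.grid(snp = colnames(G1$dosages),
                       trait = colnames(st1$traits$values))
    # mixed discovery set: all causal pairs plus random null pairs
    idx <- which(pat$gamma, arr.ind = TRUE)
    caus <- data.frame(snp_id = colnames(G1$dosages)[idx[, 1]],
                       trait_id = colnames(st1$traits$values)[idx[, 2]])
    nll <- which(!pat$gamma, arr.ind = TRUE)
    nll <- nll[sample(nrow(nll), nrow(caus)), , drop = FALSE]
    null <- data.frame(snp_id = colnames(G1$dosages)[nll[, 1]],
                       trait_id = colnames(st1$traits$values)[nll[, 2]])
    disc <- rbind(cbind(caus, truth = TRUE), cbind(null, truth = FALSE))
    disc$ppi <- 0.9; disc$stage <- "discovery"
    rep_ <- replicate_hits(disc, G2, st2$traits, level = 0.05)
    rate_true <- c(rate_true, mean(rep_$validated[rep_$truth]))
    rate_false <- c(rate_false, mean(rep_$validated[!rep_$truth]))
  }
  expect_gt(mean(rate_true), mean(rate_false))
})

test_that("locus merging chains hits within the gap and picks sentinels", {
  hits <- data.frame(
    snp_id = c("a", "b", "c"), trait_id = "t1", chrom = "1",
    pos = c(1.0e6, 1.9e6, 3.5e6), ppi = c(0.95, 0.99, 0.97))
  loci <- merge_loci(hits, max_gap = 1e6)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(1.0e6, 3.5e6))
  expect_equal(loci$end, c(1.9e6, 3.5e6))
  expect_equal(loci$sentinel_snp, c("b", "c"))

  # single hit is its own sentinel
  l1 <- merge_loci(hits[1, ])
  expect_equal(l1$sentinel_snp, "a")
  expect_equal(l1$n_snps, 1L)

  # same positions, different traits: never merged
  h2 <- hits; h2$trait_id <- c("t1", "t2", "t1")
  expect_equal(nrow(merge_loci(h2, max_gap = 5e6)), 2L)

  # gap of exactly max_gap merges (inclusive boundary)
  h3 <- data.frame(snp_id = c("a", "b"), trait_id = "t", chrom = "1",
                   pos = c(1e6, 2e6), ppi = c(0.9, 0.8))
  expect_equal(nrow(merge_loci(h3, max_gap = 1e6)), 1L)

  # sentinel ties broken by smaller position
  h4 <- data.frame(snp_id = c("a", "b"), trait_id = "t", chrom = "1",
                   pos = c(10, 20), ppi = c(0.9, 0.9))
  expect_equal(merge_loci(h4)$sentinel_snp, "a")

  # idempotent and row-order invariant
  sh <- hits[c(3, 1, 2), ]
  expect_equal(merge_loci(sh), loci)
})

test_that("cis/trans classification uses the inclusive 1 Mb window", {
  loci <- data.frame(locus_id = "l1", trait_id = "t1", chrom = "1",
                     start = 5e6, end = 5e6, sentinel_snp = "s",
                     sentinel_pos = 5e6)
  genes <- data.frame(trait_id = "t1", gene_chrom = "1",
                      gene_start = 5.5e6, gene_end = 5.6e6)
  # inside window
  expect_equal(classify_cis_trans(loci, genes)$cis_trans, "cis")
  # exactly 1 Mb upstream of gene_start: inclusive -> cis
  loci$sentinel_pos <- 5.5e6 - 1e6
  expect_equal(classify_cis_trans(loci, genes)$cis_trans, "cis")
  # 1 bp beyond
  loci$sentinel_pos <- 5.5e6 - 1e6 - 1
  expect_equal(classify_cis_trans(loci, genes)$cis_trans, "trans")
  # other chromosome
  genes$gene_chrom <- "2"
  expect_equal(classify_cis_trans(loci, genes)$cis_trans, "trans")
  # no coordinates
  genes$trait_id <- "other"
  expect_equal(classify_cis_trans(loci, genes)$cis_trans, "unknown")
})

test_that("BED export converts to 0-based half-open coordinates", {
  loci <- data.frame(locus_id = "l1", trait_id = "t1", chrom = "1",
                     start = 100, end = 200, sentinel_snp = "s",
                     sentinel_pos = 150)
  path <- withr::local_tempfile(fileext = ".bed")
  loci_to_bed(loci, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 99)
  expect_equal(bed$V3, 200)
})

test_that("resampling enrichment matches the hypergeometric tail", {
  target <- paste0("g", 1:5)
  universe <- paste0("g", 1:20)
  stat <- function(ids) length(intersect(ids, target))
  # statistic maximal for the target set itself
  res <- resampling_enrichment(target, universe, stat, B = 999, seed = 3)
  # P(overlap of a random 5-set with the 5-target >= 5) = 1/C(20,5) ~ 6e-5,
  # so with B = 999 the add-one estimate is 1/1000 (possibly 2/1000)
  expect_lte(res$p_value, 2 / 1000)
  expect_gte(res$p_value, 1 / 1000)

  # constant statistic -> p = 1
  resc <- resampling_enrichment(target, universe, function(ids) 1,
                                B = 99, seed = 1)
  expect_equal(resc$p_value, 1)

  # moderate overlap case against the exact tail, within 3 MC SEs
  sel <- paste0("g", c(1, 2, 3, 6, 7))  # overlap 3 with target
  resm <- resampling_enrichment(sel, universe, stat, B = 10000, seed = 7)
  tail_exact <- sum(dhyper(3:5, 5, 15, 5))
  mc_se <- sqrt(tail_exact * (1 - tail_exact) / 10000)
  expect_lt(abs(resm$p_value - tail_exact), 3 * mc_se + 2e-4)

  expect_error(resampling_enrichment(c("zz"), universe, stat), "subset")
})
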