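#' Design of a synthetic joint-QTL study
#'
#' Collects every knob of the generator. The defaults emulate a
#' proteomic-QTL discovery cohort: n = 376 samples, p = 20,900 SNPs on one
#' chromosome with block LD, q = 133 block-correlated trait levels,
#' associations between 20 causal SNPs and 25 controlled traits, per-pair
#' variance explained drawn from Beta(2, 5) and rescaled so no trait has
#' more than 35% of its variance under genetic control.
#'
#' @param n,p,q sample, SNP and trait counts.
#' @param maf_range minor-allele-frequency interval (uniform draw per SNP).
#' @param ld_block_size,ld_rho SNPs per LD block and latent AR(1)
#'   autocorrelation within a block (0 = independent SNPs).
#' @param n_active_snps,n_active_traits causal SNPs and controlled traits.
#' @param pleiotropy_shape Beta shape pair for the (scaled) degree of
#'   pleiotropy of each causal SNP; the default `(1, 4)` is right-skewed so
#'   only a few SNPs are hotspots.
#' @param pve_shape Beta shape pair for per-association variance explained;
#'   the default `(2, 5)` favours small effects.
#' @param max_trait_pve cap on each trait's total genetic variance.
#' @param residual_correlation either a q x q correlation matrix or a list
#'   `list(block_size =, rho =)` describing block-equicorrelated trait
#'   residuals (default: blocks of 15 at correlation 0.4).
#' @param missing_rate optional MCAR missingness rate injected into traits.
#' @param spacing_bp base-pair distance between adjacent SNPs.
#' @param seed master seed stored with the design.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n = 376, p = 20900, q = 133,
                              maf_range = c(0.05, 0.5), ld_block_size = 20,
                              ld_rho = 0.85, n_active_snps = 20,
                              n_active_traits = 25,
                              pleiotropy_shape = c(1, 4),
                              pve_shape = c(2, 5), max_trait_pve = 0.35,
                              residual_correlation = list(block_size = 15,
                                                          rho = 0.4),
                              missing_rate = 0, spacing_bp = 5000,
                              seed = 1L) {
  stopifnot(n >= 2, p >= 1, q >= 1, n_active_snps <= p,
            n_active_traits <= q, max_trait_pve > 0, max_trait_pve < 1,
            ld_rho >= 0, ld_rho < 1, ld_block_size >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], missing_rate >= 0,
            missing_rate < 1)
  if (n_active_snps == 0 && n_active_traits > 0)
    stop("active traits require at least one active SNP")
  structure(list(n = n, p = p, q = q, maf_range = maf_range,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 n_active_snps = n_active_snps,
                 n_active_traits = n_active_traits,
                 pleiotropy_shape = pleiotropy_shape, pve_shape = pve_shape,
                 max_trait_pve = max_trait_pve,
                 residual_correlation = residual_correlation,
                 missing_rate = missing_rate, spacing_bp = spacing_bp,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate genotype dosages with LD blocks under Hardy-Weinberg equilibrium
#'
#' Each SNP's minor-allele frequency is drawn uniformly from
#' `design$maf_range`. Two independent latent haplotype layers are sampled
#' from a block-AR(1) Gaussian with autocorrelation `ld_rho` and thresholded
#' at each SNP's MAF quantile; their sum gives dosages in `{0, 1, 2}`.
#' Genotype frequencies then satisfy Hardy-Weinberg equilibrium at the drawn
#' MAF, and the squared correlation of adjacent SNPs increases with
#' `ld_rho`. Columns that come out monomorphic are redrawn.
#'
#' @param design a [simulation_design()].
#' @param seed seed (defaults to `design$seed`).
#' @return A [genotype_matrix()] with SNPs evenly spaced on chromosome 1.
#' @export
simulate_genotypes <- function(design, seed = design$seed) {
  set.seed(seed)
  n <- design$n; p <- design$p
  maf <- runif(p, design$maf_range[1], design$maf_range[2])
  thr <- qnorm(1 - maf)
  draw_layer <- function() {
    Z <- matrix(rnorm(n * p), n, p)
    rho <- design$ld_rho
    if (rho > 0 && design$ld_block_size > 1) {
      sq <- sqrt(1 - rho^2)
      for (j in 2:p) {
        if ((j - 1) %% design$ld_block_size == 0) next  # new block
        Z[, j] <- rho * Z[, j - 1] + sq * Z[, j]
      }
    }
    Z
  }
  Z1 <- draw_layer(); Z2 <- draw_layer()
  dos <- (sweep(Z1, 2, thr, ">") + sweep(Z2, 2, thr, ">")) * 1
  for (tries in 1:50) {  # redraw rare monomorphic columns independently
    mono <- which(apply(dos, 2, var) == 0)
    if (!length(mono)) break
    for (j in mono)
      dos[, j] <- (rnorm(n) > thr[j]) + (rnorm(n) > thr[j])
  }
  if (any(apply(dos, 2, var) == 0))
    stop("could not generate polymorphic SNPs; raise n or maf_range")
  genotype_matrix(dos, chrom = rep("1", p),
                  pos = seq_len(p) * design$spacing_bp)
}

#' Simulate the causal association pattern
#'
#' Picks `n_active_snps` SNPs and `n_active_traits` traits uniformly; each
#' active SNP receives a degree of pleiotropy
#' `d_s = max(1, round(n_active_traits * Beta(pleiotropy_shape)))` and that
#' many partner traits drawn uniformly from the active set. Active traits
#' left without a SNP are repaired by assigning them a random active SNP, so
#' every active trait is controlled by at least one SNP.
#'
#' @param design a [simulation_design()].
#' @param seed seed (defaults to `design$seed + 1`).
#' @return List of class `qtl_pattern` with `gamma` (p x q logical mask),
#'   `active_snps`, `active_traits`, `degree` (per-SNP association count).
#' @export
simulate_pattern <- function(design, seed = design$seed + 1L) {
  set.seed(seed)
  p <- design$p; q <- design$q
  ks <- design$n_active_snps; kt <- design$n_active_traits
  gamma <- matrix(FALSE, p, q)
  act_s <- sort(sample.int(p, ks))
  act_t <- sort(sample.int(q, kt))
  if (ks > 0 && kt > 0) {
    d <- pmax(1, round(kt * rbeta(ks, design$pleiotropy_shape[1],
                                  design$pleiotropy_shape[2])))
    d <- pmin(d, kt)
    for (i in seq_len(ks))
      gamma[act_s[i], act_t[sample.int(kt, d[i])]] <- TRUE
    orphan <- act_t[colSums(gamma[, act_t, drop = FALSE]) == 0]
    for (t in orphan)
      gamma[act_s[sample.int(ks, 1)], t] <- TRUE
  }
  structure(list(gamma = gamma, active_snps = act_s, active_traits = act_t,
                 degree = rowSums(gamma)),
            class = "qtl_pattern")
}

# build the q x q residual correlation matrix from the design descriptor
resolve_residual_correlation <- function(design) {
  rc <- design$residual_correlation
  q <- design$q
  if (is.matrix(rc)) {
    if (!all(dim(rc) == q)) stop("residual correlation has wrong dimensions")
    return(rc)
  }
  C <- diag(q)
  starts <- seq(1, q, by = rc$block_size)
  for (s in starts) {
    idx <- s:min(s + rc$block_size - 1, q)
    C[idx, idx] <- rc$rho
  }
  diag(C) <- 1
  C
}

#' Simulate trait levels given genotypes and a causal pattern
#'
#' Per causal pair the proportion of trait variance explained (PVE) is drawn
#' from `Beta(pve_shape)`; per trait, the PVEs are rescaled proportionally
#' whenever their sum exceeds `max_trait_pve`. Effects follow the additive
#' dose-effect scheme `beta_st = sign * sqrt(PVE_st / Var(x_s))` with
#' independent random signs, which makes effect magnitudes inversely related
#' to minor-allele frequency. Residuals are drawn from a zero-mean Gaussian
#' with the design's trait correlation structure and variances that bring
#' each trait's total variance to 1, so PVE keeps its literal meaning.
#'
#' @param G a [genotype_matrix()] with `design$p` SNPs.
#' @param pattern a [simulate_pattern()] result (or a p x q logical mask).
#' @param design a [simulation_design()].
#' @param seed seed (defaults to `design$seed + 2`).
#' @return List with `traits` (a [trait_matrix()], gene coordinates
#'   attached) and `truth` (class `qtl_truth`: `gamma`, `beta`, `pve`,
#'   per-trait `pve_total`, per-SNP `degree`).
#' @export
simulate_traits <- function(G, pattern, design, seed = design$seed + 2L) {
  set.seed(seed)
  gamma <- if (inherits(pattern, "qtl_pattern")) pattern$gamma else pattern
  n <- design$n; q <- design$q
  stopifnot(nrow(gamma) == ncol(G$dosages), ncol(gamma) == q,
            nrow(G$dosages) == n)
  Xc <- sweep(G$dosages, 2, colMeans(G$dosages))
  vx <- apply(G$dosages, 2, var)

  pve <- matrix(0, nrow(gamma), q)
  npairs <- sum(gamma)
  pve[gamma] <- rbeta(npairs, design$pve_shape[1], design$pve_shape[2])
  tot <- colSums(pve)
  over <- tot > design$max_trait_pve
  if (any(over))
    pve[, over] <- sweep(pve[, over, drop = FALSE], 2,
                         design$max_trait_pve / tot[over], "*")
  beta <- matrix(0, nrow(gamma), q)
  beta[gamma] <- (2 * rbinom(npairs, 1, 0.5) - 1) *
    sqrt(pve[gamma] / rep(vx, ncol(gamma))[which(gamma)])

  genetic <- Xc %*% beta
  resid_sd <- sqrt(pmax(1 - colSums(pve), 1e-3))
  C <- resolve_residual_correlation(design)
  eps <- emulate_covariance(C, n, seed = seed + 10L)
  vals <- genetic + sweep(eps, 2, resid_sd, "*")
  dimnames(vals) <- list(rownames(G$dosages),
                         sprintf("trait_%03d", seq_len(q)))

  if (design$missing_rate > 0) {
    drop <- matrix(runif(n * q) < design$missing_rate, n, q)
    for (t in seq_len(q))  # keep every trait identifiable
      if (sum(!drop[, t]) < 2) drop[sample.int(n, 2), t] <- FALSE
    vals[drop] <- NA_real_
  }

  span <- max(G$info$pos)
  genes <- data.frame(trait_id = colnames(vals),
                      gene_chrom = "1",
                      gene_start = sample.int(span, q),
                      stringsAsFactors = FALSE)
  genes$gene_end <- genes$gene_start + 20000L

  truth <- structure(list(gamma = gamma, beta = beta, pve = pve,
                          pve_total = colSums(pve),
                          degree = rowSums(gamma)),
                     class = "qtl_truth")
  list(traits = trait_matrix(vals, genes = genes), truth = truth)
}

#' Sample a Gaussian block with a target correlation structure
#'
#' Draws `n` rows from a zero-mean, unit-variance Gaussian with the given
#' correlation matrix; non-positive-definite targets are repaired by
#' clipping eigenvalues at `1e-8` (with a warning) before factorization.
#'
#' @param target_correlation symmetric q x q matrix.
#' @param n rows to draw.
#' @param seed integer seed.
#' @return n x q numeric matrix.
#' @export
emulate_covariance <- function(target_correlation, n, seed = 1L) {
  C <- as.matrix(target_correlation)
  if (nrow(C) != ncol(C) || any(abs(C - t(C)) > 1e-8))
    stop("target correlation must be symmetric")
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning("target correlation repaired by eigenvalue clipping")
    ev$values <- pmax(ev$values, 1e-8)
    C <- ev$vectors %*% (ev$values * t(ev$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    ev <- eigen(C, symmetric = TRUE)
  }
  A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  set.seed(seed)
  matrix(rnorm(n * nrow(C)), n) %*% A
}

#' Generate a complete synthetic QTL study
#'
#' Convenience wrapper: genotypes, causal pattern, traits and ground truth
#' from one design and seed.
#'
#' @param design a [simulation_design()].
#' @param seed master seed (defaults to `design$seed`).
#' @return List of class `qtl_study` with `genotypes`, `traits`, `truth`,
#'   `pattern`, `design`, `seed`.
#' @export
simulate_qtl_study <- function(design = simulation_design(),
                               seed = design$seed) {
  G <- simulate_genotypes(design, seed = seed)
  pat <- simulate_pattern(design, seed = seed + 1L)
  st <- simulate_traits(G, pat, design, seed = seed + 2L)
  structure(list(genotypes = G, traits = st$traits, truth = st$truth,
                 pattern = pat, design = design, seed = as.integer(seed)),
            class = "qtl_study")
}

#' Write a synthetic study to disk
#'
#' Writes the delimited genotype/trait formats of [read_genotypes()] and
#' [read_traits()], a truth TSV (`snp_id`, `trait_id`, `beta`, `pve`) and a
#' JSON design record embedding the seed.
#'
#' @param study a [simulate_qtl_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_traits(study$traits, file.path(dir, "traits.tsv"))
  write.table(study$traits$genes, file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(study$truth$gamma, arr.ind = TRUE)
  truth <- data.frame(
    snp_id = colnames(study$genotypes$dosages)[idx[, 1]],
    trait_id = colnames(study$traits$values)[idx[, 2]],
    beta = study$truth$beta[idx], pve = study$truth$pve[idx])
  truth <- truth[order(truth$snp_id, truth$trait_id), ]
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  design <- study$design
  design$residual_correlation <- NULL  # may be a large matrix; keep JSON flat
  jsonlite::write_json(c(design, list(seed_used = study$seed)),
                       file.path(dir, "design.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
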