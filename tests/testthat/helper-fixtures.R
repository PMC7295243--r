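# programmatic fixtures

# small centered regression instance with a few real signals
random_instance <- function(n = 60, p = 6, q = 3, n_signal = 2,
                            pve = 0.25, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)[rep(seq_len(p), each = n)]),
              n, p)
  X <- scale(X, scale = FALSE)
  B <- matrix(0, p, q)
  if (n_signal > 0) {
    idx <- cbind(sample.int(p, n_signal, replace = TRUE),
                 sample.int(q, n_signal, replace = TRUE))
    B[idx] <- sqrt(pve / pmax(apply(X, 2, var)[idx[, 1]], 1e-8))
  }
  Y <- scale(X %*% B + matrix(rnorm(n * q), n, q), scale = FALSE)
  list(X = X, Y = Y, B = B)
}

# minimal 4-sample, 2-site VCF; second site monomorphic
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "2000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", "0/0", sep = "\t")), path)
  path
}

# tiny genotype container on one chromosome with chosen dosage columns
toy_genotypes <- function(dosages, pos = NULL) {
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(p) * 1000
  genotype_matrix(dosages, chrom = rep("1", p), pos = pos)
}
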