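#' Geometric annealing schedule
#'
#' Temperature ladder for the annealed variational optimizer: `K`
#' geometrically spaced temperatures decreasing from `T_init` to exactly 1.
#' The default ladder (50 temperatures starting at 20) gives the sampler-like
#' exploration needed when strong linkage disequilibrium makes the posterior
#' multimodal.
#'
#' @param T_init initial temperature, `>= 1`.
#' @param K number of temperatures, `>= 1`.
#' @return Numeric vector of length `K`, strictly decreasing, ending at 1
#'   (or the single value 1 when `K = 1`).
#' @export
anneal_schedule <- function(T_init = 20, K = 50) {
  if (T_init < 1) stop("T_init must be >= 1")
  if (K < 1 || K != round(K)) stop("K must be a positive integer")
  if (K == 1) return(1)
  out <- exp(seq(log(T_init), 0, length.out = K))
  out[K] <- 1  # exact cold end
  out
}

#' Elicit the sparsity-inducing Beta prior on hotspot propensities
#'
#' The per-SNP propensity `omega_s` is the prior probability that SNP `s` is
#' associated with any given trait. Its Beta(a_s, b_s) prior is elicited from
#' the expected number of trait-associated SNPs and the expected number of
#' traits each of them hits: the prior mean is
#' `(expected_active_snps / p) * (expected_traits_per_active_snp / q)`, and
#' with `a_s` fixed at 1 the implied `b_s = 1/mean - 1` concentrates the
#' prior near zero, so that `omega_s` exceeding twice its mean is improbable.
#'
#' @param p,q numbers of SNPs and traits.
#' @param expected_active_snps prior expected count of SNPs with at least one
#'   association, in `(0, p]`.
#' @param expected_traits_per_active_snp prior expected number of traits an
#'   active SNP controls, in `(0, q]`.
#' @return List with elements `a_s` and `b_s` (scalars, recycled per SNP).
#' @export
elicit_sparsity_prior <- function(p, q, expected_active_snps,
                                  expected_traits_per_active_snp = 1) {
  if (expected_active_snps <= 0 || expected_active_snps > p)
    stop("expected_active_snps must be in (0, p]")
  if (expected_traits_per_active_snp <= 0 ||
      expected_traits_per_active_snp > q)
    stop("expected_traits_per_active_snp must be in (0, q]")
  m <- (expected_active_snps / p) * (expected_traits_per_active_snp / q)
  if (m >= 1) stop("implied prior mean of omega_s must be < 1")
  list(a_s = 1, b_s = 1 / m - 1)
}

#' Control parameters for the joint mapping model
#'
#' Collects every fixed hyperparameter of the hierarchical spike-and-slab
#' model and the optimizer settings.
#'
#' Hyperpriors default to weakly informative values: `eta = kappa = 1e-2`
#' (diffuse Gamma on each trait's residual precision), `lambda = nu = 1e-2`
#' (diffuse Gamma on the inverse squared typical effect size). When `a_s`,
#' `b_s` are not supplied they are elicited at fitting time by
#' [elicit_sparsity_prior()] with `expected_active_snps = min(50, p/10)` and
#' `expected_traits_per_active_snp = 1`.
#'
#' The `fix_*` arguments freeze the corresponding posterior factor at a point
#' mass instead of updating it -- useful for validation against closed-form
#' posteriors and for sensitivity analyses.
#'
#' @param a_s,b_s Beta prior shapes for the hotspot propensities (scalar or
#'   per-SNP vectors); `NULL` to elicit at fit time.
#' @param eta,kappa Gamma shape/rate for the residual precisions (scalar or
#'   per-trait).
#' @param lambda,nu Gamma shape/rate for the inverse squared slab scale.
#' @param n_temperatures,T_init annealing ladder, see [anneal_schedule()].
#' @param anneal set `FALSE` to optimize at temperature 1 throughout.
#' @param tol convergence tolerance on the absolute change of the objective
#'   between consecutive temperature-1 sweeps (default `1e-3`).
#' @param max_iter maximum number of temperature-1 sweeps.
#' @param expected_active_snps,expected_traits_per_active_snp elicitation
#'   inputs used when `a_s`, `b_s` are `NULL`.
#' @param fix_tau,fix_sigma2_inv,fix_omega optional point values freezing the
#'   residual precisions (per-trait vector), the slab precision scale
#'   (scalar `1/sigma^2`) and the hotspot propensities (per-SNP vector).
#' @param seed integer recorded with the fit (the optimizer itself is
#'   deterministic).
#' @return A list of class `jqtl_control`.
#' @export
jqtl_control <- function(a_s = NULL, b_s = NULL, eta = 1e-2, kappa = 1e-2,
                         lambda = 1e-2, nu = 1e-2, n_temperatures = 50,
                         T_init = 20, anneal = TRUE, tol = 1e-3,
                         max_iter = 1000, expected_active_snps = NULL,
                         expected_traits_per_active_snp = 1,
                         fix_tau = NULL, fix_sigma2_inv = NULL,
                         fix_omega = NULL, seed = 1L) {
  stopifnot(eta > 0, kappa > 0, lambda > 0, nu > 0, tol > 0,
            n_temperatures >= 1, T_init >= 1, max_iter >= 0)
  if (!is.null(a_s)) stopifnot(all(a_s > 0))
  if (!is.null(b_s)) stopifnot(all(b_s > 0))
  structure(list(a_s = a_s, b_s = b_s, eta = eta, kappa = kappa,
                 lambda = lambda, nu = nu, n_temperatures = n_temperatures,
                 T_init = T_init, anneal = anneal, tol = tol,
                 max_iter = max_iter,
                 expected_active_snps = expected_active_snps,
                 expected_traits_per_active_snp =
                   expected_traits_per_active_snp,
                 fix_tau = fix_tau, fix_sigma2_inv = fix_sigma2_inv,
                 fix_omega = fix_omega, seed = as.integer(seed)),
            class = "jqtl_control")
}
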