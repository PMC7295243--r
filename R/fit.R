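#' Fit the joint spike-and-slab QTL model
#'
#' Fits, by annealed coordinate-ascent variational inference, the
#' hierarchical model in which every trait is regressed on all SNPs at once,
#'
#' \deqn{y_t = X \beta_t + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \tau_t^{-1} I),}
#'
#' with a spike-and-slab prior on every effect,
#' \eqn{\beta_{st} \mid \gamma_{st} \sim \gamma_{st}
#' N(0, \sigma^2 \tau_t^{-1}) + (1-\gamma_{st}) \delta_0},
#' \eqn{\gamma_{st} \sim \mathrm{Bern}(\omega_s)}, a Beta prior on each SNP's
#' hotspot propensity \eqn{\omega_s}, and Gamma priors on the residual
#' precisions \eqn{\tau_t} and on \eqn{\sigma^{-2}}. Sharing \eqn{\omega_s}
#' across traits and \eqn{\sigma} across all effects lets the model borrow
#' strength across correlated molecular outcomes, which is where its power
#' advantage over single-pair testing comes from.
#'
#' The optimizer runs one batch sweep per temperature of a geometric ladder
#' (see [anneal_schedule()]) and then iterates temperature-1 sweeps until the
#' objective changes by less than `control$tol`. Missing trait values are
#' handled inside the inference by restricting every inner product to each
#' trait's observed samples; they are never imputed.
#'
#' Genotypes and traits are centered internally (per column, on observed
#' entries); genotypes are not variance-standardized, so `beta` is on the
#' per-minor-allele scale. If `covariates` are supplied, traits are
#' residualized on them first (see [residualize_covariates()]).
#'
#' @param G a [genotype_matrix()] or plain numeric dosage matrix (samples by
#'   SNPs).
#' @param Y a [trait_matrix()] or plain numeric matrix (samples by traits);
#'   `NA` marks missing values.
#' @param covariates optional [covariate_table()] (or matrix) to residualize
#'   the traits on.
#' @param control a [jqtl_control()] list.
#' @return An object of class `jqtl` with components
#'   \describe{
#'     \item{ppi}{p x q posterior inclusion probabilities
#'       \eqn{pr(\gamma_{st}=1 \mid y)}.}
#'     \item{beta_mean}{p x q marginal posterior mean effects
#'       (inclusion probability times slab mean).}
#'     \item{omega_mean}{per-SNP posterior mean hotspot propensity
#'       \eqn{E(\omega_s \mid y)}.}
#'     \item{tau_mean}{per-trait posterior mean residual precision.}
#'     \item{sigma2_inv_mean}{posterior mean of \eqn{\sigma^{-2}}.}
#'     \item{diagnostics}{iteration counts, objective trace, schedule,
#'       convergence flag.}
#'   }
#' @seealso [bayesian_fdr_select()] to call discoveries, [summary.jqtl()],
#'   [univariate_scan()] for the single-pair comparator.
#' @export
jqtl <- function(G, Y, covariates = NULL, control = jqtl_control()) {
  stopifnot(inherits(control, "jqtl_control"))
  info <- if (inherits(G, "genotype_matrix")) G$info else NULL
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (!inherits(Y, "trait_matrix")) Y <- trait_matrix(as.matrix(Y))
  if (!is.null(covariates)) {
    if (!inherits(covariates, "covariate_table"))
      covariates <- covariate_table(as.matrix(covariates))
    Y <- residualize_covariates(Y, covariates)
  }
  if (nrow(X) != nrow(Y$values))
    stop("genotypes and traits have different sample counts")

  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- colSums(ifelse(Y$mask, Y$values, 0)) / colSums(Y$mask)
  Yc <- center_columns(Y$values, Y$mask)

  jqtl_fit_centered(Xc, Yc, control, info = info, genes = Y$genes,
                    xbar = xbar, ybar = ybar, mask = Y$mask,
                    call = match.call())
}

# core fit on already-centered inputs; also used by batch_split_experiment
# to avoid re-centering the genotype panel for every batch
jqtl_fit_centered <- function(Xc, Yc, control, info = NULL, genes = NULL,
                              xbar = NULL, ybar = NULL, mask = NULL,
                              call = NULL) {
  if (is.null(mask)) mask <- is.finite(Yc)
  if (is.null(xbar)) xbar <- rep(0, ncol(Xc))
  if (is.null(ybar)) ybar <- rep(0, ncol(Yc))
  if (is.null(colnames(Xc)))
    colnames(Xc) <- sprintf("snp_%05d", seq_len(ncol(Xc)))
  if (is.null(colnames(Yc)))
    colnames(Yc) <- sprintf("trait_%03d", seq_len(ncol(Yc)))
  st <- jqtl_init(Xc, Yc, control)
  schedule <- if (control$anneal)
    anneal_schedule(control$T_init, control$n_temperatures) else 1
  res <- .vb_fit_cpp(Xc, st$Y0, st$M, st$any_missing, st$g, st$mu,
                     st$a_s, st$b_s, st$eta, st$kappa,
                     control$lambda, control$nu,
                     schedule, control$tol, control$max_iter,
                     st$fix_tau, st$tau_fixed, st$fix_sigma, st$sig_fixed,
                     st$fix_omega, st$omega_fixed)
  if (!res$converged && control$max_iter > 0)
    warning("variational optimizer did not converge within max_iter sweeps")

  snp_ids <- colnames(Xc)
  trait_ids <- colnames(Yc)
  dn <- list(snp_ids, trait_ids)
  ppi <- res$g; dimnames(ppi) <- dn
  beta <- res$g * res$mu; dimnames(beta) <- dn
  omega_mean <- if (st$fix_omega) st$omega_fixed else
    as.vector(res$omega_a / (res$omega_a + res$omega_b))
  names(omega_mean) <- snp_ids
  tau_mean <- if (st$fix_tau) st$tau_fixed else
    as.vector(res$tau_shape / res$tau_rate)
  names(tau_mean) <- trait_ids

  structure(list(
    ppi = ppi, beta_mean = beta, mu = res$mu, s2 = res$s2,
    omega_mean = omega_mean, tau_mean = tau_mean,
    sigma2_inv_mean = if (st$fix_sigma) st$sig_fixed else
      res$sigma2inv_shape / res$sigma2inv_rate,
    state = res, snp_info = info, genes = genes,
    xbar = xbar, ybar = ybar,
    X = Xc, Y = Yc, mask = mask,
    prior = list(a_s = st$a_s[1], b_s = st$b_s[1]),
    control = control,
    diagnostics = list(
      converged = res$converged,
      n_sweeps_total = length(res$trace_objective),
      n_sweeps_cold = res$n_sweeps_cold,
      objective = res$objective,
      trace_objective = res$trace_objective,
      trace_temperature = res$trace_temperature,
      schedule = schedule,
      seed = control$seed),
    dims = c(n = nrow(Xc), p = ncol(Xc), q = ncol(Yc)),
    call = call),
    class = "jqtl")
}

#' Initialize the variational state
#'
#' Deterministic initialization used by [jqtl()]: inclusion probabilities at
#' the Beta prior mean `a_s / (a_s + b_s)`, slab means at zero, and all
#' conjugate factors at their prior values. Inputs must already be
#' column-centered.
#'
#' @param Xc centered dosage matrix.
#' @param Yc centered trait matrix (`NA` allowed).
#' @param control a [jqtl_control()].
#' @return List with the initial factor parameters and the resolved prior,
#'   consumed by the internal optimizer.
#' @export
jqtl_init <- function(Xc, Yc, control = jqtl_control()) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  if (nrow(Yc) != n) stop("dimension mismatch between genotypes and traits")
  if (max(abs(colMeans(Xc))) > 1e-6 * max(1, max(abs(Xc))))
    stop("genotypes are not centered; call center_columns() first")
  M <- ifelse(is.finite(Yc), 1, 0)
  Y0 <- ifelse(is.finite(Yc), Yc, 0)
  cm <- colSums(Y0) / pmax(colSums(M), 1)
  if (max(abs(cm)) > 1e-6 * max(1, max(abs(Y0))))
    stop("traits are not centered; call center_columns() first")

  ab <- if (is.null(control$a_s) || is.null(control$b_s)) {
    ea <- control$expected_active_snps
    if (is.null(ea)) ea <- min(50, p / 10)
    ea <- max(min(ea, p), 1e-8)
    et <- min(control$expected_traits_per_active_snp, q)
    elicit_sparsity_prior(p, q, ea, et)
  } else list(a_s = control$a_s, b_s = control$b_s)
  a_s <- rep_len(ab$a_s, p); b_s <- rep_len(ab$b_s, p)

  fix_omega <- !is.null(control$fix_omega)
  omega_fixed <- if (fix_omega) rep_len(control$fix_omega, p) else rep(0.5, p)
  g0 <- matrix(if (fix_omega) omega_fixed else a_s / (a_s + b_s), p, q)
  list(g = g0, mu = matrix(0, p, q), s2 = matrix(1, p, q),
       a_s = a_s, b_s = b_s,
       eta = rep_len(control$eta, q), kappa = rep_len(control$kappa, q),
       omega_a = a_s, omega_b = b_s,
       tau_shape = rep_len(control$eta, q),
       tau_rate = rep_len(control$kappa, q),
       sigma2inv_shape = control$lambda, sigma2inv_rate = control$nu,
       M = M, Y0 = Y0, any_missing = any(M == 0),
       fix_tau = !is.null(control$fix_tau),
       tau_fixed = if (is.null(control$fix_tau)) rep(1, q) else
         rep_len(control$fix_tau, q),
       fix_sigma = !is.null(control$fix_sigma2_inv),
       sig_fixed = if (is.null(control$fix_sigma2_inv)) 1 else
         control$fix_sigma2_inv,
       fix_omega = fix_omega, omega_fixed = omega_fixed)
}

#' One tempered variational sweep
#'
#' Applies a single batch coordinate-ascent pass at the given temperature:
#' all `(beta, gamma)` blocks in trait-major order with running residuals,
#' then the conjugate Beta/Gamma updates. Exposed for validation; [jqtl()]
#' drives the full schedule.
#'
#' @param state a state as returned by [jqtl_init()] or a previous sweep.
#' @param Xc,Yc centered inputs as in [jqtl_init()].
#' @param control a [jqtl_control()].
#' @param temperature sweep temperature, `>= 1`; at 1 the swept objective is
#'   the evidence lower bound and sweeps are monotone.
#' @return The updated state; element `objective` holds the tempered
#'   objective after the sweep.
#' @export
jqtl_sweep <- function(state, Xc, Yc, control = jqtl_control(),
                       temperature = 1) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  M <- ifelse(is.finite(Yc), 1, 0)
  Y0 <- ifelse(is.finite(Yc), Yc, 0)
  res <- .vb_sweep_cpp(Xc, Y0, M, any(M == 0),
                       state$g, state$mu, state$s2,
                       state$omega_a, state$omega_b,
                       state$tau_shape, state$tau_rate,
                       state$sigma2inv_shape, state$sigma2inv_rate,
                       state$a_s, state$b_s, state$eta, state$kappa,
                       control$lambda, control$nu, temperature,
                       state$fix_tau, state$tau_fixed,
                       state$fix_sigma, state$sig_fixed,
                       state$fix_omega, state$omega_fixed)
  state$g <- res$g; state$mu <- res$mu; state$s2 <- res$s2
  state$omega_a <- as.vector(res$omega_a)
  state$omega_b <- as.vector(res$omega_b)
  state$tau_shape <- as.vector(res$tau_shape)
  state$tau_rate <- as.vector(res$tau_rate)
  state$sigma2inv_shape <- res$sigma2inv_shape
  state$sigma2inv_rate <- res$sigma2inv_rate
  state$objective <- res$objective
  state$temperature <- temperature
  state
}

#' @export
print.jqtl <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Joint spike-and-slab QTL fit: n = %d, p = %d SNPs, q = %d traits\n",
              d["n"], d["p"], d["q"]))
  cat(sprintf("  %s after %d sweeps (%d at temperature 1); objective %.4f\n",
              if (x$diagnostics$converged) "converged" else "NOT converged",
              x$diagnostics$n_sweeps_total, x$diagnostics$n_sweeps_cold,
              x$diagnostics$objective))
  cat(sprintf("  pairs with PPI > 0.5: %d; max hotspot propensity: %.3g\n",
              sum(x$ppi > 0.5), max(x$omega_mean)))
  invisible(x)
}

#' Summarize a joint QTL fit
#'
#' Reports the discoveries at a Bayesian FDR level and the strongest hotspot
#' SNPs (largest posterior mean propensities).
#'
#' @param object a [jqtl()] fit.
#' @param fdr_level Bayesian FDR level for the discovery count (default 0.05).
#' @param n_hotspots number of top hotspot SNPs to display.
#' @param ... unused.
#' @return A list of class `summary.jqtl` with the selection table and
#'   hotspot ranking.
#' @export
summary.jqtl <- function(object, fdr_level = 0.05, n_hotspots = 5, ...) {
  hits <- bayesian_fdr_select(object, level = fdr_level)
  deg <- rowSums(object$ppi > 0.5)
  ord <- order(object$omega_mean, decreasing = TRUE)
  hs <- data.frame(snp_id = names(object$omega_mean)[ord],
                   omega_mean = object$omega_mean[ord],
                   traits_ppi_gt_0.5 = deg[ord], row.names = NULL)
  structure(list(dims = object$dims, fdr_level = fdr_level, hits = hits,
                 hotspots = head(hs, n_hotspots),
                 diagnostics = object$diagnostics),
            class = "summary.jqtl")
}

#' @export
print.summary.jqtl <- function(x, ...) {
  cat(sprintf("Joint QTL fit (n = %d, p = %d, q = %d)\n",
              x$dims["n"], x$dims["p"], x$dims["q"]))
  cat(sprintf("Discoveries at Bayesian FDR %.0f%%: %d SNP-trait pairs\n",
              100 * x$fdr_level, nrow(x$hits)))
  if (nrow(x$hits)) {
    cat("Top associations:\n")
    print(head(x$hits[, c("snp_id", "trait_id", "ppi", "beta_mean")], 10))
  }
  cat("Top hotspot SNPs:\n")
  print(x$hotspots)
  invisible(x)
}

#' @export
coef.jqtl <- function(object, ...) object$beta_mean

#' @export
fitted.jqtl <- function(object, ...) {
  sweep(object$X %*% object$beta_mean, 2, object$ybar, "+")
}

#' @export
residuals.jqtl <- function(object, ...) {
  r <- (object$Y - object$X %*% object$beta_mean)
  r[!object$mask] <- NA_real_
  r
}

#' Predict trait levels for new genotypes
#'
#' @param object a [jqtl()] fit.
#' @param newdata dosage matrix (or [genotype_matrix()]) with the same SNPs.
#' @param ... unused.
#' @return Matrix of posterior-mean trait predictions on the original trait
#'   scale.
#' @export
predict.jqtl <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  Xn <- if (inherits(newdata, "genotype_matrix")) newdata$dosages
        else as.matrix(newdata)
  if (ncol(Xn) != nrow(object$beta_mean)) stop("newdata has the wrong SNPs")
  sweep(sweep(Xn, 2, object$xbar) %*% object$beta_mean, 2, object$ybar, "+")
}

#' Simulate trait matrices from the fitted model
#'
#' Draws traits from the posterior-mean generative model: each trait is its
#' fitted genetic component plus Gaussian noise at the posterior mean
#' residual precision.
#'
#' @param object a [jqtl()] fit.
#' @param nsim number of trait matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of `nsim` matrices.
#' @export
simulate.jqtl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fv <- fitted(object)
  sds <- rep(1 / sqrt(object$tau_mean), each = nrow(fv))
  lapply(seq_len(nsim), function(i)
    fv + matrix(rnorm(length(fv), sd = sds), nrow(fv), ncol(fv)))
}

#' Plot hotspot propensities along the genome
#'
#' @param x a [jqtl()] fit.
#' @param ppi_min pairs with PPI above this are marked (default 0.5).
#' @param ... passed to [plot()].
#' @export
plot.jqtl <- function(x, ppi_min = 0.5, ...) {
  pos <- if (!is.null(x$snp_info)) x$snp_info$pos else
    seq_along(x$omega_mean)
  plot(pos, x$omega_mean, type = "h", xlab = "position (bp)",
       ylab = expression(E(omega[s] ~ "|" ~ y)),
       main = "Pleiotropy propensity", ...)
  hit <- which(rowSums(x$ppi > ppi_min) > 0)
  if (length(hit)) points(pos[hit], x$omega_mean[hit], col = 2, pch = 16)
  invisible(x)
}

#' Long-format association table of a fit
#'
#' @param x a [jqtl()] fit.
#' @param ppi_min keep pairs with PPI at or above this (default 0, all pairs).
#' @param ... unused.
#' @return Data frame with columns `snp_id`, `trait_id`, `ppi`, `beta_mean`,
#'   sorted by decreasing PPI.
#' @export
as.data.frame.jqtl <- function(x, ppi_min = 0, ...) {
  idx <- which(x$ppi >= ppi_min, arr.ind = TRUE)
  out <- data.frame(snp_id = rownames(x$ppi)[idx[, 1]],
                    trait_id = colnames(x$ppi)[idx[, 2]],
                    ppi = x$ppi[idx], beta_mean = x$beta_mean[idx],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$ppi, out$snp_id, out$trait_id), , drop = FALSE]
}

#' Write fit outputs to a directory
#'
#' Writes the long association table and the per-SNP hotspot table as TSV,
#' and a JSON fit report (seed, schedule, iterations, objective trace).
#'
#' @param fit a [jqtl()] fit.
#' @param dir output directory (created if needed).
#' @param ppi_min threshold for the association table (default 0.01 keeps
#'   file sizes sane).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir, ppi_min = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(fit, ppi_min = ppi_min),
              file.path(dir, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(snp_id = names(fit$omega_mean),
                         omega_mean = fit$omega_mean, row.names = NULL),
              file.path(dir, "hotspots.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = fit$diagnostics$seed,
         schedule = fit$diagnostics$schedule,
         n_sweeps_total = fit$diagnostics$n_sweeps_total,
         n_sweeps_cold = fit$diagnostics$n_sweeps_cold,
         converged = fit$diagnostics$converged,
         objective_trace = fit$diagnostics$trace_objective),
    file.path(dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
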