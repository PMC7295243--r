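# Independent oracles used across the suite. All of these are deliberately
# naive (enumeration, per-pair lm fits, closed forms) and share no code with
# the package internals they check.

# log N(y; 0, V)
log_mvn_dens <- function(y, V) {
  ch <- chol(V)
  -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2) -
    length(y) / 2 * log(2 * pi)
}

# exact posterior inclusion probability for a single (SNP, trait) pair with
# fixed tau, sigma^2 and omega: two-model Bayes factor, spike vs conjugate
# Gaussian slab
exact_single_ppi <- function(x, y, tau, sigma2, omega) {
  n <- length(y)
  l0 <- log_mvn_dens(y, diag(n) / tau)
  l1 <- log_mvn_dens(y, diag(n) / tau + sigma2 / tau * tcrossprod(x))
  plogis(log(omega / (1 - omega)) + l1 - l0)
}

# exact PPIs by summing conjugate marginal likelihoods over all 2^p inclusion
# configurations per trait (traits decouple when tau, sigma2, omega are
# fixed); feasible for p <= ~10
enum_ppi <- function(X, Y, sigma2, omega, tau) {
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  omega <- rep_len(omega, p)
  ppi <- matrix(0, p, q)
  sets <- lapply(0:(2^p - 1), function(k) which(bitwAnd(k, 2^(0:(p - 1))) > 0))
  for (t in seq_len(q)) {
    y <- Y[, t]
    lw <- vapply(sets, function(S) {
      V <- diag(n) / tau
      if (length(S))
        V <- V + sigma2 / tau *
          tcrossprod(X[, S, drop = FALSE], X[, S, drop = FALSE])
      log_mvn_dens(y, V) + sum(log(omega)[S]) +
        sum(log(1 - omega)[setdiff(seq_len(p), S)])
    }, numeric(1))
    w <- exp(lw - max(lw)); w <- w / sum(w)
    for (s in seq_len(p))
      ppi[s, t] <- sum(w[vapply(sets, function(S) s %in% S, logical(1))])
  }
  ppi
}

# Mann-Whitney AUC (rank-sum identity)
mann_whitney_auc <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# naive per-pair OLS scan with lm(), observed samples only
lm_scan <- function(X, Y) {
  p <- ncol(X); q <- ncol(Y)
  eff <- pv <- matrix(NA_real_, p, q)
  for (s in seq_len(p)) for (t in seq_len(q)) {
    obs <- is.finite(Y[, t])
    f <- summary(lm(Y[obs, t] ~ X[obs, s]))$coefficients
    eff[s, t] <- f[2, 1]; pv[s, t] <- f[2, 4]
  }
  list(effect = eff, p_value = pv)
}

# pure-R reference implementation of one tempered variational sweep,
# sequential over traits then SNPs, written directly from the update
# equations; checks the optimized (blocked, BLAS) C++ path
reference_sweep <- function(state, Xc, Yc, control, temperature = 1) {
  p <- ncol(Xc); q <- ncol(Yc); n <- nrow(Xc)
  M <- is.finite(Yc)
  Y0 <- ifelse(M, Yc, 0)
  invT <- 1 / temperature
  g <- state$g; mu <- state$mu; s2 <- state$s2
  Etau <- state$tau_shape / state$tau_rate
  Elogtau <- digamma(state$tau_shape) - log(state$tau_rate)
  if (state$fix_tau) { Etau <- state$tau_fixed; Elogtau <- log(Etau) }
  Esig <- state$sigma2inv_shape / state$sigma2inv_rate
  Elogsig <- digamma(state$sigma2inv_shape) - log(state$sigma2inv_rate)
  if (state$fix_sigma) { Esig <- state$sig_fixed; Elogsig <- log(Esig) }
  if (state$fix_omega) {
    Elw <- log(state$omega_fixed); El1 <- log(1 - state$omega_fixed)
  } else {
    Elw <- digamma(state$omega_a) - digamma(state$omega_a + state$omega_b)
    El1 <- digamma(state$omega_b) - digamma(state$omega_a + state$omega_b)
  }
  for (t in seq_len(q)) {
    m <- M[, t]
    r <- ifelse(m, Y0[, t] - Xc %*% (g[, t] * mu[, t]), 0)
    for (s in seq_len(p)) {
      xm <- Xc[, s] * m
      xtx <- sum(xm^2)
      b_old <- g[s, t] * mu[s, t]
      xr <- sum(xm * r) + b_old * xtx
      prec <- Etau[t] * (invT * xtx + Esig)
      s2[s, t] <- 1 / prec
      mu[s, t] <- invT * Etau[t] * xr / prec
      u <- Elw[s] - El1[s] + 0.5 * (Elogsig + Elogtau[t]) +
        0.5 * log(s2[s, t]) + mu[s, t]^2 / (2 * s2[s, t])
      u <- max(min(u, 35), -35)
      g[s, t] <- plogis(u)
      r <- r + (b_old - g[s, t] * mu[s, t]) * xm
    }
  }
  nobs <- colSums(M)
  Sg <- colSums(g); Sm <- colSums(g * (mu^2 + s2))
  out <- state
  out$g <- g; out$mu <- mu; out$s2 <- s2
  if (!state$fix_omega) {
    out$omega_a <- state$a_s + rowSums(g)
    out$omega_b <- state$b_s + q - rowSums(g)
  }
  if (!state$fix_tau) {
    Ers <- vapply(seq_len(q), function(t) {
      m <- M[, t]
      rr <- ifelse(m, Y0[, t] - Xc %*% (g[, t] * mu[, t]), 0)
      xtx <- colSums((Xc * m)^2)
      sum(rr^2) + sum(xtx * (g[, t] * (mu[, t]^2 + s2[, t]) -
                               (g[, t] * mu[, t])^2))
    }, numeric(1))
    out$tau_shape <- state$eta + 0.5 * invT * nobs + 0.5 * Sg
    out$tau_rate <- state$kappa + 0.5 * invT * Ers + 0.5 * Esig * Sm
  }
  if (!state$fix_sigma) {
    Etau2 <- if (state$fix_tau) state$tau_fixed else
      out$tau_shape / out$tau_rate
    out$sigma2inv_shape <- control$lambda + 0.5 * sum(Sg)
    out$sigma2inv_rate <- control$nu + 0.5 * sum(Etau2 * Sm)
  }
  out
}
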